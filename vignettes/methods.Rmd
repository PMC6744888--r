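---
title: "Endogenous-fluctuation-triggered risky choice: models, trigger, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endogenous-fluctuation-triggered risky choice: models, trigger, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endofluct)
```

## The problem this package addresses

Spontaneous ("endogenous") fluctuations in BOLD activity of the dopaminergic
midbrain (SN/VTA) are hypothesized to bias risky decision making: options
presented against a background of *low* activity elicit larger phasic
(task-evoked) responses and more risk taking than identical options
presented during *high* activity. Testing this requires (i) an online
algorithm that classifies each moment of an incoming single-ROI BOLD stream
as low or high and triggers trial presentation accordingly, (ii) an
economic choice model that can express a value-independent shift in risk
appetite, and (iii) group-level statistics for the evoked responses and for
the mediation chain from prestimulus state through phasic response to
choice.

`endofluct` implements all three stages plus a seeded synthetic-data
generator that emulates the coupled BOLD/behavioral structure, so that every
stage can be validated by simulation, parameter recovery, and calibration
checks without access to scanner data.

## The decision model

Each trial offers a gamble paying a prize $V_\text{gain} \in \{6, 9, 12\}$
pounds or £0 with equal probability, against a certain amount
$V_\text{certain}$. Utilities follow a one-parameter power value function,

$$U_\text{gamble} = 0.5\,V_\text{gain}^{\alpha}, \qquad
  U_\text{certain} = V_\text{certain}^{\alpha},$$

with risk aversion $\alpha$ ($\alpha<1$ risk-averse, $=1$ neutral, $>1$
seeking). Choice follows a softmax with inverse temperature $\mu$ and an
additive *gambling bias* $\kappa$:

$$P_\text{gamble} =
  \frac{1}{1 + e^{-\mu\,(U_\text{gamble} - U_\text{certain} + \kappa)}}.$$

$\kappa$ shifts the sigmoid horizontally: a positive bias favors the gamble
at every offer value. The base model fixes $\kappa = 0$. The package
registry (`model_spec()`) contains:

* `pt` — base model, free $(\alpha, \mu)$;
* `pt_kappa` — adds a single free $\kappa$;
* `pt_kappa_cond` — shared $(\alpha, \mu)$ with separate
  $\kappa_\text{low}, \kappa_\text{high}$ per activity condition;
* `pt_mult`, `pt_dual_alpha` — two further comparison models (a
  multiplicative bias on the gamble's utility, and curvature split at a £9
  reference prize). These two are structural placeholders that keep the
  model-comparison machinery exercised; they are not claimed to match any
  particular published alternative.

An identifiability point that shaped the registry: a *constant* additive
$\kappa$ is almost perfectly mimicked by adjusting $(\alpha, \mu)$ on these
offer designs (we measure a likelihood gain of only ~0.7 nats per 180
calibration trials), so BIC cannot recover a constant bias at realistic
per-subject trial counts. What *is* recoverable — and what the scientific
claim concerns — is a bias that *differs between activity conditions*,
because no setting of $(\alpha, \mu)$ can produce any low/high asymmetry on
matched offers. `pt_kappa_cond` expresses exactly that and is the model the
BIC comparison selects on data generated with a condition-dependent bias.

Fitting (`fit_mle()`) is bounded maximum likelihood: box constraints
$\alpha \in (0, 3]$, $\mu \in (10^{-3}, 50]$, $\kappa \in [-5, 5]$,
multi-start `L-BFGS-B` from the canonical start plus Latin-hypercube points
(20 by default), best NLL kept, deterministic given the seed. Missed trials
(`choice = NA`) are excluded from the likelihood. Goodness of fit is
summarized by a McFadden-style pseudo-$R^2$ against a coin-flip null,
$1 - \mathrm{LL}/(n \ln 0.5)$, and models are compared by
$\mathrm{BIC} = k \ln n - 2\,\mathrm{LL}$ summed over subjects.

## The real-time trigger

The trigger (`run_session()`, or `trigger_step()` online) quantifies the
momentary activity level non-parametrically against the recent past: the
mean $m$ of the most recent 2 volumes is ranked against the 69 volumes
immediately preceding them via a normal CDF,
$\Phi\!\big((m - \mu_w)/\sigma_w\big)$, updated with every new volume
(TR = 1.75 s, so the window spans about 2 minutes). Percentiles at or below
0.15 trigger a *low* trial, at or above 0.85 a *high* trial; a 20-s minimum
inter-trial interval lets the hemodynamic response relax, and if neither
threshold is met within 55 s a trial is forced and labelled by the sign of
$m - \mu_w$. Design choices the protocol leaves open, resolved here:

* the 69-volume window *excludes* the 2 volumes being tested;
* thresholds are closed ($\le 0.15$, $\ge 0.85$) for floating-point
  robustness — a measure-zero difference;
* window SD uses the $n-1$ denominator; a zero-variance window returns 0.5;
* no events fire before 71 samples exist (warm-up), and the ITI clock for
  the first trial is anchored at the end of warm-up;
* the rule is evaluated at every volume; volume indexing is 0-based with
  times `index × TR`.

One property worth knowing: because a 2-volume mean is ranked against the
spread of *single* volumes, its percentile distribution is compressed
toward 0.5. On white noise the 0.15 threshold is crossed with probability
$\Phi\!\big(\Phi^{-1}(0.15)\big/\sqrt{1/2 + 1/69}\big) \approx 0.074$ per
evaluable volume, not 0.15. Autocorrelated real signals sit in between;
the timeout rule guarantees trials keep coming regardless.

Real-time denoising is modelled by `incremental_nuisance_regress()`: an
expanding-window least-squares fit of the signal on nuisance regressors
(plus intercept) that returns the running residual; after a full pass the
coefficients equal the batch solution, and collinear regressors fall back
to a flagged minimum-norm solution.

## Task design

Calibration offers use the fixed divisor ladder (0.82 … 3.5) applied to the
gambles' expected values, three gains × 12 divisors × 5 repeats = 180
trials (day 1; 3 repeats = 108 on day 2), rounded to the penny. For the
triggered session, `safe_values_for_pbins()` inverts the fitted base model:
a target probability $p$ maps to
$U_\text{certain} = U_\text{gamble} + \kappa - \ln\!\frac{p}{1-p}\big/\mu$,
converted back to money by $V = U^{1/\alpha}$, rounded to the penny, and
clipped to $(0.01, \text{gain} - 0.01)$ — the safe amount is always
positive and below the prize. Five evenly spaced targets
(0.3–0.7 for calibration group 1, 0.1–0.9 for group 2) × 6 repeats give 30
trials per gain; each (gain, safe) cell is split equally between low and
high slots so the two conditions face *identical* offer multisets, which is
what licenses attributing any behavioral difference to the endogenous
state.

## Evoked-response statistics

Percent signal change is computed per trial relative to the mean of the
first 2 volumes at/after onset (correcting each trial's starting
baseline); trials with non-positive baselines are flagged invalid. The
per-trial evoked amplitude is the mean PSC over the closed 5.25–10.5 s
peristimulus window — at TR 1.75 s exactly the samples at 5.25, 7, 8.75,
and 10.5 s.

Condition differences in the mean time courses are tested with a
cluster-extent permutation test: pointwise paired $t$, clusters = maximal
runs with $|t| \ge 2$, null distribution = maximum cluster extent under
random per-subject sign flips of the paired differences (5000 draws by
default), $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$. A
cluster-mass statistic is available via
`cluster_test_config(statistic = "mass")`; mass is markedly more sensitive
to spatially extended moderate effects (in our calibration simulations,
power 0.98 vs 0.88 for extent at a 0.5-SD, 5-timepoint effect in 43
subjects) while both hold the nominal type-I rate.

Mediation (`multilevel_mediation()`) is a two-stage summary-statistics
scheme: per subject, path $a$ from the linear fit of mediator on predictor,
paths $b$ and $c'$ from a logistic fit of choice on mediator and predictor,
and the total path $c$ from choice on predictor alone; at the group level,
one-sample $t$ tests on the subject coefficients and a subject-level
percentile bootstrap for the indirect effect $\overline{a_i b_i}$. The
logistic outcome stage is the right likelihood for binary choice but breaks
the exact identity $c = c' + ab$; a linear variant
(`y_family = "gaussian"`) that preserves the identity exactly is provided
and tested. Exact multilevel (random-effects) mediation estimators with
nested bootstraps exist in the literature; the two-stage scheme here is the
standard transparent summary-statistics counterpart and is what the
calibration tests validate (null CI coverage ≈ 0.93 at 43 subjects).

## The synthetic-data generator

The generator defines the study conditions under which everything is
validated; its defaults are fixed once and are not tuning knobs.

* **Endogenous BOLD** — stationary AR(1) innovations (`ar_coefficient`
  0.4, innovation SD 1) plus three slow cosines (periods 100–300 s, random
  phases, amplitude 1 each) around a raw baseline of 100 a.u.; TR 1.75 s;
  2400 volumes (70 min), long enough for a 90-trial triggered session with
  margin. The baseline level exists so percent signal change is well
  defined; real scanners report signal in arbitrary positive units.
* **Evoked responses** — canonical double-gamma HRF (6-s peak, 16-s
  undershoot, ratio 1/6, unit peak) with amplitude
  $1.5 - 2(\text{percentile} - 0.5) + \varepsilon$,
  $\varepsilon \sim N(0, 0.5^2)$ per trial. The negative slope encodes the
  larger phasic response after low prestimulus activity. The magnitude is
  a choice (the source literature reports no effect sizes in signal
  units): 1.5% peak PSC with a ±1-unit condition swing is in the range
  typical of subcortical event-related responses and makes the effect
  detectable, not trivial, at 43 subjects.
* **Choice coupling** — in the full generative chain the trial-level
  gambling bias is an affine function of the trial's evoked amplitude,
  calibrated so threshold-triggered low/high trials have expected biases
  `kappa_low = 0.3`, `kappa_high = -0.1` (difference 0.4). Routing the bias
  *through* the amplitude (rather than attaching it to the condition label)
  realizes the hypothesized causal chain — prestimulus state shapes the
  phasic response, which shapes choice — so the mediation analysis faces a
  generative model in which its null is genuinely false. The trial-level
  amplitude noise is what gives the mediator information about choice over
  and above the condition label; without it path $b$ would be inestimable.
  The faster behavioral mode (`gen_cohort(mode = "behavioral")`) skips the
  imaging chain and applies condition-level biases directly.
* **Agent determinism and calibration drift** — `mu = 5` with a relative
  day-to-day drift of SD 0.2 between the calibration-day parameters (used
  to place the safe offers) and the scanner-day parameters (driving
  behavior). A perfectly calibrated agent would pin every triggered-task
  choice near its target probability, capping the achievable pseudo-$R^2$
  around 0.06–0.18 — far below observed values, which imply both strong
  value guidance and drifted indifference points (the protocol recalibrates
  on day 2 for exactly this reason). With these two values the synthetic
  cohort's fitted pseudo-$R^2$ lands near 0.42 (base) and 0.53 (bias
  model), matching the empirically reported pair.
* **Reaction times** — log-normal, $\sigma_{\log} = 0.3$, means 1.72 s
  (low) and 1.67 s (high): right-skewed like real RT distributions, with
  the faster-under-high-activity direction built in.
* **Per-subject heterogeneity** — Gaussian jitter, SD 10% of each
  parameter, truncated to the valid ranges.
* **Seeding** — every stage and subject seed derives from the master seed
  via a stable string hash (`derive_seed()`); identical configurations are
  bit-reproducible end to end.

What the generator does *not* emulate: volumetric images, motion,
cardiac/respiratory waveforms, habituation or learning across trials, and
any temporal autocorrelation in evoked amplitudes. Passing tests therefore
demonstrate the correctness and calibration of the algorithms under a
plausible generative model — not that real SN/VTA data satisfy that model.

## Validation design and problem sizes

The test suite validates each stage against independent oracles (closed
forms, brute-force summation, least-squares refits, null/power
simulations), then checks the full chain. Simulation sizes are chosen to
make Monte-Carlo error small relative to the asserted margins while keeping
a laptop-scale run: parameter recovery at n = 5000 trials (median over 5
replicate datasets, since the single-draw MLE of $\mu$ has sampling SD
≈ 0.2 at this n); model recovery over 100 cohorts of 20 subjects;
permutation-test calibration over 500 null runs at 1000 permutations and
power over 50 effect runs; mediation coverage over 200 null runs at the
study's 43 subjects; and 10 end-to-end 43-subject studies, each checked for
the five qualitative sign patterns (more risk taking, larger fitted bias,
larger evoked response after low activity; faster RTs after high activity;
negative indirect effect of prestimulus level on gambling through the
evoked response).

Two calibration facts surfaced by these simulations are worth recording.
First, the trigger-percentile tail rate on white noise is ≈ 0.074, not
0.15 (see above) — the implementation follows the protocol verbatim, and
the test asserts the correctly derived value. Second, at exactly a 0.5-SD
effect over 5 of 10 timepoints in 43 subjects, the extent-statistic cluster
test has true power ≈ 0.88 at $p < 0.01$ (the mass statistic: ≈ 0.98);
claims of ≥ 90% power for the extent statistic at this effect size are
optimistic by a small margin.

## Known limitations

* Per-condition 3-parameter fits on 45 trials are noisy; the fitted
  $\kappa$ difference retains the generated sign but not its magnitude
  (condition-wise $\alpha$ and $\mu$ partially absorb the bias within each
  condition). Group inference should use the paired difference, as the
  package does.
* The mediation estimator is two-stage (no shrinkage across subjects);
  subjects without variance in predictor, mediator, or outcome are dropped
  with a warning.
* The trigger's low/high classes are symmetric only for stationary input;
  strong drifts make forced-trial labels follow the drift, as they would
  online.
* Monetary rounding is £0.01 throughout; value-difference bins use
  objective expected values.
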