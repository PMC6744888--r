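#' Configuration for the synthetic BOLD/behavior generator
#'
#' Bundles every parameter of the seeded synthetic-data generator: the
#' endogenous BOLD process (AR(1) noise riding on slow cosine drifts around a
#' raw-signal baseline), the evoked-response model (canonical HRF responses
#' whose amplitude is coupled, negatively by default, to the prestimulus
#' activity percentile), and the behavioral agent (prospect-theory softmax
#' with a gambling bias that is larger when prestimulus activity is low, and
#' log-normal reaction times that are faster when activity is high).
#'
#' @param n_volumes Number of volumes to simulate. Default 2400, long enough
#'   for a 90-trial triggered session at the default inter-trial intervals.
#' @param tr_seconds Repetition time (volume spacing), seconds. Default 1.75.
#' @param ar_coefficient Lag-1 autoregressive coefficient of the endogenous
#'   noise, in `[0, 1)`. Default 0.4.
#' @param drift_amplitude Amplitude (signal units) of each of the three slow
#'   cosine drifts. Default 1.
#' @param noise_sd Innovation SD of the AR(1) noise, signal units. Default 1.
#' @param baseline_level Mean raw signal level the fluctuations ride on
#'   (arbitrary scanner units; needed for percent-signal-change to be well
#'   defined). Default 100.
#' @param evoked_base_amplitude Evoked-response peak amplitude (signal units)
#'   at a prestimulus percentile of 0.5. Default 1.5.
#' @param evoked_coupling_slope Change in evoked amplitude per unit change in
#'   prestimulus percentile; negative values give larger responses after low
#'   prestimulus activity. Default -2.
#' @param evoked_amplitude_sd Trial-to-trial SD of the evoked amplitude around
#'   its percentile-predicted value, signal units. Default 0.5.
#' @param kappa_low,kappa_high Gambling-bias parameter (utility units) in the
#'   low- and high-activity conditions. Defaults 0.3 and -0.1 (difference
#'   0.4).
#' @param alpha Risk-aversion exponent of the utility function. Default 0.9.
#' @param mu Softmax inverse temperature. Default 5.
#' @param param_drift_sd Relative SD of the day-to-day drift between the
#'   calibration-day parameters (used to place the safe offers) and the
#'   scanner-day parameters (used to generate behavior). Default 0.2,
#'   chosen so the fitted models' pseudo-R-squared on the triggered task
#'   matches the values observed empirically; 0 gives a perfectly
#'   calibrated agent.
#' @param rt_mean_low_s,rt_mean_high_s Mean reaction time (seconds) in the
#'   low- and high-activity conditions. Defaults 1.72 and 1.67.
#' @param rt_sdlog SD of log reaction times. Default 0.3.
#' @param seed Integer seed.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_volumes = 2400,
                             tr_seconds = 1.75,
                             ar_coefficient = 0.4,
                             drift_amplitude = 1,
                             noise_sd = 1,
                             baseline_level = 100,
                             evoked_base_amplitude = 1.5,
                             evoked_coupling_slope = -2,
                             evoked_amplitude_sd = 0.5,
                             kappa_low = 0.3,
                             kappa_high = -0.1,
                             alpha = 0.9,
                             mu = 5,
                             param_drift_sd = 0.2,
                             rt_mean_low_s = 1.72,
                             rt_mean_high_s = 1.67,
                             rt_sdlog = 0.3,
                             seed = 1L) {
  cfg <- list(n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
              ar_coefficient = ar_coefficient,
              drift_amplitude = drift_amplitude, noise_sd = noise_sd,
              baseline_level = baseline_level,
              evoked_base_amplitude = evoked_base_amplitude,
              evoked_coupling_slope = evoked_coupling_slope,
              evoked_amplitude_sd = evoked_amplitude_sd,
              kappa_low = kappa_low, kappa_high = kappa_high,
              alpha = alpha, mu = mu, param_drift_sd = param_drift_sd,
              rt_mean_low_s = rt_mean_low_s, rt_mean_high_s = rt_mean_high_s,
              rt_sdlog = rt_sdlog, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' @keywords internal
validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with(cfg, {
    if (!(n_volumes > 0)) stop("n_volumes must be positive", call. = FALSE)
    if (!(tr_seconds > 0)) stop("tr_seconds must be positive", call. = FALSE)
    if (!(ar_coefficient >= 0 && ar_coefficient < 1))
      stop("ar_coefficient must lie in [0, 1)", call. = FALSE)
    if (!(noise_sd > 0)) stop("noise_sd must be positive", call. = FALSE)
    if (!(drift_amplitude >= 0))
      stop("drift_amplitude must be non-negative", call. = FALSE)
    if (!(evoked_amplitude_sd >= 0))
      stop("evoked_amplitude_sd must be non-negative", call. = FALSE)
    if (!(rt_mean_low_s > 0 && rt_mean_high_s > 0))
      stop("reaction-time means must be positive", call. = FALSE)
    if (!(alpha > 0)) stop("alpha must be positive", call. = FALSE)
    if (!(mu > 0)) stop("mu must be positive", call. = FALSE)
    if (!(param_drift_sd >= 0))
      stop("param_drift_sd must be non-negative", call. = FALSE)
  })
  invisible(cfg)
}

#' Construct a BOLD time-series object
#'
#' A light container for a single-ROI BOLD time course: sample values, the
#' repetition time, and the acquisition time of the first sample.
#'
#' @param values Numeric vector of signal samples (finite, length >= 1).
#' @param tr_seconds Repetition time, seconds.
#' @param origin_time_s Acquisition time of `values[1]`, seconds. Default 0.
#' @return An object of class `bold_ts`.
#' @export
bold_time_series <- function(values, tr_seconds, origin_time_s = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("BOLD series must contain at least 1 sample",
                                call. = FALSE)
  if (!all(is.finite(values))) stop("BOLD series must be finite",
                                    call. = FALSE)
  if (!(tr_seconds > 0)) stop("tr_seconds must be positive", call. = FALSE)
  structure(list(values = values, tr_seconds = tr_seconds,
                 origin_time_s = origin_time_s),
            class = "bold_ts")
}

#' Sample times of a BOLD series
#' @param ts A `bold_ts` object.
#' @return Numeric vector of acquisition times in seconds.
#' @export
bold_times <- function(ts) {
  stopifnot(inherits(ts, "bold_ts"))
  ts$origin_time_s + (seq_along(ts$values) - 1) * ts$tr_seconds
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("<bold_ts> %d volumes, TR %.3g s, t0 = %.3g s\n",
              length(x$values), x$tr_seconds, x$origin_time_s))
  invisible(x)
}

#' Generate an endogenous (stimulus-free) BOLD time series
#'
#' Simulates spontaneous ROI activity as stationary AR(1) noise plus a slow
#' drift (the sum of three cosines with periods of at least 100 s and random
#' phases, mimicking scanner warming and other slow confounds) around
#' `baseline_level`. Identical configurations (including the seed) give
#' bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @return A [bold_time_series()] of length `config$n_volumes`.
#' @examples
#' ts <- gen_endogenous_bold(synthetic_config(n_volumes = 200, seed = 7))
#' length(ts$values)
#' @export
gen_endogenous_bold <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_volumes
  with_seed(config$seed, {
    innov <- stats::rnorm(n, sd = config$noise_sd)
    x <- as.numeric(stats::filter(innov, config$ar_coefficient,
                                  method = "recursive"))
    if (config$ar_coefficient > 0) {
      # stationary start: scale an extra draw to the marginal SD
      x0 <- stats::rnorm(1, sd = config$noise_sd /
                           sqrt(1 - config$ar_coefficient^2))
      x <- x + x0 * config$ar_coefficient^seq_len(n)
    }
    tt <- (seq_len(n) - 1) * config$tr_seconds
    drift <- 0
    if (config$drift_amplitude > 0) {
      periods <- stats::runif(3, 100, 300)
      phases <- stats::runif(3, 0, 2 * pi)
      for (k in 1:3)
        drift <- drift +
          config$drift_amplitude * cos(2 * pi * tt / periods[k] + phases[k])
    }
    bold_time_series(config$baseline_level + x + drift, config$tr_seconds)
  })
}

#' Add HRF-shaped evoked responses to a BOLD series
#'
#' Superimposes, at each onset, a canonical double-gamma response
#' ([canonical_hrf()]) scaled by
#' `evoked_base_amplitude + evoked_coupling_slope * (percentile - 0.5)`,
#' or by explicitly supplied amplitudes. Samples outside the response support
#' are untouched.
#'
#' @param ts A [bold_time_series()].
#' @param onsets_s Numeric vector of stimulus-onset times, seconds. Each must
#'   lie inside the series' time span.
#' @param prestim_percentiles Prestimulus activity percentiles in `[0, 1]`,
#'   one per onset. Ignored when `amplitudes` is given.
#' @param config A [synthetic_config()] carrying the coupling parameters.
#' @param amplitudes Optional explicit peak amplitudes (signal units), one per
#'   onset, overriding the percentile coupling.
#' @return A new `bold_ts` with responses added; the attribute
#'   `"amplitudes"` carries the per-onset amplitudes used.
#' @export
add_evoked_responses <- function(ts, onsets_s, prestim_percentiles = NULL,
                                 config = synthetic_config(),
                                 amplitudes = NULL) {
  stopifnot(inherits(ts, "bold_ts"))
  onsets_s <- as.numeric(onsets_s)
  if (length(onsets_s) == 0L) {
    out <- ts
    attr(out, "amplitudes") <- numeric(0)
    return(out)
  }
  tt <- bold_times(ts)
  if (any(onsets_s < tt[1] | onsets_s > tt[length(tt)]))
    stop("onset outside the BOLD series duration", call. = FALSE)
  if (is.null(amplitudes)) {
    if (is.null(prestim_percentiles) ||
        length(prestim_percentiles) != length(onsets_s))
      stop("one prestimulus percentile per onset is required", call. = FALSE)
    amplitudes <- config$evoked_base_amplitude +
      config$evoked_coupling_slope * (prestim_percentiles - 0.5)
  }
  if (length(amplitudes) != length(onsets_s))
    stop("one amplitude per onset is required", call. = FALSE)
  values <- ts$values
  for (i in seq_along(onsets_s)) {
    rel <- tt - onsets_s[i]
    idx <- which(rel >= 0 & rel <= hrf_support_s())
    values[idx] <- values[idx] + amplitudes[i] * canonical_hrf(rel[idx])
  }
  out <- bold_time_series(values, ts$tr_seconds, ts$origin_time_s)
  attr(out, "amplitudes") <- amplitudes
  out
}

#' Simulate choices and reaction times from the softmax agent
#'
#' Each choice is a Bernoulli draw with probability [p_gamble()] under the
#' given decision parameters; reaction times are log-normal with the given
#' mean and `rt_sdlog` SD on the log scale.
#'
#' @param offers Data frame of offers with columns `gain` and `safe` (pounds).
#' @param params A [decision_params()].
#' @param rt_mean_s Mean reaction time, seconds.
#' @param seed Integer seed.
#' @param rt_sdlog SD of log reaction times. Default 0.3.
#' @return A data.frame with one row per offer: `trial_index`, `gain`,
#'   `safe`, `p_gamble`, `choice` (1 = gamble, 0 = safe), `rt_s`.
#' @examples
#' offers <- data.frame(gain = 6, safe = 2.5)
#' gen_agent_choices(offers, decision_params(0.9, 3, 0), 1.7, seed = 1)
#' @export
gen_agent_choices <- function(offers, params, rt_mean_s, seed,
                              rt_sdlog = 0.3) {
  stopifnot(is.data.frame(offers), all(c("gain", "safe") %in% names(offers)),
            rt_mean_s > 0)
  p <- p_gamble(params, offers)
  with_seed(seed, {
    choice <- stats::rbinom(nrow(offers), 1L, p)
    meanlog <- log(rt_mean_s) - rt_sdlog^2 / 2
    rt <- stats::rlnorm(nrow(offers), meanlog = meanlog, sdlog = rt_sdlog)
    data.frame(trial_index = seq_len(nrow(offers)),
               gain = offers$gain, safe = offers$safe,
               p_gamble = p, choice = choice, rt_s = rt)
  })
}

# Nominal mean prestimulus percentile of threshold-triggered low/high events;
# used to map the configured condition-level gambling-bias difference onto a
# per-trial amplitude->bias slope.
nominal_percentile_low <- 0.075
nominal_percentile_high <- 0.925

#' @keywords internal
jitter_positive <- function(x, rel_sd, lower, upper) {
  y <- x * (1 + stats::rnorm(1, sd = rel_sd))
  min(max(y, lower), upper)
}

# Per-subject parameters: calibration-day (design) values jittered around the
# cohort configuration, plus scanner-day (behavioral) values drifted from
# them; the offers are placed with the design values, behavior is generated
# with the behavioral ones.
draw_subject_params <- function(config, seed_subj, jitter_sd) {
  with_seed(derive_seed(seed_subj, "params"), {
    alpha_d <- jitter_positive(config$alpha, jitter_sd, 0.2, 3)
    mu_d <- jitter_positive(config$mu, jitter_sd, 1e-3, 50)
    dr <- config$param_drift_sd
    alpha_b <- min(max(alpha_d * (1 + dr * stats::rnorm(1)), 0.2), 3)
    mu_b <- min(max(mu_d * exp(dr * stats::rnorm(1)), 1e-3), 50)
    kl <- config$kappa_low * (1 + stats::rnorm(1, sd = jitter_sd))
    kh <- config$kappa_high * (1 + stats::rnorm(1, sd = jitter_sd))
    list(alpha_design = alpha_d, mu_design = mu_d,
         alpha = alpha_b, mu = mu_b,
         kappa_low = min(max(kl, -5), 5), kappa_high = min(max(kh, -5), 5))
  })
}

#' Simulate one subject of the triggered gambling experiment
#'
#' Runs the full generative chain for a single subject: endogenous BOLD,
#' offline trigger replay to schedule low/high trials, offer assembly around
#' the subject's (jittered) indifference points, percentile-coupled evoked
#' responses, and choices whose trial-level gambling bias is driven by the
#' evoked amplitude (so that the influence of prestimulus activity on choice
#' is mediated by the phasic response, as in the generative account the
#' models target). Reaction times are condition-dependent log-normals.
#'
#' @param config A [synthetic_config()]; its `seed` field is ignored in favor
#'   of a seed derived from `master_seed` and `subject_id`.
#' @param subject_id Integer or character subject identifier.
#' @param master_seed Master integer seed of the cohort.
#' @param trigger A [trigger_config()].
#' @param design A [design_config()].
#' @param group Calibration group (1 or 2), fixing the p-target span.
#' @param n_per_condition Trials per condition to schedule. Default 45.
#' @param jitter_sd Relative SD of per-subject parameter jitter. Default 0.1.
#' @return An object of class `subject_dataset`: list with `bold` (evoked
#'   series), `bold_endogenous`, `trials` (data.frame), `events`,
#'   `true_params_low`, `true_params_high`, `subject_id`, `seed`.
#' @export
gen_subject <- function(config, subject_id, master_seed,
                        trigger = trigger_config_default(config),
                        design = design_config(),
                        group = 1L, n_per_condition = 45L,
                        jitter_sd = 0.1) {
  validate_synthetic_config(config)
  seed_subj <- derive_seed(master_seed, "subject", subject_id)

  pars <- draw_subject_params(config, seed_subj, jitter_sd)

  cfg_bold <- config
  cfg_bold$seed <- derive_seed(seed_subj, "bold")
  bold0 <- gen_endogenous_bold(cfg_bold)

  events <- run_session(bold0, trigger)
  # fill per-condition quotas in arrival order
  keep <- logical(nrow(events))
  quota <- c(low = n_per_condition, high = n_per_condition)
  for (i in seq_len(nrow(events))) {
    lab <- events$label[i]
    if (quota[[lab]] > 0L) {
      keep[i] <- TRUE
      quota[[lab]] <- quota[[lab]] - 1L
    }
  }
  ev <- events[keep, , drop = FALSE]
  if (sum(quota) > 0L)
    warning(sprintf("subject %s: only %d/%d trials scheduled before the series ended",
                    subject_id, nrow(ev), 2L * n_per_condition), call. = FALSE)

  base_params <- decision_params(pars$alpha_design, pars$mu_design, 0)
  offers <- build_realtime_trials(base_params, design, group = group,
                                  seed = derive_seed(seed_subj, "offers"))
  # assign offers to events: next unused offer of the event's condition
  trials <- assign_offers_to_events(ev, offers)

  # evoked amplitudes, coupled to the prestimulus percentile
  amp <- with_seed(derive_seed(seed_subj, "amplitudes"), {
    config$evoked_base_amplitude +
      config$evoked_coupling_slope * (trials$percentile - 0.5) +
      stats::rnorm(nrow(trials), sd = config$evoked_amplitude_sd)
  })
  bold <- add_evoked_responses(bold0, trials$onset_s, amplitudes = amp)

  # trial-level gambling bias driven by the evoked amplitude: calibrated so
  # that threshold-triggered low/high trials have expected biases
  # kappa_low/kappa_high
  d_amp <- config$evoked_coupling_slope *
    (nominal_percentile_low - nominal_percentile_high)
  if (abs(d_amp) > .Machine$double.eps) {
    k_per_amp <- (pars$kappa_low - pars$kappa_high) / d_amp
  } else {
    k_per_amp <- 0
  }
  k0 <- (pars$kappa_low + pars$kappa_high) / 2 -
    k_per_amp * config$evoked_base_amplitude
  kappa_trial <- k0 + k_per_amp * amp
  if (k_per_amp == 0)  # uncoupled evoked model: fall back to condition bias
    kappa_trial <- ifelse(trials$condition == "low",
                          pars$kappa_low, pars$kappa_high)

  uo <- utility(trials, pars$alpha)
  p <- stable_logistic(pars$mu * (uo$u_gamble - uo$u_certain + kappa_trial))
  beh <- with_seed(derive_seed(seed_subj, "choices"), {
    choice <- stats::rbinom(nrow(trials), 1L, p)
    rt_mean <- ifelse(trials$condition == "low",
                      config$rt_mean_low_s, config$rt_mean_high_s)
    meanlog <- log(rt_mean) - config$rt_sdlog^2 / 2
    rt <- stats::rlnorm(nrow(trials), meanlog = meanlog,
                        sdlog = config$rt_sdlog)
    list(choice = choice, rt = rt)
  })

  trials$amplitude_true <- amp
  trials$kappa_true <- kappa_trial
  trials$p_gamble_true <- p
  trials$choice <- beh$choice
  trials$rt_s <- beh$rt
  trials$subject_id <- subject_id
  trials <- trials[, c("subject_id", setdiff(names(trials), "subject_id"))]

  structure(list(bold = bold, bold_endogenous = bold0, trials = trials,
                 events = events,
                 true_params_low = decision_params(pars$alpha, pars$mu,
                                                   pars$kappa_low),
                 true_params_high = decision_params(pars$alpha, pars$mu,
                                                    pars$kappa_high),
                 subject_id = subject_id, seed = seed_subj),
            class = "subject_dataset")
}

#' @keywords internal
assign_offers_to_events <- function(ev, offers) {
  pool <- split(offers, offers$condition_slot)
  used <- list(low = 0L, high = 0L)
  rows <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    lab <- ev$label[i]
    k <- used[[lab]] + 1L
    if (k > nrow(pool[[lab]]))
      stop("more events than offers in condition ", lab, call. = FALSE)
    used[[lab]] <- k
    off <- pool[[lab]][k, ]
    rows[[i]] <- data.frame(trial_index = i,
                            onset_s = ev$time_s[i],
                            volume_index = ev$volume_index[i],
                            condition = lab, forced = ev$forced[i],
                            percentile = ev$percentile[i],
                            gain = off$gain, safe = off$safe,
                            p_target = off$p_target)
  }
  do.call(rbind, rows)
}

#' Simulate a cohort of subjects
#'
#' In `"full"` mode each subject goes through the entire generative chain of
#' [gen_subject()] (endogenous BOLD, trigger replay, evoked coupling,
#' amplitude-mediated choices). In `"behavioral"` mode the imaging stages are
#' skipped: trials are labelled low/high directly (with nominal prestimulus
#' percentiles) and choices are drawn from the condition-level gambling
#' biases, which is much faster and sufficient for behavioral power and
#' recovery simulations.
#'
#' @param n_subjects Number of subjects. Default 43.
#' @param config A [synthetic_config()]; `config$seed` is the master seed.
#' @param mode `"full"` or `"behavioral"`.
#' @param group Calibration group (1 or 2). Default 1.
#' @param n_per_condition Trials per condition. Default 45.
#' @param trigger,design Module configurations ([trigger_config()],
#'   [design_config()]).
#' @return A list of `subject_dataset` objects (class `cohort`).
#' @export
gen_cohort <- function(n_subjects = 43L, config = synthetic_config(),
                       mode = c("full", "behavioral"), group = 1L,
                       n_per_condition = 45L,
                       trigger = trigger_config_default(config),
                       design = design_config()) {
  mode <- match.arg(mode)
  validate_synthetic_config(config)
  n_subjects <- as.integer(n_subjects)
  stopifnot(n_subjects >= 0L)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    out[[s]] <- if (mode == "full") {
      gen_subject(config, s, config$seed, trigger, design,
                  group = group, n_per_condition = n_per_condition)
    } else {
      gen_subject_behavioral(config, s, config$seed, design,
                             group = group,
                             n_per_condition = n_per_condition)
    }
  }
  class(out) <- "cohort"
  out
}

#' @keywords internal
gen_subject_behavioral <- function(config, subject_id, master_seed,
                                   design = design_config(),
                                   group = 1L, n_per_condition = 45L) {
  seed_subj <- derive_seed(master_seed, "subject", subject_id)
  pars <- draw_subject_params(config, seed_subj, 0.1)
  base_params <- decision_params(pars$alpha_design, pars$mu_design, 0)
  offers <- build_realtime_trials(base_params, design, group = group,
                                  seed = derive_seed(seed_subj, "offers"))
  # trim/extend the 90-offer template to the requested quota per condition
  offers <- do.call(rbind, lapply(split(offers, offers$condition_slot),
                                  function(d) {
    idx <- rep_len(seq_len(nrow(d)), n_per_condition)
    d[idx, , drop = FALSE]
  }))
  offers <- offers[order(with_seed(derive_seed(seed_subj, "order"),
                                   stats::runif(nrow(offers)))), ]
  pct <- with_seed(derive_seed(seed_subj, "percentiles"),
                   ifelse(offers$condition_slot == "low",
                          stats::runif(nrow(offers), 0, 0.15),
                          stats::runif(nrow(offers), 0.85, 1)))
  kappa_trial <- ifelse(offers$condition_slot == "low",
                        pars$kappa_low, pars$kappa_high)
  uo <- utility(offers, pars$alpha)
  p <- stable_logistic(pars$mu * (uo$u_gamble - uo$u_certain + kappa_trial))
  beh <- with_seed(derive_seed(seed_subj, "choices"), {
    choice <- stats::rbinom(nrow(offers), 1L, p)
    rt_mean <- ifelse(offers$condition_slot == "low",
                      config$rt_mean_low_s, config$rt_mean_high_s)
    meanlog <- log(rt_mean) - config$rt_sdlog^2 / 2
    rt <- stats::rlnorm(nrow(offers), meanlog = meanlog,
                        sdlog = config$rt_sdlog)
    list(choice = choice, rt = rt)
  })
  n <- nrow(offers)
  trials <- data.frame(subject_id = subject_id, trial_index = seq_len(n),
                       onset_s = 30 * seq_len(n), volume_index = NA_integer_,
                       condition = offers$condition_slot, forced = FALSE,
                       percentile = pct,
                       gain = offers$gain, safe = offers$safe,
                       p_target = offers$p_target,
                       amplitude_true = NA_real_, kappa_true = kappa_trial,
                       p_gamble_true = p, choice = beh$choice,
                       rt_s = beh$rt)
  structure(list(bold = NULL, bold_endogenous = NULL, trials = trials,
                 events = NULL,
                 true_params_low = decision_params(pars$alpha, pars$mu,
                                                   pars$kappa_low),
                 true_params_high = decision_params(pars$alpha, pars$mu,
                                                    pars$kappa_high),
                 subject_id = subject_id, seed = seed_subj),
            class = "subject_dataset")
}

#' Bind a cohort's trials into one data.frame
#' @param cohort A list of `subject_dataset` objects.
#' @return A data.frame of all trials.
#' @export
cohort_trials <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) s$trials))
}
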