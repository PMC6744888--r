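#' Decision parameters of the prospect-theory softmax model
#'
#' @param alpha Risk-aversion exponent (> 0; < 1 risk-averse, 1 risk-neutral,
#'   > 1 risk-seeking).
#' @param mu Softmax inverse temperature (> 0).
#' @param kappa Additive gambling bias in utility units (0 in the base
#'   model; positive values shift choice toward the gamble irrespective of
#'   value).
#' @return An object of class `decision_params`.
#' @examples
#' decision_params(0.9, 3, 0.2)
#' @export
decision_params <- function(alpha, mu, kappa = 0) {
  if (!(alpha > 0)) stop("alpha must be positive", call. = FALSE)
  if (!(mu > 0)) stop("mu must be positive", call. = FALSE)
  structure(list(alpha = alpha, mu = mu, kappa = kappa),
            class = "decision_params")
}

#' @export
print.decision_params <- function(x, ...) {
  cat(sprintf("<decision_params> alpha = %.4g, mu = %.4g, kappa = %.4g\n",
              x$alpha, x$mu, x$kappa))
  invisible(x)
}

#' Expected utilities of a gamble and its certain alternative
#'
#' `u_gamble = 0.5 * gain^alpha` (the gamble pays `gain` or 0 with equal
#' probability) and `u_certain = safe^alpha`.
#'
#' @param offer Data frame (or list) with elements `gain` and `safe`, pounds.
#' @param alpha Risk-aversion exponent.
#' @return List with numeric vectors `u_gamble` and `u_certain`.
#' @examples
#' utility(data.frame(gain = 6, safe = 4), alpha = 0.5)
#' @export
utility <- function(offer, alpha) {
  list(u_gamble = 0.5 * offer$gain^alpha, u_certain = offer$safe^alpha)
}

# logistic clamped to a machine-open (0, 1): extreme arguments neither
# overflow nor produce log(0) downstream
stable_logistic <- function(x) {
  p <- stats::plogis(x)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Probability of choosing the gamble
#'
#' Softmax choice rule
#' `P = 1 / (1 + exp(-mu * (u_gamble - u_certain + kappa)))`, evaluated
#' stably and clamped to the open unit interval.
#'
#' @param params A [decision_params()].
#' @param offer Data frame with columns `gain` and `safe` (one row per
#'   offer).
#' @return Numeric vector of gamble probabilities.
#' @examples
#' p_gamble(decision_params(1, 1, 0), data.frame(gain = 6, safe = 3))  # 0.5
#' @export
p_gamble <- function(params, offer) {
  stopifnot(inherits(params, "decision_params"))
  u <- utility(offer, params$alpha)
  stable_logistic(params$mu * (u$u_gamble - u$u_certain + params$kappa))
}

#' Model specifications for the choice-model registry
#'
#' Returns the specification of one of the registered decision models:
#' \describe{
#'   \item{`pt`}{Base prospect-theory model; free `alpha`, `mu`; `kappa`
#'     fixed at 0.}
#'   \item{`pt_kappa`}{Adds the additive gambling bias `kappa` as a free
#'     parameter; with `kappa = 0` it is likelihood-identical to `pt`.}
#'   \item{`pt_kappa_cond`}{Shared `alpha` and `mu` with separate gambling
#'     biases `kappa_low`/`kappa_high` for the two activity conditions
#'     (requires a `condition` column in the trials); the state-dependent
#'     bias account of choice, nested above both `pt` and `pt_kappa`.}
#'   \item{`pt_mult`}{Non-canonical comparison model: a multiplicative bias
#'     `beta_g` on the gamble's utility,
#'     `P = logistic(mu * (beta_g * u_gamble - u_certain))`.}
#'   \item{`pt_dual_alpha`}{Non-canonical comparison model: separate
#'     curvature below/above a £9 reference prize.}
#' }
#' The two non-canonical models exist to exercise the model-comparison
#' machinery; they are not fitted by default.
#'
#' @param name One of `"pt"`, `"pt_kappa"`, `"pt_kappa_cond"`, `"pt_mult"`,
#'   `"pt_dual_alpha"`.
#' @return An object of class `model_spec`: list with `name`, `par_names`,
#'   `lower`, `upper`, `start`, `fixed`, and `prob_fun(par, offers)`.
#' @export
model_spec <- function(name = c("pt", "pt_kappa", "pt_kappa_cond", "pt_mult",
                                "pt_dual_alpha")) {
  name <- match.arg(name)
  spec <- switch(name,
    pt = list(
      par_names = c("alpha", "mu"),
      lower = c(alpha = 0.01, mu = 1e-3),
      upper = c(alpha = 3, mu = 50),
      start = c(alpha = 1, mu = 1),
      fixed = c(kappa = 0),
      prob_fun = function(par, offers) {
        u <- utility(offers, par[["alpha"]])
        stable_logistic(par[["mu"]] * (u$u_gamble - u$u_certain))
      }),
    pt_kappa = list(
      par_names = c("alpha", "mu", "kappa"),
      lower = c(alpha = 0.01, mu = 1e-3, kappa = -5),
      upper = c(alpha = 3, mu = 50, kappa = 5),
      start = c(alpha = 1, mu = 1, kappa = 0),
      fixed = numeric(0),
      prob_fun = function(par, offers) {
        u <- utility(offers, par[["alpha"]])
        stable_logistic(par[["mu"]] *
                          (u$u_gamble - u$u_certain + par[["kappa"]]))
      }),
    pt_kappa_cond = list(
      par_names = c("alpha", "mu", "kappa_low", "kappa_high"),
      lower = c(alpha = 0.01, mu = 1e-3, kappa_low = -5, kappa_high = -5),
      upper = c(alpha = 3, mu = 50, kappa_low = 5, kappa_high = 5),
      start = c(alpha = 1, mu = 1, kappa_low = 0, kappa_high = 0),
      fixed = numeric(0),
      prob_fun = function(par, offers) {
        if (is.null(offers$condition))
          stop("model 'pt_kappa_cond' needs a condition column",
               call. = FALSE)
        u <- utility(offers, par[["alpha"]])
        k <- ifelse(offers$condition == "low", par[["kappa_low"]],
                    par[["kappa_high"]])
        stable_logistic(par[["mu"]] * (u$u_gamble - u$u_certain + k))
      }),
    pt_mult = list(
      par_names = c("alpha", "mu", "beta_g"),
      lower = c(alpha = 0.01, mu = 1e-3, beta_g = 0.25),
      upper = c(alpha = 3, mu = 50, beta_g = 4),
      start = c(alpha = 1, mu = 1, beta_g = 1),
      fixed = numeric(0),
      prob_fun = function(par, offers) {
        u <- utility(offers, par[["alpha"]])
        stable_logistic(par[["mu"]] *
                          (par[["beta_g"]] * u$u_gamble - u$u_certain))
      }),
    pt_dual_alpha = list(
      par_names = c("alpha_lo", "alpha_hi", "mu"),
      lower = c(alpha_lo = 0.01, alpha_hi = 0.01, mu = 1e-3),
      upper = c(alpha_lo = 3, alpha_hi = 3, mu = 50),
      start = c(alpha_lo = 1, alpha_hi = 1, mu = 1),
      fixed = numeric(0),
      prob_fun = function(par, offers) {
        a <- ifelse(offers$gain < 9, par[["alpha_lo"]], par[["alpha_hi"]])
        u_g <- 0.5 * offers$gain^a
        u_c <- offers$safe^a
        stable_logistic(par[["mu"]] * (u_g - u_c))
      }))
  spec$name <- name
  class(spec) <- "model_spec"
  spec
}

#' Negative log-likelihood of observed choices
#'
#' Bernoulli likelihood of the observed gamble/safe choices under the model:
#' `-sum(log P(observed choice))`. Trials with a missing choice (missed
#' responses) are excluded.
#'
#' @param params A [decision_params()] or a named numeric vector matching
#'   `spec$par_names`.
#' @param trials Data frame with columns `gain`, `safe`, `choice`
#'   (1 = gamble, 0 = safe, `NA` = missed).
#' @param spec A [model_spec()]. Default `"pt_kappa"`.
#' @return Negative log-likelihood in nats.
#' @export
neg_log_likelihood <- function(params, trials,
                               spec = model_spec("pt_kappa")) {
  par <- params_to_vector(params, spec)
  tr <- trials[!is.na(trials$choice), , drop = FALSE]
  if (nrow(tr) == 0L) return(0)
  p <- spec$prob_fun(par, tr)
  -sum(ifelse(tr$choice == 1L, log(p), log1p(-p)))
}

params_to_vector <- function(params, spec) {
  if (inherits(params, "decision_params")) {
    full <- c(alpha = params$alpha, mu = params$mu, kappa = params$kappa)
    if (!all(spec$par_names %in% names(full)))
      stop("decision_params cannot parameterize model '", spec$name, "'",
           call. = FALSE)
    return(full[spec$par_names])
  }
  par <- as.numeric(params)
  names(par) <- names(params)
  if (!all(spec$par_names %in% names(par)))
    stop("params must provide ", paste(spec$par_names, collapse = ", "),
         call. = FALSE)
  par[spec$par_names]
}

#' Maximum-likelihood fit of a decision model
#'
#' Bounded multi-start optimization of the Bernoulli likelihood: one start at
#' the model's canonical starting point plus `n_starts - 1` Latin-hypercube
#' points across the parameter box, each refined with `L-BFGS-B`. The best
#' solution is returned. Deterministic given the seed.
#'
#' @param trials Data frame with columns `gain`, `safe`, `choice`.
#' @param spec A [model_spec()]. Default `"pt_kappa"`.
#' @param n_starts Number of starting points. Default 20.
#' @param seed Integer seed for the start-point design.
#' @return An object of class `fit_result`: list with `params` (named
#'   vector), `decision_params` (for the canonical models), `log_likelihood`,
#'   `n_trials`, `pseudo_r2`, `bic`, `n_starts_converged`, `model`.
#' @examples
#' off <- build_calibration_trials(design_config(), seed = 1)
#' tr <- gen_agent_choices(off, decision_params(0.9, 3, 0), 1.7, seed = 2)
#' fit_mle(tr, model_spec("pt"), n_starts = 5, seed = 3)$params
#' @export
fit_mle <- function(trials, spec = model_spec("pt_kappa"), n_starts = 20L,
                    seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  tr <- trials[!is.na(trials$choice), , drop = FALSE]
  if (nrow(tr) == 0L) stop("no usable trials to fit", call. = FALSE)
  k <- length(spec$par_names)
  # lightweight copies: the objective is evaluated thousands of times under
  # numerical differentiation, so avoid data.frame dispatch in the hot path
  off <- list(gain = tr$gain, safe = tr$safe, condition = tr$condition)
  gambled <- tr$choice == 1L
  nll <- function(par) {
    names(par) <- spec$par_names
    p <- spec$prob_fun(par, off)
    -sum(log(ifelse(gambled, p, 1 - p)))
  }
  starts <- matrix(spec$start, nrow = 1)
  if (n_starts > 1L) {
    u <- with_seed(seed, lhs_design(n_starts - 1L, k))
    box <- sweep(sweep(u, 2, spec$upper - spec$lower, `*`), 2, spec$lower,
                 `+`)
    starts <- rbind(starts, box)
  }
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                   lower = spec$lower, upper = spec$upper,
                   control = list(factr = 1e6, maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all optimizer starts failed for model '", spec$name, "'",
         call. = FALSE)
  par <- best$par
  names(par) <- spec$par_names
  ll <- -best$value
  n <- nrow(tr)
  dp <- NULL
  if (spec$name %in% c("pt", "pt_kappa")) {
    kap <- if ("kappa" %in% names(par)) par[["kappa"]] else 0
    dp <- decision_params(par[["alpha"]], par[["mu"]], kap)
  }
  structure(list(params = par, decision_params = dp, log_likelihood = ll,
                 n_trials = n,
                 pseudo_r2 = 1 - ll / (n * log(0.5)),
                 bic = k * log(n) - 2 * ll,
                 n_free = k, n_starts_converged = n_conv,
                 model = spec$name),
            class = "fit_result")
}

# Latin hypercube in [0,1]^k via the lhs package when present, else a plain
# stratified permutation design with identical marginal structure
lhs_design <- function(n, k) {
  if (requireNamespace("lhs", quietly = TRUE))
    return(lhs::randomLHS(n, k))
  sapply(seq_len(k), function(j) (sample.int(n) - stats::runif(n)) / n)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model %s: LL = %.3f, n = %d, pseudo-R2 = %.3f, BIC = %.2f\n",
              x$model, x$log_likelihood, x$n_trials, x$pseudo_r2, x$bic))
  print(round(x$params, 4))
  invisible(x)
}

#' McFadden-style pseudo-R-squared against a coin-flip null
#'
#' `1 - LL_model / LL_chance` with `LL_chance = n * log(0.5)`.
#'
#' @param fit A `fit_result`, or a log-likelihood (then `n` is required).
#' @param n Number of trials when `fit` is a bare log-likelihood.
#' @return Pseudo-R-squared (at most 1; 0 for a chance-level model).
#' @export
pseudo_r2 <- function(fit, n = NULL) {
  if (inherits(fit, "fit_result")) {
    ll <- fit$log_likelihood
    n <- fit$n_trials
  } else {
    ll <- fit
    if (is.null(n)) stop("n is required when fit is a log-likelihood",
                         call. = FALSE)
  }
  1 - ll / (n * log(0.5))
}

#' Bayesian information criterion of a fit
#'
#' `k * log(n) - 2 * LL` for `k` free parameters.
#'
#' @param fit A `fit_result`, or a log-likelihood (then `k` and `n` are
#'   required).
#' @param k,n Free-parameter count and trial count when `fit` is a bare
#'   log-likelihood.
#' @return BIC in nats.
#' @export
bic <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "fit_result")) return(fit$bic)
  if (is.null(k) || is.null(n))
    stop("k and n are required when fit is a log-likelihood", call. = FALSE)
  k * log(n) - 2 * fit
}

#' Fit the full model separately in the low- and high-activity conditions
#'
#' Independent fits (all parameters free in each condition) on the subsets of
#' trials labelled `"low"` and `"high"`, plus the paired parameter
#' differences used by the group tests.
#'
#' @param trials Data frame with columns `gain`, `safe`, `choice`,
#'   `condition`.
#' @param spec A [model_spec()]. Default `"pt_kappa"`.
#' @param n_starts,seed Passed to [fit_mle()].
#' @return List with elements `low`, `high` (both `fit_result`) and `diff`
#'   (named vector of low-minus-high parameter differences).
#' @export
fit_by_condition <- function(trials, spec = model_spec("pt_kappa"),
                             n_starts = 20L, seed = 1L) {
  stopifnot("condition" %in% names(trials))
  f_lo <- fit_mle(trials[trials$condition == "low", , drop = FALSE], spec,
                  n_starts = n_starts, seed = derive_seed(seed, "low"))
  f_hi <- fit_mle(trials[trials$condition == "high", , drop = FALSE], spec,
                  n_starts = n_starts, seed = derive_seed(seed, "high"))
  list(low = f_lo, high = f_hi, diff = f_lo$params - f_hi$params)
}

#' Group-level BIC model comparison
#'
#' Fits each candidate model to every subject's trials and compares the
#' models by total (summed) BIC.
#'
#' @param trials Data frame with a `subject_id` column plus the columns
#'   required by [fit_mle()].
#' @param models Character vector of model names from the registry.
#' @param n_starts,seed Passed to [fit_mle()].
#' @return List with `per_subject` (data.frame of subject x model BIC),
#'   `total_bic` (named vector), and `best` (name of the winning model).
#' @export
compare_models_bic <- function(trials, models = c("pt", "pt_kappa"),
                               n_starts = 10L, seed = 1L) {
  specs <- lapply(models, model_spec)
  subjects <- unique(trials$subject_id)
  rows <- list()
  for (s in subjects) {
    tr_s <- trials[trials$subject_id == s, , drop = FALSE]
    for (sp in specs) {
      fit <- fit_mle(tr_s, sp, n_starts = n_starts,
                     seed = derive_seed(seed, "cmp", s, sp$name))
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = s, model = sp$name, bic = fit$bic,
                   log_likelihood = fit$log_likelihood,
                   pseudo_r2 = fit$pseudo_r2)
    }
  }
  per <- do.call(rbind, rows)
  tot <- tapply(per$bic, per$model, sum)
  tot <- tot[models]  # stable order
  list(per_subject = per, total_bic = tot,
       best = models[which.min(tot)])
}
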