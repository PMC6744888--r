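#' Configuration of the real-time activity trigger
#'
#' Parameters of the sliding-window scheduler that classifies each new volume
#' as reflecting low or high endogenous activity and decides when to present
#' a trial. Defaults follow the real-time protocol the package models: the
#' mean of the most recent 2 volumes is ranked, via a normal CDF, against the
#' 69 volumes that precede them; trials trigger below the 15th or above the
#' 85th percentile, with a 20-s minimum inter-trial interval and a 55-s
#' timeout after which a trial is forced and labelled by its sign relative to
#' the window mean.
#'
#' @param window_volumes Size of the reference window, volumes. Default 69.
#' @param recent_volumes Number of most recent volumes averaged into the test
#'   statistic. Default 2.
#' @param low_threshold,high_threshold Percentile cutoffs (fractions) for
#'   low/high triggering. Defaults 0.15 and 0.85.
#' @param min_iti_s Minimum inter-trial interval, seconds. Default 20.
#' @param timeout_s Time after which a trial is forced, seconds. Default 55.
#' @param tr_seconds Repetition time, seconds. Default 1.75.
#' @return An object of class `trigger_config`.
#' @export
trigger_config <- function(window_volumes = 69L, recent_volumes = 2L,
                           low_threshold = 0.15, high_threshold = 0.85,
                           min_iti_s = 20, timeout_s = 55,
                           tr_seconds = 1.75) {
  cfg <- list(window_volumes = as.integer(window_volumes),
              recent_volumes = as.integer(recent_volumes),
              low_threshold = low_threshold, high_threshold = high_threshold,
              min_iti_s = min_iti_s, timeout_s = timeout_s,
              tr_seconds = tr_seconds)
  if (!(cfg$low_threshold > 0 && cfg$low_threshold < cfg$high_threshold &&
        cfg$high_threshold < 1))
    stop("need 0 < low_threshold < high_threshold < 1", call. = FALSE)
  if (cfg$recent_volumes < 1L) stop("recent_volumes must be >= 1",
                                    call. = FALSE)
  if (cfg$window_volumes <= cfg$recent_volumes)
    stop("window_volumes must exceed recent_volumes", call. = FALSE)
  if (!(cfg$min_iti_s < cfg$timeout_s))
    stop("min_iti_s must be smaller than timeout_s", call. = FALSE)
  if (!(cfg$tr_seconds > 0)) stop("tr_seconds must be positive",
                                  call. = FALSE)
  class(cfg) <- "trigger_config"
  cfg
}

#' Trigger configuration matched to a synthetic configuration's TR
#' @param config A [synthetic_config()].
#' @param ... Overrides passed to [trigger_config()].
#' @return A `trigger_config`.
#' @export
trigger_config_default <- function(config, ...) {
  trigger_config(tr_seconds = config$tr_seconds, ...)
}

#' Create an empty sliding-window state
#'
#' @param config A [trigger_config()].
#' @return An object of class `window_state` holding an empty buffer of
#'   capacity `window_volumes + recent_volumes`.
#' @export
new_window_state <- function(config) {
  structure(list(buffer = numeric(0), volumes_seen = 0L,
                 last_trial_volume = NA_integer_),
            class = "window_state")
}

# mean of the recent volumes, mean/SD of the reference window preceding
# them, and the normal-CDF percentile; x must hold >= w + r samples
window_stats <- function(x, w, r) {
  n <- length(x)
  recent <- x[(n - r + 1L):n]
  win <- x[(n - r - w + 1L):(n - r)]
  m <- sum(recent) / r
  mu <- sum(win) / w
  s2 <- sum((win - mu)^2) / (w - 1L)
  pct <- if (s2 <= 0) 0.5 else stats::pnorm((m - mu) / sqrt(s2))
  list(m = m, mu = mu, sd = sqrt(s2), percentile = pct)
}

#' Percentile of the most recent activity within the sliding window
#'
#' Ranks the mean of the `recent_volumes` newest samples against the
#' `window_volumes` samples immediately preceding them, using a normal CDF:
#' `pnorm((m - mean_w) / sd_w)`. A zero-variance window returns 0.5. Before
#' warm-up (fewer than `window_volumes + recent_volumes` samples seen) the
#' percentile is undefined and `NA` is returned.
#'
#' @param state A [new_window_state()] that has absorbed samples via
#'   [trigger_step()].
#' @param config A [trigger_config()].
#' @return Percentile in `(0, 1)`, or `NA_real_` during warm-up.
#' @export
percentile_of_recent <- function(state, config) {
  need <- config$window_volumes + config$recent_volumes
  if (state$volumes_seen < need) return(NA_real_)
  window_stats(state$buffer, config$window_volumes,
               config$recent_volumes)$percentile
}

#' Advance the trigger by one volume
#'
#' Appends `new_value` to the sliding window and applies the trigger rule:
#' during warm-up or within `min_iti_s` of the previous trial no event fires;
#' otherwise a percentile at or below `low_threshold` fires a low event, at
#' or above `high_threshold` a high event; failing both, once
#' `elapsed_since_last_trial_s >= timeout_s` a forced event fires, labelled
#' low when the recent mean is below the window mean and high otherwise.
#'
#' @param state A `window_state`.
#' @param new_value New BOLD sample (signal units).
#' @param config A [trigger_config()].
#' @param elapsed_since_last_trial_s Time since the previous trial (or since
#'   triggering became possible), seconds.
#' @param volume_index 0-based index of the incoming volume (bookkeeping for
#'   the emitted event; defaults to `volumes_seen`).
#' @return A list with elements `state` (updated) and `event` (a one-row
#'   data.frame with columns `volume_index`, `time_s`, `label`, `forced`,
#'   `percentile`, or `NULL` when no trial fires).
#' @export
trigger_step <- function(state, new_value, config,
                         elapsed_since_last_trial_s,
                         volume_index = state$volumes_seen) {
  stopifnot(inherits(state, "window_state"), is.finite(new_value))
  cap <- config$window_volumes + config$recent_volumes
  buf <- c(state$buffer, new_value)
  if (length(buf) > cap) buf <- buf[(length(buf) - cap + 1L):length(buf)]
  state$buffer <- buf
  state$volumes_seen <- state$volumes_seen + 1L

  if (state$volumes_seen < cap)
    return(list(state = state, event = NULL))
  st <- window_stats(buf, config$window_volumes, config$recent_volumes)
  if (elapsed_since_last_trial_s < config$min_iti_s)
    return(list(state = state, event = NULL))

  label <- NULL
  forced <- FALSE
  if (st$percentile <= config$low_threshold) {
    label <- "low"
  } else if (st$percentile >= config$high_threshold) {
    label <- "high"
  } else if (elapsed_since_last_trial_s >= config$timeout_s) {
    label <- if (st$m < st$mu) "low" else "high"
    forced <- TRUE
  }
  if (is.null(label))
    return(list(state = state, event = NULL))
  state$last_trial_volume <- as.integer(volume_index)
  event <- data.frame(volume_index = as.integer(volume_index),
                      time_s = volume_index * config$tr_seconds,
                      label = label, forced = forced,
                      percentile = st$percentile)
  list(state = state, event = event)
}

#' Replay the online trigger over a recorded BOLD series
#'
#' Deterministic offline replay of [trigger_step()] over every volume of a
#' series, evaluating the rule at each new volume. The inter-trial clock is
#' anchored at the end of warm-up for the first trial and at the preceding
#' trial thereafter.
#'
#' @param bold A [bold_time_series()].
#' @param config A [trigger_config()].
#' @return A data.frame of trigger events (possibly 0 rows) with columns
#'   `volume_index`, `time_s`, `label`, `forced`, `percentile`.
#' @examples
#' ts <- gen_endogenous_bold(synthetic_config(n_volumes = 400, seed = 2))
#' ev <- run_session(ts, trigger_config())
#' all(diff(ev$time_s) >= 20)
#' @export
run_session <- function(bold, config) {
  stopifnot(inherits(bold, "bold_ts"), inherits(config, "trigger_config"))
  x <- bold$values
  n <- length(x)
  w <- config$window_volumes
  r <- config$recent_volumes
  cap <- w + r
  if (n < cap)
    return(empty_events())
  tr <- config$tr_seconds
  warmup_time <- (cap - 1L) * tr
  last_time <- warmup_time
  events <- list()
  for (i in cap:n) {
    t_i <- (i - 1L) * tr
    elapsed <- t_i - last_time
    if (elapsed < config$min_iti_s) next
    st <- window_stats(x[(i - cap + 1L):i], w, r)
    label <- NULL
    forced <- FALSE
    if (st$percentile <= config$low_threshold) {
      label <- "low"
    } else if (st$percentile >= config$high_threshold) {
      label <- "high"
    } else if (elapsed >= config$timeout_s) {
      label <- if (st$m < st$mu) "low" else "high"
      forced <- TRUE
    }
    if (is.null(label)) next
    events[[length(events) + 1L]] <-
      data.frame(volume_index = i - 1L, time_s = t_i, label = label,
                 forced = forced, percentile = st$percentile)
    last_time <- t_i
  }
  if (length(events) == 0L) return(empty_events())
  do.call(rbind, events)
}

empty_events <- function() {
  data.frame(volume_index = integer(0), time_s = numeric(0),
             label = character(0), forced = logical(0),
             percentile = numeric(0))
}

#' Create the state of the incremental (expanding-window) nuisance regression
#'
#' @param n_regressors Number of nuisance regressors (an intercept is always
#'   added internally).
#' @return An object of class `nuisance_state` accumulating the normal
#'   equations of the expanding least-squares fit.
#' @export
new_nuisance_state <- function(n_regressors) {
  p <- as.integer(n_regressors) + 1L
  structure(list(XtX = matrix(0, p, p), Xty = numeric(p), n = 0L,
                 n_regressors = as.integer(n_regressors),
                 rank_deficient = FALSE),
            class = "nuisance_state")
}

#' One step of the online nuisance regression
#'
#' Updates an expanding-window least-squares fit of the signal on the
#' nuisance regressors (plus intercept) with one new sample and returns the
#' residual of that sample under the current coefficient estimates. After a
#' full series has been processed the coefficients equal the batch
#' least-squares solution on the same data. Collinear regressors are handled
#' with a minimum-norm (pseudoinverse) solution and flagged.
#'
#' @param state A [new_nuisance_state()].
#' @param y_value New signal sample.
#' @param x_values Numeric vector of the nuisance-regressor samples at this
#'   time point (length `n_regressors`; may be length 0 for intercept-only).
#' @return A list with `state` (updated), `residual` (numeric), `coef`
#'   (current coefficient vector, intercept first), and `rank_deficient`
#'   (logical flag).
#' @export
incremental_nuisance_regress <- function(state, y_value, x_values = numeric(0)) {
  stopifnot(inherits(state, "nuisance_state"),
            length(x_values) == state$n_regressors)
  z <- c(1, as.numeric(x_values))
  state$XtX <- state$XtX + tcrossprod(z)
  state$Xty <- state$Xty + z * y_value
  state$n <- state$n + 1L
  p <- length(z)
  full_rank <- qr(state$XtX)$rank == p
  if (full_rank) {
    beta <- solve(state$XtX, state$Xty)
  } else {
    beta <- as.numeric(MASS::ginv(state$XtX) %*% state$Xty)
    # an underdetermined system during warm-up (n < p) is expected; only a
    # persistent deficiency with enough samples marks collinear regressors
    if (state$n >= p) state$rank_deficient <- TRUE
  }
  list(state = state, residual = y_value - sum(z * beta), coef = beta,
       rank_deficient = state$rank_deficient)
}

#' Denoise a full series with the online nuisance regression
#'
#' Convenience wrapper running [incremental_nuisance_regress()] over every
#' sample of a series.
#'
#' @param y Numeric signal vector.
#' @param X Numeric matrix of nuisance regressors (rows = samples), or `NULL`
#'   for intercept-only.
#' @return A list with `residuals` (same length as `y`), `coef` (final
#'   coefficients, intercept first), and `rank_deficient`.
#' @export
nuisance_regress_series <- function(y, X = NULL) {
  n <- length(y)
  k <- if (is.null(X)) 0L else ncol(X)
  if (!is.null(X)) stopifnot(nrow(X) == n)
  state <- new_nuisance_state(k)
  res <- numeric(n)
  out <- NULL
  for (i in seq_len(n)) {
    xi <- if (k > 0L) X[i, ] else numeric(0)
    out <- incremental_nuisance_regress(state, y[i], xi)
    state <- out$state
    res[i] <- out$residual
  }
  list(residuals = res, coef = out$coef,
       rank_deficient = out$rank_deficient)
}
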