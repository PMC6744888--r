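#' Configuration of the gambling-task design
#'
#' Parameters of the two-stage task design: a calibration task whose safe
#' amounts are the gambles' expected values divided by a fixed ladder of 12
#' divisors, and a triggered (real-time) task whose safe amounts are placed
#' at target gamble probabilities by inverting each subject's fitted decision
#' model.
#'
#' @param gains Gamble prize magnitudes in pounds. Default `c(6, 9, 12)`
#'   (each gamble pays the prize or 0 with equal probability).
#' @param divisors Ladder of divisors applied to the gambles' expected
#'   values on the calibration task.
#' @param day1_repeats,day2_repeats Repeats of each (gain, divisor) cell in
#'   the long and short calibration tasks. Defaults 5 and 3.
#' @param p_bins_group1,p_bins_group2 Target gamble probabilities for the
#'   triggered task, by calibration group. Defaults: 5 evenly spaced values
#'   in `[0.3, 0.7]` (group 1) and in `[0.1, 0.9]` (group 2).
#' @param trials_per_gain_rt Triggered-task trials per gain. Default 30.
#' @param per_condition_rt Triggered-task trials per gain and condition.
#'   Default 15.
#' @return An object of class `design_config`.
#' @export
design_config <- function(gains = c(6, 9, 12),
                          divisors = c(0.82, 0.87, 0.93, 1, 1.1, 1.23, 1.4,
                                       1.6, 1.9, 2.25, 2.75, 3.5),
                          day1_repeats = 5L, day2_repeats = 3L,
                          p_bins_group1 = seq(0.3, 0.7, length.out = 5),
                          p_bins_group2 = seq(0.1, 0.9, length.out = 5),
                          trials_per_gain_rt = 30L, per_condition_rt = 15L) {
  stopifnot(all(divisors > 0), all(gains > 0),
            all(p_bins_group1 > 0 & p_bins_group1 < 1),
            all(p_bins_group2 > 0 & p_bins_group2 < 1))
  structure(list(gains = gains, divisors = divisors,
                 day1_repeats = as.integer(day1_repeats),
                 day2_repeats = as.integer(day2_repeats),
                 p_bins_group1 = p_bins_group1, p_bins_group2 = p_bins_group2,
                 trials_per_gain_rt = as.integer(trials_per_gain_rt),
                 per_condition_rt = as.integer(per_condition_rt)),
            class = "design_config")
}

#' Safe amount for a calibration trial
#'
#' The certain amount offered against a gamble paying `gain` or 0 with equal
#' probability: the gamble's expected value divided by `divisor`, rounded to
#' the nearest penny.
#'
#' @param gain Gamble prize, pounds.
#' @param divisor Positive divisor.
#' @return Certain amount in pounds, penny precision.
#' @examples
#' certain_amount(6, 3.5)  # 0.86
#' certain_amount(6, 1)    # 3.00, the expected value itself
#' @export
certain_amount <- function(gain, divisor) {
  if (any(divisor <= 0)) stop("divisor must be positive", call. = FALSE)
  if (any(gain <= 0)) stop("gain must be positive", call. = FALSE)
  round(0.5 * gain / divisor, 2)
}

#' Build the calibration-task offer sequence
#'
#' One offer per (gain, divisor) pair per repeat, shuffled with the seed.
#'
#' @param config A [design_config()].
#' @param repeats Repeats per cell; defaults to `config$day1_repeats`.
#' @param seed Integer seed for the shuffle.
#' @return A data.frame of offers: `trial_index`, `gain`, `safe`, `divisor`.
#' @examples
#' nrow(build_calibration_trials(design_config(), seed = 1))  # 180
#' @export
build_calibration_trials <- function(config = design_config(),
                                     repeats = config$day1_repeats,
                                     seed = 1L) {
  grid <- expand.grid(gain = config$gains, divisor = config$divisors,
                      KEEP.OUT.ATTRS = FALSE)
  offers <- grid[rep(seq_len(nrow(grid)), times = repeats), , drop = FALSE]
  if (nrow(offers) == 0L)
    return(data.frame(trial_index = integer(0), gain = numeric(0),
                      safe = numeric(0), divisor = numeric(0)))
  offers$safe <- certain_amount(offers$gain, offers$divisor)
  ord <- with_seed(seed, sample.int(nrow(offers)))
  offers <- offers[ord, c("gain", "safe", "divisor")]
  rownames(offers) <- NULL
  cbind(trial_index = seq_len(nrow(offers)), offers)
}

#' Safe amounts hitting target gamble probabilities
#'
#' Inverts the softmax decision rule: for each target probability `p` the
#' certain-option utility satisfying
#' `p = logistic(mu * (u_gamble - u_certain + kappa))` is
#' `u_certain = u_gamble + kappa - log(p / (1 - p)) / mu`, which is mapped
#' back to money through the utility function (`V = U^(1/alpha)`), rounded to
#' the penny and clipped to `[0.01, gain - 0.01]` (safe offers are always
#' positive and below the prize).
#'
#' @param params A [decision_params()]; for calibration the base model is
#'   used (`kappa = 0`).
#' @param gain Gamble prize, pounds.
#' @param p_targets Target gamble probabilities, each in (0, 1).
#' @return Numeric vector of safe amounts (pounds); the attribute
#'   `"clipped"` flags targets that hit the admissible range's edge.
#' @examples
#' safe_values_for_pbins(decision_params(1, 1, 0), 6, 0.75)  # 3 - log(3)
#' @export
safe_values_for_pbins <- function(params, gain, p_targets) {
  stopifnot(inherits(params, "decision_params"))
  if (params$mu <= 0 || params$alpha <= 0)
    stop("mu and alpha must be positive", call. = FALSE)
  if (any(p_targets <= 0 | p_targets >= 1))
    stop("p_targets must lie strictly inside (0, 1)", call. = FALSE)
  u_g <- 0.5 * gain^params$alpha
  u_c <- u_g + params$kappa - log(p_targets / (1 - p_targets)) / params$mu
  v <- ifelse(u_c > 0, u_c^(1 / params$alpha), 0)
  v <- round(v, 2)
  lo <- 0.01
  hi <- gain - 0.01
  clipped <- v < lo | v > hi
  v <- pmin(pmax(v, lo), hi)
  attr(v, "clipped") <- clipped
  v
}

#' Build the triggered-session offer set
#'
#' For each gain, safe amounts are placed at the group's target gamble
#' probabilities (5 bins) and each (gain, safe) cell is repeated
#' `trials_per_gain_rt / length(p_bins)` times, split equally between
#' low- and high-activity slots so both conditions face identical offer
#' multisets. The order is shuffled with the seed.
#'
#' @param params Fitted base-model [decision_params()] for this subject.
#' @param config A [design_config()].
#' @param group Calibration group, 1 or 2 (fixes the p-target span).
#' @param seed Integer seed for the shuffle.
#' @return A data.frame of offers: `trial_index`, `gain`, `safe`, `p_target`,
#'   `condition_slot` (`"low"`/`"high"`).
#' @examples
#' off <- build_realtime_trials(decision_params(0.9, 3, 0), design_config(),
#'                              group = 1, seed = 1)
#' nrow(off); table(off$condition_slot)
#' @export
build_realtime_trials <- function(params, config = design_config(),
                                  group = 1L, seed = 1L) {
  stopifnot(group %in% c(1L, 2L))
  p_targets <- if (group == 1L) config$p_bins_group1 else config$p_bins_group2
  reps <- config$trials_per_gain_rt / length(p_targets)
  if (reps != round(reps))
    stop("trials_per_gain_rt must be a multiple of the number of p bins",
         call. = FALSE)
  if (reps %% 2 != 0)
    stop("repeats per (gain, safe) cell must be even to balance conditions",
         call. = FALSE)
  rows <- list()
  for (g in config$gains) {
    safes <- safe_values_for_pbins(params, g, p_targets)
    for (j in seq_along(p_targets)) {
      cell <- data.frame(gain = g, safe = as.numeric(safes[j]),
                         p_target = p_targets[j],
                         condition_slot = rep(c("low", "high"),
                                              each = reps / 2))
      rows[[length(rows) + 1L]] <- cell
    }
  }
  offers <- do.call(rbind, rows)
  ord <- with_seed(seed, sample.int(nrow(offers)))
  offers <- offers[ord, ]
  rownames(offers) <- NULL
  cbind(trial_index = seq_len(nrow(offers)), offers)
}
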