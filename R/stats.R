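#' Extract raw peristimulus epochs from a BOLD series
#'
#' Cuts one row per onset, starting at the first volume acquired at or after
#' the onset, on a common peristimulus time axis.
#'
#' @param bold A [bold_time_series()].
#' @param onsets_s Numeric vector of stimulus onsets, seconds.
#' @param n_timepoints Number of volumes per epoch. Default 10 (17.5 s at a
#'   1.75-s TR).
#' @param condition Optional per-onset condition labels carried along.
#' @return A matrix (onsets x timepoints) with attributes `time_s`
#'   (peristimulus times, seconds) and `condition`.
#' @export
extract_epochs <- function(bold, onsets_s, n_timepoints = 10L,
                           condition = NULL) {
  stopifnot(inherits(bold, "bold_ts"))
  tt <- bold_times(bold)
  n <- length(bold$values)
  first <- vapply(onsets_s, function(o) {
    i <- which(tt >= o - 1e-9)[1]
    if (is.na(i) || i + n_timepoints - 1L > n)
      stop("epoch extends beyond the BOLD series", call. = FALSE)
    i
  }, integer(1))
  ep <- t(vapply(first, function(i)
    bold$values[i:(i + n_timepoints - 1L)], numeric(n_timepoints)))
  attr(ep, "time_s") <- (seq_len(n_timepoints) - 1L) * bold$tr_seconds
  attr(ep, "condition") <- condition
  ep
}

#' Percent signal change relative to the first post-onset volumes
#'
#' Per trial, `PSC(t) = 100 * (x(t) - b) / b` with `b` the mean of the first
#' `baseline_volumes` samples at/after stimulus onset, correcting each trial
#' for its starting baseline. Trials with a non-positive baseline are
#' invalid (all-`NA` row, flagged).
#'
#' @param raw_epochs Trials x timepoints matrix of raw signal (e.g. from
#'   [extract_epochs()]); attributes `time_s`/`condition` are preserved.
#' @param baseline_volumes Number of leading volumes forming the baseline.
#'   Default 2.
#' @return Matrix of the same shape in percent units, with attributes
#'   `time_s`, `condition`, and `invalid` (logical per trial).
#' @export
percent_signal_change <- function(raw_epochs, baseline_volumes = 2L) {
  x <- as.matrix(raw_epochs)
  stopifnot(ncol(x) > baseline_volumes, baseline_volumes >= 1L)
  b <- rowMeans(x[, seq_len(baseline_volumes), drop = FALSE])
  invalid <- !(b > 0)
  psc <- 100 * sweep(sweep(x, 1, b, `-`), 1, b, `/`)
  psc[invalid, ] <- NA_real_
  attr(psc, "time_s") <- attr(raw_epochs, "time_s")
  attr(psc, "condition") <- attr(raw_epochs, "condition")
  attr(psc, "invalid") <- invalid
  psc
}

#' Per-trial evoked amplitude: mean PSC inside a peristimulus window
#'
#' Averages each trial's percent-signal-change samples over the timepoints
#' whose peristimulus times fall inside the closed window (boundaries snap to
#' sample times within numerical tolerance). At the default TR of 1.75 s the
#' default window covers the samples at 5.25, 7, 8.75, and 10.5 s.
#'
#' @param epochs Trials x timepoints PSC matrix with a `time_s` attribute
#'   (or supply `time_s`).
#' @param window_s Length-2 numeric window in seconds. Default
#'   `c(5.25, 10.5)`.
#' @param time_s Optional explicit peristimulus time axis.
#' @return Numeric vector of per-trial window means.
#' @export
epoch_average <- function(epochs, window_s = c(5.25, 10.5), time_s = NULL) {
  x <- as.matrix(epochs)
  tt <- if (is.null(time_s)) attr(epochs, "time_s") else time_s
  if (is.null(tt)) stop("epochs carry no time axis", call. = FALSE)
  stopifnot(length(tt) == ncol(x), length(window_s) == 2L)
  sel <- tt >= window_s[1] - 1e-9 & tt <= window_s[2] + 1e-9
  if (!any(sel)) stop("window contains no sample times", call. = FALSE)
  rowMeans(x[, sel, drop = FALSE])
}

#' Configuration of the cluster-extent permutation test
#'
#' @param height_threshold_t Cluster-forming |t| threshold. Default 2.
#' @param n_permutations Number of sign-flip permutations. Default 5000.
#' @param alpha Cluster-level significance threshold. Default 0.01.
#' @param statistic Cluster statistic: `"extent"` (number of contiguous
#'   supra-threshold timepoints; default) or `"mass"` (sum of |t| over the
#'   cluster).
#' @return An object of class `cluster_test_config`.
#' @export
cluster_test_config <- function(height_threshold_t = 2,
                                n_permutations = 5000L, alpha = 0.01,
                                statistic = c("extent", "mass")) {
  stopifnot(n_permutations >= 1L, alpha > 0, alpha < 1,
            height_threshold_t > 0)
  structure(list(height_threshold_t = height_threshold_t,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 statistic = match.arg(statistic)),
            class = "cluster_test_config")
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end)
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Cluster-extent permutation test on paired condition time courses
#'
#' Compares two conditions' per-subject mean time courses with a paired t
#' statistic at every timepoint. Clusters are maximal runs of contiguous
#' timepoints with `|t| >=` the height threshold; their extent (or mass) is
#' compared against the permutation distribution of the maximum cluster
#' statistic obtained under random per-subject sign flips of the paired
#' differences. Cluster p-values use the add-one convention
#' `(1 + #{null >= observed}) / (1 + B)`.
#'
#' @param epochs_low,epochs_high Subjects x timepoints matrices of mean time
#'   courses (matching rows = subjects, on a common time axis).
#' @param config A [cluster_test_config()].
#' @param seed Integer seed for the permutation draws.
#' @return A list with `t` (per-timepoint paired t values), `clusters`
#'   (data.frame `start`, `end`, `extent`, `mass`, `stat`, `p_value`),
#'   `null_max` (permutation distribution of the max cluster statistic), and
#'   `config`.
#' @export
cluster_extent_permutation_test <- function(epochs_low, epochs_high,
                                            config = cluster_test_config(),
                                            seed = 1L) {
  lo <- as.matrix(epochs_low)
  hi <- as.matrix(epochs_high)
  stopifnot(all(dim(lo) == dim(hi)))
  n <- nrow(lo)
  if (n < 3L) stop("at least 3 subjects are required", call. = FALSE)
  d <- lo - hi
  nt <- ncol(d)
  h <- config$height_threshold_t

  t_of <- function(mn, ss) {
    v <- (ss - n * mn^2) / (n - 1)
    v[v < 1e-300] <- 1e-300
    mn / sqrt(v / n)
  }
  ss <- colSums(d^2)  # invariant under sign flips
  t_obs <- t_of(colMeans(d), ss)

  cl <- runs_of(abs(t_obs) >= h)
  stat_of <- function(cl_df, tvals) {
    ext <- cl_df$end - cl_df$start + 1L
    mass <- vapply(seq_len(nrow(cl_df)), function(i)
      sum(abs(tvals[cl_df$start[i]:cl_df$end[i]])), numeric(1))
    list(extent = ext, mass = mass)
  }
  obs <- stat_of(cl, t_obs)
  cl$extent <- obs$extent
  cl$mass <- obs$mass
  cl$stat <- if (config$statistic == "extent") cl$extent else cl$mass

  B <- config$n_permutations
  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), B * n, replace = TRUE), B, n)
    mns <- signs %*% d / n
    vapply(seq_len(B), function(b) {
      tb <- t_of(mns[b, ], ss)
      rb <- runs_of(abs(tb) >= h)
      if (nrow(rb) == 0L) return(0)
      sb <- stat_of(rb, tb)
      max(if (config$statistic == "extent") sb$extent else sb$mass)
    }, numeric(1))
  })
  cl$p_value <- vapply(cl$stat, function(s)
    (1 + sum(null_max >= s)) / (1 + B), numeric(1))
  list(t = t_obs, clusters = cl, null_max = null_max, config = config)
}

#' Two-stage multilevel mediation with subject bootstrap
#'
#' Level 1 fits, per subject, the three mediation regressions:
#' `m ~ x` (path a), `y ~ m + x` (paths b and c'), and `y ~ x` (total path
#' c), with a logistic outcome stage for binary choice (`y_family =
#' "binomial"`, the default) or a linear stage (`"gaussian"`, under which
#' `c = c' + a*b` holds exactly per subject). Level 2 applies one-sample t
#' tests to the subject coefficients; the indirect effect is the mean of the
#' per-subject `a*b` products with a percentile bootstrap CI over subjects.
#'
#' @param x Per-trial predictor (e.g. prestimulus percentile).
#' @param m Per-trial mediator (e.g. evoked-response amplitude).
#' @param y Per-trial outcome (binary choice, or continuous for the linear
#'   variant).
#' @param subject_ids Per-trial subject identifiers.
#' @param n_boot Bootstrap resamples of subjects. Default 5000.
#' @param seed Integer seed.
#' @param y_family `"binomial"` or `"gaussian"`.
#' @return An object of class `mediation_result`: list with `paths` (a
#'   data.frame of level-2 estimates, SEs, t, p for a, b, c, c_prime, and
#'   the bootstrap summary for ab), `per_subject` coefficients, `n_subjects`
#'   used, and `dropped` subject ids.
#' @export
multilevel_mediation <- function(x, m, y, subject_ids, n_boot = 5000L,
                                 seed = 1L,
                                 y_family = c("binomial", "gaussian")) {
  y_family <- match.arg(y_family)
  stopifnot(length(x) == length(m), length(m) == length(y),
            length(y) == length(subject_ids))
  subjects <- unique(subject_ids)
  rows <- list()
  dropped <- character(0)
  for (s in subjects) {
    i <- subject_ids == s
    xs <- x[i]; ms <- m[i]; ys <- y[i]
    ok <- stats::var(xs) > 0 && stats::var(ms) > 0 &&
      (y_family == "gaussian" || length(unique(ys)) > 1L)
    if (!ok) {
      dropped <- c(dropped, as.character(s))
      next
    }
    a <- stats::coef(stats::lm(ms ~ xs))[["xs"]]
    if (y_family == "binomial") {
      f2 <- suppressWarnings(stats::glm(ys ~ ms + xs, family = stats::binomial()))
      f3 <- suppressWarnings(stats::glm(ys ~ xs, family = stats::binomial()))
    } else {
      f2 <- stats::lm(ys ~ ms + xs)
      f3 <- stats::lm(ys ~ xs)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = s, a = a,
                 b = stats::coef(f2)[["ms"]],
                 c_prime = stats::coef(f2)[["xs"]],
                 c = stats::coef(f3)[["xs"]])
  }
  if (length(dropped) > 0L)
    warning("dropped subjects without predictor/mediator/outcome variance: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) < 3L)
    stop("fewer than 3 usable subjects for mediation", call. = FALSE)
  per$ab <- per$a * per$b

  lvl2 <- function(v) {
    tt <- stats::t.test(v)
    c(estimate = mean(v), se = stats::sd(v) / sqrt(length(v)),
      t = unname(tt$statistic), p = tt$p.value,
      ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2])
  }
  paths <- as.data.frame(t(vapply(per[c("a", "b", "c", "c_prime")], lvl2,
                                  numeric(6))))
  paths$path <- rownames(paths)

  ns <- nrow(per)
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(ns, ns * n_boot, replace = TRUE), n_boot, ns)
    apply(idx, 1, function(j) mean(per$ab[j]))
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  p_boot <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p_boot <- min(max(p_boot, 1 / n_boot), 1)
  ab_row <- data.frame(estimate = mean(per$ab),
                       se = stats::sd(per$ab) / sqrt(ns),
                       t = NA_real_, p = p_boot,
                       ci_lo = ci[1], ci_hi = ci[2], path = "ab")
  paths <- rbind(paths, ab_row)
  rownames(paths) <- paths$path
  structure(list(paths = paths[c("path", "estimate", "se", "t", "p",
                                 "ci_lo", "ci_hi")],
                 per_subject = per, n_subjects = ns, dropped = dropped,
                 y_family = y_family, n_boot = n_boot),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %d subjects (%s outcome stage)\n",
              x$n_subjects, x$y_family))
  print(x$paths, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-subject behavioral summaries and group tests
#'
#' Computes, for each subject, gamble rates and mean reaction times by
#' activity condition, and gamble rates within equal-size quantile bins of
#' the objective value difference between risky and safe options
#' (`0.5 * gain - safe`), binned per subject. Group-level paired t tests
#' compare the low and high conditions.
#'
#' @param trials Data.frame with columns `subject_id`, `condition`,
#'   `gain`, `safe`, `choice`, `rt_s`.
#' @param n_bins Number of value-difference bins per subject. Default 5.
#' @return An object of class `behavioral_summary`: list with `per_subject`
#'   (one row per subject: rates and RT means by condition and their
#'   differences), `by_bin` (gamble rate per subject, bin, and condition),
#'   `rate_test`, `rt_test` (paired t tests, low minus high), and `n_bins`.
#' @export
behavioral_summary <- function(trials, n_bins = 5L) {
  need <- c("subject_id", "condition", "gain", "safe", "choice", "rt_s")
  stopifnot(all(need %in% names(trials)))
  tr <- trials[!is.na(trials$choice), , drop = FALSE]
  sp <- split(tr, tr$subject_id)
  per <- do.call(rbind, lapply(sp, function(d) {
    lo <- d[d$condition == "low", ]
    hi <- d[d$condition == "high", ]
    data.frame(subject_id = d$subject_id[1],
               rate_low = mean(lo$choice), rate_high = mean(hi$choice),
               rate_overall = mean(d$choice),
               rt_low = mean(lo$rt_s), rt_high = mean(hi$rt_s))
  }))
  per$rate_diff <- per$rate_low - per$rate_high
  per$rt_diff <- per$rt_low - per$rt_high
  rownames(per) <- NULL

  by_bin <- do.call(rbind, lapply(sp, function(d) {
    vd <- 0.5 * d$gain - d$safe
    # equal-size bins: rank order, ties broken by trial order
    ord <- order(vd)
    bin <- integer(nrow(d))
    bin[ord] <- ceiling(seq_along(ord) / (length(ord) / n_bins))
    bin <- pmin(bin, n_bins)
    agg <- stats::aggregate(list(rate = d$choice, value_diff = vd),
                            by = list(bin = bin, condition = d$condition),
                            FUN = mean)
    agg$n <- stats::aggregate(seq_len(nrow(d)),
                              by = list(bin = bin, condition = d$condition),
                              FUN = length)$x
    agg$subject_id <- d$subject_id[1]
    agg
  }))
  rownames(by_bin) <- NULL

  rate_test <- rt_test <- NULL
  if (nrow(per) >= 3L && stats::sd(per$rate_diff) > 0) {
    rate_test <- stats::t.test(per$rate_low, per$rate_high, paired = TRUE)
    rt_test <- stats::t.test(per$rt_low, per$rt_high, paired = TRUE)
  }
  structure(list(per_subject = per, by_bin = by_bin, rate_test = rate_test,
                 rt_test = rt_test, n_bins = n_bins),
            class = "behavioral_summary")
}

#' Correlations between susceptibility measures across subjects
#'
#' Spearman (midrank ties) and/or Pearson correlations, with p-values from
#' `stats::cor.test` (exact where available for small n without ties,
#' t/S approximations otherwise).
#'
#' @param df Data.frame of per-subject scalars.
#' @param x_vars Character vector of predictor column names.
#' @param y_var Response column name.
#' @param method `"spearman"`, `"pearson"`, or both.
#' @return Data.frame with columns `x`, `y`, `method`, `estimate`,
#'   `p_value`, `n`.
#' @export
susceptibility_correlations <- function(df, x_vars, y_var,
                                        method = c("spearman", "pearson")) {
  method <- match.arg(method, several.ok = TRUE)
  rows <- list()
  for (xv in x_vars) for (mth in method) {
    ok <- stats::complete.cases(df[[xv]], df[[y_var]])
    ct <- suppressWarnings(
      stats::cor.test(df[[xv]][ok], df[[y_var]][ok], method = mth))
    rows[[length(rows) + 1L]] <-
      data.frame(x = xv, y = y_var, method = mth,
                 estimate = unname(ct$estimate), p_value = ct$p.value,
                 n = sum(ok))
  }
  do.call(rbind, rows)
}

#' Per-subject reaction-time regression with group-level tests
#'
#' For each subject, ordinary least squares of reaction time on prestimulus
#' activity (percentile), the choice indicator, and the absolute subjective
#' value difference `|u_gamble - u_certain|` under the subject's fitted
#' parameters (an index of choice difficulty). Coefficients are then tested
#' against zero across subjects.
#'
#' @param trials Data.frame with columns `subject_id`, `rt_s`, `percentile`,
#'   `choice`, `gain`, `safe`.
#' @param params_by_subject Named list mapping subject id to
#'   [decision_params()] (or a single `decision_params` applied to all).
#' @return List with `per_subject` (coefficient data.frame), `group`
#'   (one-sample t tests per coefficient), and `flagged` (subjects with
#'   rank-deficient design matrices, excluded).
#' @export
rt_regression <- function(trials, params_by_subject) {
  sp <- split(trials, trials$subject_id)
  rows <- list()
  flagged <- character(0)
  for (s in names(sp)) {
    d <- sp[[s]]
    d <- d[!is.na(d$choice) & !is.na(d$rt_s), , drop = FALSE]
    pars <- if (inherits(params_by_subject, "decision_params"))
      params_by_subject else params_by_subject[[s]]
    if (is.null(pars)) stop("no parameters for subject ", s, call. = FALSE)
    u <- utility(d, pars$alpha)
    X <- cbind(1, d$percentile, d$choice, abs(u$u_gamble - u$u_certain))
    colnames(X) <- c("(Intercept)", "activity", "choice", "abs_dsv")
    if (qr(X)$rank < ncol(X)) {
      flagged <- c(flagged, s)
      next
    }
    beta <- stats::coef(stats::lm.fit(X, d$rt_s))
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = s, t(beta), check.names = FALSE)
  }
  per <- do.call(rbind, rows)
  if (is.null(per)) stop("no subject had a full-rank design", call. = FALSE)
  rownames(per) <- NULL
  coefs <- setdiff(names(per), "subject_id")
  group <- do.call(rbind, lapply(coefs, function(cn) {
    v <- per[[cn]]
    tt <- if (length(v) >= 3L)
      tryCatch(stats::t.test(v), error = function(e) NULL) else NULL
    if (is.null(tt))  # too few subjects or (numerically) constant estimates
      return(data.frame(coef = cn, estimate = mean(v), t = NA_real_,
                        p = NA_real_))
    data.frame(coef = cn, estimate = mean(v), t = unname(tt$statistic),
               p = tt$p.value)
  }))
  list(per_subject = per, group = group, flagged = flagged)
}
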