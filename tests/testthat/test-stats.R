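test_that("percent signal change normalizes to the post-onset baseline", {
  # constant epoch -> all zeros
  m <- matrix(200, 3, 8)
  psc <- percent_signal_change(m)
  expect_equal(unclass(psc)[, ], matrix(0, 3, 8), ignore_attr = TRUE)

  # epoch at 1.01 x baseline -> 1.0 after the baseline volumes
  m2 <- matrix(100, 1, 8)
  m2[1, 3:8] <- 101
  psc2 <- percent_signal_change(m2)
  expect_equal(as.numeric(psc2[1, 3:8]), rep(1, 6))

  # arithmetic oracle: b = 200, x = 205 -> 2.5
  m3 <- matrix(c(200, 200, 205), 1, 3)
  expect_equal(as.numeric(percent_signal_change(m3)[1, 3]), 2.5)

  # invariance to multiplicative rescaling of the raw signal
  set.seed(40)
  m4 <- matrix(100 + rnorm(40), 5, 8)
  expect_equal(unclass(percent_signal_change(3 * m4)),
               unclass(percent_signal_change(m4)), ignore_attr = TRUE)

  # non-positive baseline flags the trial invalid
  m5 <- rbind(c(-1, 1, 5, 5), c(10, 10, 11, 12))
  psc5 <- percent_signal_change(m5)
  expect_true(attr(psc5, "invalid")[1])
  expect_true(all(is.na(psc5[1, ])))
  expect_false(anyNA(psc5[2, ]))
})

test_that("epoch_average selects the closed peristimulus window", {
  tt <- (0:9) * 1.75
  # default window covers exactly the samples at 5.25, 7, 8.75, 10.5 s
  x <- matrix(tt, 1, 10, byrow = TRUE)
  expect_equal(epoch_average(x, time_s = tt),
               mean(c(5.25, 7, 8.75, 10.5)))  # linear ramp -> 7.875
  expect_equal(epoch_average(x, time_s = tt), 7.875)
  # a window covering one sample returns that sample
  expect_equal(epoch_average(x, window_s = c(7, 7), time_s = tt), 7)
  expect_error(epoch_average(x, window_s = c(0.3, 0.4), time_s = tt),
               "no sample")
})

test_that("epoch extraction aligns to the first volume at/after onset", {
  ts <- bold_time_series(1:100, 1.75)
  ep <- extract_epochs(ts, onsets_s = c(0, 17.5), n_timepoints = 4)
  expect_equal(unclass(ep), rbind(1:4, 11:14), ignore_attr = TRUE)
  expect_equal(attr(ep, "time_s"), (0:3) * 1.75)
  expect_error(extract_epochs(ts, 174, n_timepoints = 4), "beyond")
})

test_that("cluster test finds no clusters when conditions are identical", {
  set.seed(41)
  a <- matrix(rnorm(60), 6, 10)
  res <- cluster_extent_permutation_test(a, a,
                                         cluster_test_config(n_permutations = 99))
  expect_equal(nrow(res$clusters), 0)
  expect_error(cluster_extent_permutation_test(a[1:2, ], a[1:2, ]),
               "3 subjects")
})

test_that("cluster permutation null is seeded and p-values are bounded", {
  set.seed(42)
  lo <- matrix(rnorm(200), 20, 10)
  lo[, 4:7] <- lo[, 4:7] + 1
  hi <- matrix(rnorm(200), 20, 10)
  cfg <- cluster_test_config(n_permutations = 200)
  r1 <- cluster_extent_permutation_test(lo, hi, cfg, seed = 9)
  r2 <- cluster_extent_permutation_test(lo, hi, cfg, seed = 9)
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(r1$clusters, r2$clusters)
  expect_true(all(r1$clusters$p_value >= 1 / 201))
  expect_true(all(r1$clusters$p_value <= 1))
  expect_gte(nrow(r1$clusters), 1)
  # the injected 4-timepoint span is inside a detected cluster
  top <- r1$clusters[which.max(r1$clusters$extent), ]
  expect_lte(top$start, 4)
  expect_gte(top$end, 7)
  expect_lt(top$p_value, 0.05)
  # the mass statistic flags the same leading cluster
  rm_ <- cluster_extent_permutation_test(lo, hi,
    cluster_test_config(n_permutations = 200, statistic = "mass"), seed = 9)
  expect_equal(rm_$clusters$start, r1$clusters$start)
})

test_that("mediation recovers the generative path structure", {
  gen_med <- function(seed, n_subj = 12, n_tr = 60, b_direct = 0,
                      b_med = 1.5) {
    set.seed(seed)
    out <- lapply(seq_len(n_subj), function(s) {
      x <- rnorm(n_tr)
      m <- -1.2 * x + rnorm(n_tr, sd = 0.6)
      eta <- b_med * m + b_direct * x
      y <- rbinom(n_tr, 1, plogis(eta))
      data.frame(subject_id = s, x = x, m = m, y = y)
    })
    do.call(rbind, out)
  }
  # full mediation: a and b nonzero, c' centered on 0, ab clearly negative
  d <- gen_med(50)
  res <- multilevel_mediation(d$x, d$m, d$y, d$subject_id, n_boot = 500,
                              seed = 1)
  p <- res$paths
  expect_lt(p["a", "estimate"], -0.8)
  expect_gt(p["b", "estimate"], 0.5)
  expect_lt(p["ab", "ci_hi"], 0)
  expect_gt(p["c_prime", "p"], 0.05)
  # and the total effect is carried by the indirect path
  expect_lt(p["c", "estimate"], 0)

  # no-mediation structure: y generated from x only
  set.seed(51)
  d2 <- lapply(1:12, function(s) {
    x <- rnorm(60)
    data.frame(subject_id = s, x = x, m = rnorm(60),
               y = rbinom(60, 1, plogis(1.5 * x)))
  })
  d2 <- do.call(rbind, d2)
  res2 <- multilevel_mediation(d2$x, d2$m, d2$y, d2$subject_id,
                               n_boot = 500, seed = 2)
  p2 <- res2$paths
  expect_gt(p2["ab", "p"], 0.05)
  expect_lt(abs(p2["c", "estimate"] - p2["c_prime", "estimate"]),
            0.25 * abs(p2["c", "estimate"]) + 0.2)
})

test_that("with a linear outcome stage c = c' + a*b exactly per subject", {
  set.seed(52)
  d <- lapply(1:5, function(s) {
    x <- rnorm(40)
    m <- 0.8 * x + rnorm(40)
    data.frame(subject_id = s, x = x, m = m,
               y = 0.5 * m - 0.2 * x + rnorm(40))
  })
  d <- do.call(rbind, d)
  res <- multilevel_mediation(d$x, d$m, d$y, d$subject_id, n_boot = 200,
                              seed = 3, y_family = "gaussian")
  with(res$per_subject, expect_equal(c, c_prime + a * b, tolerance = 1e-10))
})

test_that("mediation drops degenerate subjects and enforces minimum n", {
  set.seed(53)
  x <- c(rnorm(30), rep(1, 30), rnorm(30), rnorm(30))
  m <- rnorm(120)
  y <- rbinom(120, 1, 0.5)
  ids <- rep(1:4, each = 30)
  expect_warning(res <- multilevel_mediation(x, m, y, ids, n_boot = 50,
                                             seed = 1),
                 "dropped")
  expect_equal(res$n_subjects, 3)
  expect_error(suppressWarnings(
    multilevel_mediation(x[1:60], m[1:60], y[1:60], ids[1:60], n_boot = 50,
                         seed = 1)), "3 usable")
})

test_that("behavioral summary computes rates, bins, and paired tests", {
  co <- gen_cohort(8, synthetic_config(seed = 60), mode = "behavioral")
  tr <- cohort_trials(co)
  bs <- behavioral_summary(tr, n_bins = 5)
  expect_equal(nrow(bs$per_subject), 8)
  expect_true(all(bs$per_subject$rate_low >= 0 &
                    bs$per_subject$rate_low <= 1))
  # 90 trials in 5 bins -> 18 per bin; 9 per bin and condition on average
  n_per <- with(bs$by_bin[bs$by_bin$subject_id == 1, ], tapply(n, bin, sum))
  expect_equal(unname(n_per), rep(18, 5), ignore_attr = TRUE)
  # bins ordered by value difference
  b1 <- bs$by_bin[bs$by_bin$subject_id == 1 & bs$by_bin$condition == "low", ]
  expect_true(all(diff(b1$value_diff[order(b1$bin)]) > 0))
  # generated bias difference shows up as higher low-condition gamble rates
  expect_gt(mean(bs$per_subject$rate_diff), 0)
  expect_lt(bs$rate_test$p.value, 0.05)

  # all-gamble subject: rate 1 in both conditions, difference 0
  one <- tr[tr$subject_id == 1, ]
  one$choice <- 1L
  bs1 <- behavioral_summary(one)
  expect_equal(bs1$per_subject$rate_low, 1)
  expect_equal(bs1$per_subject$rate_diff, 0)
})

test_that("susceptibility correlations match a brute-force rank oracle", {
  # hand-checkable 6-point table
  df <- data.frame(u = c(1, 2, 3, 4, 5, 6), v = c(2, 1, 4, 3, 6, 5))
  out <- susceptibility_correlations(df, "u", "v", "spearman")
  rx <- rank(df$u); ry <- rank(df$v)
  rho_oracle <- 1 - 6 * sum((rx - ry)^2) / (6 * (36 - 1))
  expect_equal(out$estimate, rho_oracle)
  # perfectly monotone and anti-monotone pairs
  df2 <- data.frame(a = 1:7, up = (1:7)^3, dn = -(1:7))
  res <- susceptibility_correlations(df2, c("up", "dn"), "a", "spearman")
  expect_equal(res$estimate, c(1, -1))
  # pearson on a linear pair
  resp <- susceptibility_correlations(df2, "dn", "a", "pearson")
  expect_equal(resp$estimate, -1)
})

test_that("reaction-time regression recovers noise-free coefficients", {
  set.seed(61)
  pars <- decision_params(0.9, 3, 0)
  mk <- function(s) {
    d <- offer_grid(40, seed = s)
    d$subject_id <- s
    d$percentile <- runif(40)
    d$choice <- rbinom(40, 1, 0.5)
    u <- utility(d, pars$alpha)
    d$rt_s <- 2 - 0.1 * d$percentile + 0.05 * d$choice +
      0.02 * abs(u$u_gamble - u$u_certain)
    d
  }
  tr <- do.call(rbind, lapply(1:4, mk))
  res <- rt_regression(tr, pars)
  expect_equal(unname(res$per_subject$activity), rep(-0.1, 4),
               tolerance = 1e-8)
  expect_equal(unname(res$per_subject$abs_dsv), rep(0.02, 4),
               tolerance = 1e-8)
  expect_equal(res$group$estimate[res$group$coef == "activity"], -0.1,
               tolerance = 1e-8)

  # constant predictor column -> subject flagged and excluded
  tr2 <- tr
  tr2$percentile[tr2$subject_id == 2] <- 0.5
  res2 <- rt_regression(tr2, pars)
  expect_equal(res2$flagged, "2")
  expect_equal(nrow(res2$per_subject), 3)
})

test_that("null reaction times give nominal false-positive rates", {
  pars <- decision_params(0.9, 3, 0)
  ps <- vapply(1:40, function(i) {
    set.seed(600 + i)
    tr <- do.call(rbind, lapply(1:10, function(s) {
      d <- offer_grid(30, seed = s + i)
      d$subject_id <- s
      d$percentile <- runif(30)
      d$choice <- rbinom(30, 1, 0.5)
      d$rt_s <- rlnorm(30, log(1.7), 0.3)
      d
    }))
    rt_regression(tr, pars)$group$p[2]
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps < 0.6), 0.25)
})
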