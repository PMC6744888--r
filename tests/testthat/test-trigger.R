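test_that("percentile_of_recent matches the normal-CDF definition", {
  cfg <- trigger_config()
  need <- cfg$window_volumes + cfg$recent_volumes

  # constant series: recent mean equals window mean, zero variance -> 0.5
  st <- warm_state(rep(3.7, need))
  expect_equal(percentile_of_recent(st, cfg), 0.5)

  # recent mean one window-SD above the window mean -> pnorm(1)
  set.seed(1)
  win <- rnorm(cfg$window_volumes)
  m_target <- mean(win) + sd(win)
  st <- warm_state(c(win, m_target, m_target))
  expect_equal(percentile_of_recent(st, cfg), pnorm(1), tolerance = 1e-12)

  # warm-up: no value before window + recent samples have been seen
  st_short <- warm_state(rnorm(need - 1))
  expect_true(is.na(percentile_of_recent(st_short, cfg)))
})

test_that("percentile_of_recent is weakly increasing in the newest sample", {
  cfg <- trigger_config()
  set.seed(2)
  hist <- rnorm(cfg$window_volumes + 1)
  pcts <- vapply(seq(-3, 3, length.out = 25), function(v) {
    st <- warm_state(c(hist, v))
    percentile_of_recent(st, cfg)
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("on iid input the tail frequencies match the closed-form rate", {
  # ranking the mean of 2 volumes against the distribution of single
  # volumes compresses percentiles toward 0.5: on iid noise the 0.15
  # threshold is crossed with probability
  # pnorm(qnorm(0.15) / sqrt(1/2 + 1/69)), not 0.15
  cfg <- trigger_config()
  p_expected <- pnorm(qnorm(0.15) / sqrt(1 / cfg$recent_volumes +
                                           1 / cfg$window_volumes))
  set.seed(3)
  x <- rnorm(10071)
  st <- new_window_state(cfg)
  pct <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    st <- trigger_step(st, x[i], cfg, 0)$state
    pct[i] <- percentile_of_recent(st, cfg)
  }
  pct <- pct[!is.na(pct)]
  expect_gte(length(pct), 10000)
  expect_lt(abs(mean(pct <= 0.15) - p_expected), 0.02)
  expect_lt(abs(mean(pct >= 0.85) - p_expected), 0.02)
})

test_that("trigger_step applies threshold, lockout, and timeout rules", {
  cfg <- trigger_config()
  need <- cfg$window_volumes + cfg$recent_volumes
  set.seed(4)
  win <- rnorm(cfg$window_volumes)
  low_val <- mean(win) - 3 * sd(win)
  mid_val <- mean(win) + 0.2 * sd(win)

  base <- warm_state(c(win, rnorm(1)))
  # low percentile, ITI satisfied -> low event, not forced
  out <- trigger_step(base, low_val, cfg, elapsed_since_last_trial_s = 25)
  expect_equal(out$event$label, "low")
  expect_false(out$event$forced)
  expect_lte(out$event$percentile, 0.15)
  # identical value during the lockout -> no event
  out2 <- trigger_step(base, low_val, cfg, elapsed_since_last_trial_s = 10)
  expect_null(out2$event)
  # mid percentile at timeout -> forced, labelled by sign vs the window mean
  st_mid <- warm_state(c(win, mid_val))
  out3 <- trigger_step(st_mid, mid_val, cfg, elapsed_since_last_trial_s = 55)
  expect_true(out3$event$forced)
  expect_equal(out3$event$label, "high")  # recent mean above window mean
  st_lo <- warm_state(c(win, -mid_val))
  out4 <- trigger_step(st_lo, -mid_val, cfg, elapsed_since_last_trial_s = 55)
  expect_true(out4$event$forced)
  expect_equal(out4$event$label, "low")
  # mid percentile before timeout -> nothing
  out5 <- trigger_step(st_mid, mid_val, cfg, elapsed_since_last_trial_s = 30)
  expect_null(out5$event)
})

test_that("run_session respects warm-up, ITI, and threshold contracts", {
  cfg <- trigger_config()
  short <- bold_time_series(rnorm(50), cfg$tr_seconds)
  expect_equal(nrow(run_session(short, cfg)), 0)

  ts <- gen_endogenous_bold(synthetic_config(n_volumes = 1200, seed = 21))
  ev <- run_session(ts, cfg)
  expect_gt(nrow(ev), 10)
  expect_true(all(diff(ev$time_s) >= cfg$min_iti_s))
  expect_true(all(diff(ev$volume_index) > 0))
  nf <- ev[!ev$forced, ]
  expect_true(all(nf$percentile <= cfg$low_threshold |
                    nf$percentile >= cfg$high_threshold))
  expect_true(all(ev$label %in% c("low", "high")))
})

test_that("run_session equals the iterated online step rule", {
  cfg <- trigger_config()
  ts <- gen_endogenous_bold(synthetic_config(n_volumes = 600, seed = 31))
  ev <- run_session(ts, cfg)

  st <- new_window_state(cfg)
  need <- cfg$window_volumes + cfg$recent_volumes
  last_time <- (need - 1) * cfg$tr_seconds
  got <- list()
  for (i in seq_along(ts$values)) {
    t_i <- (i - 1) * cfg$tr_seconds
    out <- trigger_step(st, ts$values[i], cfg, t_i - last_time,
                        volume_index = i - 1L)
    st <- out$state
    if (!is.null(out$event)) {
      got[[length(got) + 1L]] <- out$event
      last_time <- t_i
    }
  }
  expect_identical(do.call(rbind, got), ev)
})

test_that("low/high trigger counts are symmetric on exchangeable input", {
  cfg <- trigger_config()
  set.seed(6)
  counts <- colSums(t(sapply(1:8, function(i) {
    ts <- bold_time_series(rnorm(1200), cfg$tr_seconds)
    ev <- run_session(ts, cfg)
    c(low = sum(ev$label == "low" & !ev$forced),
      high = sum(ev$label == "high" & !ev$forced),
      forced = sum(ev$forced), total = nrow(ev))
  })))
  # binomial 95% band for equality of non-forced low/high counts
  n <- counts[["low"]] + counts[["high"]]
  expect_lt(abs(counts[["low"]] - n / 2), 1.96 * sqrt(n / 4) + 1)
  expect_gte(counts[["forced"]], 0)
  expect_lt(counts[["forced"]], counts[["total"]])
})

test_that("incremental nuisance regression matches batch least squares", {
  set.seed(7)
  n <- 500
  X <- cbind(rnorm(n), rnorm(n), rnorm(n))
  y <- 2 + X %*% c(0.5, -1, 0.25) + rnorm(n)
  out <- nuisance_regress_series(as.numeric(y), X)
  batch <- unname(coef(lm(y ~ X)))
  expect_equal(unname(out$coef), batch, tolerance = 1e-8)
  expect_false(out$rank_deficient)

  # intercept-only, constant signal: residuals identically zero
  out0 <- nuisance_regress_series(rep(5, 20))
  expect_equal(out0$residuals, rep(0, 20))

  # exact linear combination: residuals vanish as samples accumulate
  y2 <- 1 + 2 * X[, 1] - 0.5 * X[, 2]
  out2 <- nuisance_regress_series(y2, X[, 1:2])
  expect_lt(max(abs(out2$residuals[-(1:4)])), 1e-8)

  # collinear regressors: minimum-norm solution, flagged
  Xc <- cbind(X[, 1], 2 * X[, 1])
  outc <- nuisance_regress_series(y2, Xc)
  expect_true(outc$rank_deficient)
  expect_true(all(is.finite(outc$residuals)))
})
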