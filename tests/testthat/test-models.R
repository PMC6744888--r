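test_that("utilities follow the power-law value function", {
  u <- utility(data.frame(gain = 6, safe = 4), alpha = 1)
  expect_equal(u$u_gamble, 3)
  u2 <- utility(data.frame(gain = 6, safe = 4), alpha = 0.5)
  expect_equal(u2$u_certain, 2)
  u3 <- utility(data.frame(gain = 17, safe = 0.3), alpha = 0)
  expect_equal(u3$u_gamble, 0.5)
  expect_equal(u3$u_certain, 1)
})

test_that("p_gamble is a stable logistic with the expected structure", {
  expect_equal(p_gamble(decision_params(1, 1, 0),
                        data.frame(gain = 6, safe = 3)), 0.5)
  # kappa = ln 3 at equal utilities and mu = 1 -> 0.75
  expect_equal(p_gamble(decision_params(1, 1, log(3)),
                        data.frame(gain = 6, safe = 3)), 0.75)
  # extreme arguments stay inside the open unit interval
  p_hi <- p_gamble(decision_params(1, 50, 5), data.frame(gain = 12, safe = 1))
  expect_lt(p_hi, 1)
  expect_gt(p_hi, 1 - 1e-9)
  # strictly increasing in kappa and in the utility difference
  ks <- seq(-2, 2, by = 0.25)
  ps <- vapply(ks, function(k) p_gamble(decision_params(0.8, 2, k),
                                        data.frame(gain = 9, safe = 4)),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  # symmetry: p(delta, kappa) = 1 - p(-delta, -kappa)
  p1 <- p_gamble(decision_params(1, 2, 0.3), data.frame(gain = 6, safe = 2))
  p2 <- p_gamble(decision_params(1, 2, -0.3), data.frame(gain = 6, safe = 4))
  expect_equal(p1, 1 - p2, tolerance = 1e-12)
})

test_that("the likelihood sums per-trial Bernoulli terms", {
  one <- data.frame(gain = 6, safe = 3, choice = 1L)
  expect_equal(neg_log_likelihood(decision_params(1, 1, 0), one,
                                  model_spec("pt")), log(2))
  # brute-force per-trial summation oracle on random trials
  set.seed(10)
  off <- offer_grid(100)
  pars <- decision_params(0.8, 2.5, 0.2)
  tr <- gen_agent_choices(off, pars, 1.7, seed = 11)
  p <- p_gamble(pars, tr)
  oracle <- -sum(log(ifelse(tr$choice == 1, p, 1 - p)))
  expect_equal(neg_log_likelihood(pars, tr, model_spec("pt_kappa")), oracle,
               tolerance = 1e-10)
  # order invariance
  perm <- tr[sample.int(nrow(tr)), ]
  expect_equal(neg_log_likelihood(pars, perm, model_spec("pt_kappa")),
               oracle, tolerance = 1e-10)
  # missed trials are excluded
  tr$choice[1:10] <- NA
  p_rest <- p[-(1:10)]
  oracle2 <- -sum(log(ifelse(tr$choice[-(1:10)] == 1, p_rest, 1 - p_rest)))
  expect_equal(neg_log_likelihood(pars, tr, model_spec("pt_kappa")), oracle2)
  # near-deterministic correct predictions drive the NLL toward 0
  det <- data.frame(gain = 12, safe = 1, choice = 1L)
  expect_lt(neg_log_likelihood(decision_params(1, 50, 0), det,
                               model_spec("pt")), 1e-6)
})

test_that("the bias model with kappa = 0 equals the base model exactly", {
  off <- offer_grid(60)
  tr <- gen_agent_choices(off, decision_params(0.9, 3, 0), 1.7, seed = 12)
  expect_identical(
    neg_log_likelihood(decision_params(0.7, 2, 0), tr, model_spec("pt")),
    neg_log_likelihood(decision_params(0.7, 2, 0), tr,
                       model_spec("pt_kappa")))
})

test_that("fit_mle recovers generating parameters and is seeded", {
  gen <- decision_params(0.9, 3, 0.5)
  tr <- gen_agent_choices(offer_grid(5000), gen, 1.7, seed = 2)
  f <- fit_mle(tr, model_spec("pt_kappa"), n_starts = 8, seed = 3)
  expect_lt(abs(f$params[["alpha"]] - 0.9), 0.1)
  expect_lt(abs(f$params[["kappa"]] - 0.5), 0.1)
  expect_lt(abs(f$params[["mu"]] - 3) / 3, 0.15)
  # optimality: fitted NLL no worse than at the generating parameters
  expect_lte(-f$log_likelihood,
             neg_log_likelihood(gen, tr, model_spec("pt_kappa")))
  # determinism
  f2 <- fit_mle(tr, model_spec("pt_kappa"), n_starts = 8, seed = 3)
  expect_identical(f$params, f2$params)
  expect_gte(f$n_starts_converged, 1L)
  # degenerate input
  expect_error(fit_mle(tr[0, ], model_spec("pt")), "no usable trials")
})

test_that("pseudo-R2 and BIC follow their definitions", {
  expect_equal(pseudo_r2(-50, n = 100), 1 - (-50) / (100 * log(0.5)))
  expect_equal(bic(-60, k = 2, n = 100), 2 * log(100) + 120)
  # chance-level model scores 0; perfect prediction scores 1
  expect_equal(pseudo_r2(100 * log(0.5), n = 100), 0)
  expect_equal(pseudo_r2(0, n = 100), 1)
  # adding a useless parameter raises BIC by log(n)
  expect_equal(bic(-60, k = 3, n = 100) - bic(-60, k = 2, n = 100), log(100))
  # fit_result fields are mutually consistent
  tr <- gen_agent_choices(offer_grid(200), decision_params(0.9, 3, 0), 1.7,
                          seed = 4)
  f <- fit_mle(tr, model_spec("pt"), n_starts = 5, seed = 5)
  expect_equal(f$pseudo_r2, pseudo_r2(f$log_likelihood, n = f$n_trials))
  expect_equal(f$bic, bic(f$log_likelihood, k = 2, n = f$n_trials))
  expect_lte(f$log_likelihood, 0)
})

test_that("BIC prefers the base model on base-generated data", {
  sel <- vapply(1:5, function(i) {
    tr <- gen_agent_choices(offer_grid(180, seed = i),
                            decision_params(0.9, 3, 0), 1.7, seed = 20 + i)
    tr$subject_id <- 1L
    tr$condition <- rep(c("low", "high"), length.out = nrow(tr))
    compare_models_bic(tr, c("pt", "pt_kappa", "pt_kappa_cond"),
                       n_starts = 4, seed = i)$best
  }, character(1))
  expect_true(all(sel == "pt"))
})

test_that("condition-wise fits detect a generated bias difference", {
  # identical data in both conditions -> identical fits
  tr <- gen_agent_choices(offer_grid(80), decision_params(0.9, 3, 0.2), 1.7,
                          seed = 30)
  both <- rbind(cbind(tr, condition = "low"), cbind(tr, condition = "high"))
  fb <- fit_by_condition(both, n_starts = 5, seed = 31)
  expect_equal(unname(fb$diff), rep(0, 3), tolerance = 1e-4)

  # cohorts generated with kappa_low - kappa_high = 0.4: the paired test on
  # fitted kappa differences is positive and significant in most cohorts
  hits <- vapply(1:10, function(i) {
    co <- gen_cohort(43, synthetic_config(seed = 400 + i),
                     mode = "behavioral")
    kd <- vapply(co, function(s) {
      fit_by_condition(s$trials, n_starts = 3,
                       seed = derive_seed(400 + i, s$subject_id))$diff[["kappa"]]
    }, numeric(1))
    tt <- t.test(kd)
    mean(kd) > 0 && tt$p.value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("alpha and mu differences center on zero under a null cohort", {
  # conditions share all generating parameters (kappa difference 0)
  diffs <- sapply(1:8, function(i) {
    co <- gen_cohort(10, synthetic_config(kappa_low = 0.1, kappa_high = 0.1,
                                          seed = 500 + i),
                     mode = "behavioral")
    rowMeans(vapply(co, function(s)
      fit_by_condition(s$trials, n_starts = 3,
                       seed = derive_seed(500 + i, s$subject_id))$diff,
      numeric(3)))
  })
  # across independent cohorts the mean paired differences straddle zero
  for (par in c("alpha", "mu", "kappa")) {
    m <- mean(diffs[par, ])
    se <- sd(diffs[par, ]) / sqrt(ncol(diffs))
    expect_lt(abs(m), 4 * se + 0.05)
  }
})
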