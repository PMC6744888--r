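# shared fixtures built in code

# flat (noise-free) BOLD series at a given level
flat_bold <- function(n = 200, level = 100, tr = 1.75) {
  bold_time_series(rep(level, n), tr)
}

# offer grid spanning the calibration design, repeated to n trials
offer_grid <- function(n, seed = 1) {
  base <- build_calibration_trials(design_config(), seed = seed)
  base[rep_len(seq_len(nrow(base)), n), c("gain", "safe")]
}

# feed a numeric vector through the streaming trigger without ever firing
# (elapsed = 0 keeps the ITI lockout active); returns the final state
warm_state <- function(x, cfg = trigger_config()) {
  st <- new_window_state(cfg)
  for (v in x) st <- trigger_step(st, v, cfg, 0)$state
  st
}

# paired-difference matrix (subjects x timepoints) from a generating function
sim_diff_matrix <- function(n_subj, n_time, effect = 0, effect_span = NULL) {
  d <- matrix(rnorm(n_subj * n_time), n_subj, n_time)
  if (!is.null(effect_span)) d[, effect_span] <- d[, effect_span] + effect
  d
}
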