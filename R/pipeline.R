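#' Configuration of a full synthetic-study run
#'
#' Bundles the module configurations, the cohort size, and the analysis
#' options for [run_all()]. Every default that corresponds to a protocol
#' constant (TR, window sizes, thresholds, divisor ladder, p-bins, epoch
#' window, permutation settings) is inherited from the module defaults.
#'
#' @param seed Master seed (mandatory; all stage and subject seeds derive
#'   from it).
#' @param n_subjects Cohort size. Default 43.
#' @param synthetic A [synthetic_config()] (its `seed` field is overridden
#'   by `seed`).
#' @param trigger A [trigger_config()].
#' @param design A [design_config()].
#' @param group Calibration group. Default 1.
#' @param n_per_condition Trials per condition per subject. Default 45.
#' @param fit_n_starts Optimizer starts per model fit. Default 10.
#' @param cluster A [cluster_test_config()].
#' @param n_boot Mediation bootstrap resamples. Default 2000.
#' @param epoch_window_s Peristimulus averaging window, seconds. Default
#'   `c(5.25, 10.5)`.
#' @param n_epoch_timepoints Volumes per epoch. Default 10.
#' @param write_bold Write each subject's BOLD series to the output
#'   directory. Default TRUE.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed,
                       n_subjects = 43L,
                       synthetic = synthetic_config(),
                       trigger = trigger_config_default(synthetic),
                       design = design_config(),
                       group = 1L,
                       n_per_condition = 45L,
                       fit_n_starts = 10L,
                       cluster = cluster_test_config(),
                       n_boot = 2000L,
                       epoch_window_s = c(5.25, 10.5),
                       n_epoch_timepoints = 10L,
                       write_bold = TRUE) {
  if (missing(seed)) stop("a master seed is mandatory", call. = FALSE)
  synthetic$seed <- as.integer(seed)
  validate_synthetic_config(synthetic)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 synthetic = synthetic, trigger = trigger, design = design,
                 group = as.integer(group),
                 n_per_condition = as.integer(n_per_condition),
                 fit_n_starts = as.integer(fit_n_starts), cluster = cluster,
                 n_boot = as.integer(n_boot),
                 epoch_window_s = epoch_window_s,
                 n_epoch_timepoints = as.integer(n_epoch_timepoints),
                 write_bold = isTRUE(write_bold)),
            class = "run_config")
}

#' Run the full synthetic study end to end
#'
#' Executes cohort generation (endogenous BOLD, trigger replay, offer
#' assembly, evoked coupling, choices), per-subject condition-wise model
#' fits, behavioral summaries, evoked-response statistics (percent signal
#' change, epoch averages, the cluster-extent permutation test), the
#' reaction-time regression, susceptibility correlations, and the multilevel
#' mediation of choice on prestimulus activity through the evoked response.
#' All artifacts are written to `out_dir` together with a deterministic
#' manifest (stage log with wall times goes to a separate `run.log`).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_all <- function(config, out_dir = tempfile("endofluct_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  t_all <- proc.time()[["elapsed"]]
  log_stage <- function(stage, t0) {
    cat(sprintf("%s\tseed=%d\telapsed_s=%.2f\n", stage, config$seed,
                proc.time()[["elapsed"]] - t0), file = log_path,
        append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_stage(name, t0)
    out
  }
  manifest <- list(package_version = as.character(utils::packageVersion("endofluct")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed, n_subjects = config$n_subjects,
                   group = config$group,
                   n_per_condition = config$n_per_condition)
  persist <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  on.exit(persist())

  cohort <- stage("simulate", gen_cohort(
    config$n_subjects, config$synthetic, mode = "full",
    group = config$group, n_per_condition = config$n_per_condition,
    trigger = config$trigger, design = config$design))
  trials <- cohort_trials(cohort)
  write_trials_tsv(trials, file.path(out_dir, "trials.tsv"))
  events <- do.call(rbind, lapply(cohort, function(s)
    cbind(subject_id = s$subject_id, s$events)))
  write_trials_tsv(events, file.path(out_dir, "events.tsv"))
  if (config$write_bold) {
    bold_dir <- file.path(out_dir, "bold")
    dir.create(bold_dir, showWarnings = FALSE)
    for (s in cohort)
      write_bold_tsv(s$bold, file.path(bold_dir,
                                       sprintf("sub-%02d.tsv", s$subject_id)))
  }

  fits <- stage("fit", lapply(cohort, function(s)
    fit_by_condition(s$trials, model_spec("pt_kappa"),
                     n_starts = config$fit_n_starts,
                     seed = derive_seed(config$seed, "fit", s$subject_id))))
  fit_tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(subject_id = cohort[[i]]$subject_id,
               alpha_low = f$low$params[["alpha"]],
               mu_low = f$low$params[["mu"]],
               kappa_low = f$low$params[["kappa"]],
               alpha_high = f$high$params[["alpha"]],
               mu_high = f$high$params[["mu"]],
               kappa_high = f$high$params[["kappa"]],
               pseudo_r2_low = f$low$pseudo_r2,
               pseudo_r2_high = f$high$pseudo_r2,
               kappa_diff = f$diff[["kappa"]])
  }))
  write_trials_tsv(fit_tab, file.path(out_dir, "fits.tsv"))
  jsonlite::write_json(fit_tab, file.path(out_dir, "fits.json"),
                       digits = NA, dataframe = "rows")

  beh <- stage("behavior", behavioral_summary(trials))
  insufficient_n <- is.null(beh$rate_test)
  write_trials_tsv(beh$per_subject, file.path(out_dir, "behavior.tsv"))

  # evoked responses: per-trial epoch averages and per-subject mean courses
  ev <- stage("evoked", {
    per_trial <- list()
    lo_courses <- hi_courses <- list()
    amp_diff <- numeric(length(cohort))
    for (i in seq_along(cohort)) {
      s <- cohort[[i]]
      tr_len <- (config$n_epoch_timepoints - 1L) * s$bold$tr_seconds
      tt_max <- max(bold_times(s$bold))
      ok <- s$trials$onset_s + tr_len <= tt_max
      d <- s$trials[ok, , drop = FALSE]
      raw <- extract_epochs(s$bold, d$onset_s, config$n_epoch_timepoints,
                            condition = d$condition)
      psc <- percent_signal_change(raw)
      amp <- epoch_average(psc, config$epoch_window_s)
      per_trial[[i]] <- cbind(d, evoked_psc = amp)
      lo_courses[[i]] <- colMeans(psc[d$condition == "low", , drop = FALSE])
      hi_courses[[i]] <- colMeans(psc[d$condition == "high", , drop = FALSE])
      amp_diff[i] <- mean(amp[d$condition == "low"]) -
        mean(amp[d$condition == "high"])
    }
    list(per_trial = do.call(rbind, per_trial),
         low = do.call(rbind, lo_courses), high = do.call(rbind, hi_courses),
         amp_diff = amp_diff)
  })
  write_trials_tsv(ev$per_trial, file.path(out_dir, "evoked_trials.tsv"))

  cluster <- NULL
  if (config$n_subjects >= 3L)
    cluster <- stage("cluster", cluster_extent_permutation_test(
      ev$low, ev$high, config$cluster,
      seed = derive_seed(config$seed, "cluster")))

  med <- NULL
  if (config$n_subjects >= 3L)
    med <- stage("mediation", multilevel_mediation(
      ev$per_trial$percentile, ev$per_trial$evoked_psc,
      ev$per_trial$choice, ev$per_trial$subject_id,
      n_boot = config$n_boot,
      seed = derive_seed(config$seed, "mediation")))

  rt_params <- stats::setNames(
    lapply(fits, function(f) f$low$decision_params),
    as.character(vapply(cohort, function(s) s$subject_id, numeric(1))))
  # a degenerate cohort (e.g. an always-gambling lone subject) can leave no
  # full-rank design; the run still completes with the stage marked absent
  rt <- tryCatch(rt_regression(trials, rt_params), error = function(e) NULL)
  if (!is.null(rt))
    write_trials_tsv(rt$per_subject, file.path(out_dir, "rt_coefficients.tsv"))

  sus <- NULL
  if (config$n_subjects >= 4L) {
    sus_df <- data.frame(rate_overall = beh$per_subject$rate_overall,
                         rate_diff = beh$per_subject$rate_diff,
                         kappa_diff = fit_tab$kappa_diff,
                         evoked_diff = ev$amp_diff)
    sus <- stage("correlations", rbind(
      susceptibility_correlations(sus_df, "rate_overall", "rate_diff",
                                  "spearman"),
      susceptibility_correlations(sus_df, "evoked_diff", "kappa_diff",
                                  "pearson")))
    write_trials_tsv(sus, file.path(out_dir, "correlations.tsv"))
  }

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        c("manifest.json", "run.log")))
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files

  group_summary <- list(
    gamble_rate_low = mean(beh$per_subject$rate_low),
    gamble_rate_high = mean(beh$per_subject$rate_high),
    gamble_rate_diff = mean(beh$per_subject$rate_diff),
    gamble_rate_p = if (insufficient_n) NA else beh$rate_test$p.value,
    rt_low = mean(beh$per_subject$rt_low),
    rt_high = mean(beh$per_subject$rt_high),
    rt_p = if (insufficient_n) NA else beh$rt_test$p.value,
    kappa_diff_mean = mean(fit_tab$kappa_diff),
    pseudo_r2_mean = mean(c(fit_tab$pseudo_r2_low, fit_tab$pseudo_r2_high)),
    evoked_diff_mean = mean(ev$amp_diff),
    min_cluster_p = if (is.null(cluster) || nrow(cluster$clusters) == 0L)
      NA else min(cluster$clusters$p_value),
    mediation_ab = if (is.null(med)) NA else
      med$paths["ab", "estimate"],
    mediation_ab_p = if (is.null(med)) NA else med$paths["ab", "p"],
    insufficient_n = insufficient_n)
  sign_patterns <- list(
    gamble_rate_low_gt_high = group_summary$gamble_rate_diff > 0,
    kappa_low_gt_high = group_summary$kappa_diff_mean > 0,
    rt_high_lt_low = group_summary$rt_high < group_summary$rt_low,
    evoked_low_gt_high = group_summary$evoked_diff_mean > 0,
    mediation_negative_via_evoked =
      !is.na(group_summary$mediation_ab) && group_summary$mediation_ab < 0)

  manifest$stage_seeds <- list(
    fit = derive_seed(config$seed, "fit", 1L),
    cluster = derive_seed(config$seed, "cluster"),
    mediation = derive_seed(config$seed, "mediation"))
  manifest$artifacts <- hashes
  manifest$group_summary <- group_summary
  manifest$sign_patterns <- sign_patterns
  manifest$complete <- TRUE
  persist()
  cat(sprintf("total\tseed=%d\telapsed_s=%.2f\n", config$seed,
              proc.time()[["elapsed"]] - t_all), file = log_path,
      append = TRUE)
  invisible(manifest)
}

#' Read a run configuration from a YAML file
#'
#' Builds a [run_config()] from a human-readable YAML file. Top-level keys
#' mirror the `run_config()` arguments; the nested mappings `synthetic`,
#' `trigger`, `design`, and `cluster` are passed to the corresponding
#' configuration constructors. `seed` is mandatory (a `--seed` style
#' override can be supplied via `seed_override`).
#'
#' @param path Path to a YAML file.
#' @param seed_override Optional integer replacing the file's seed.
#' @return A `run_config`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("seed: 3", "n_subjects: 2", "synthetic:", "  mu: 4"), f)
#' read_run_config(f)$synthetic$mu
#' @export
read_run_config <- function(path, seed_override = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed_override)) y$seed <- seed_override
  if (is.null(y$seed)) stop("the run configuration must set a seed",
                            call. = FALSE)
  args <- list(seed = as.integer(y$seed))
  for (nm in c("n_subjects", "group", "n_per_condition", "fit_n_starts",
               "n_boot", "epoch_window_s", "n_epoch_timepoints",
               "write_bold"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$synthetic))
    args$synthetic <- do.call(synthetic_config, y$synthetic)
  if (!is.null(y$trigger)) args$trigger <- do.call(trigger_config, y$trigger)
  if (!is.null(y$design)) args$design <- do.call(design_config, y$design)
  if (!is.null(y$cluster))
    args$cluster <- do.call(cluster_test_config, y$cluster)
  do.call(run_config, args)
}
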