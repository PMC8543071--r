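# Orchestration: simulate -> preprocess -> analyze -> report, driven by one
# JSON-serializable config, with a manifest of input/output hashes so a run
# is fully determined by (config, input data).

#' Pipeline configuration
#'
#' Bundles the design spec, generative parameters, preprocessing thresholds
#' and analysis options. Serializes losslessly to JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param design a [design_spec()].
#' @param generation a [generative_params()].
#' @param thresholds preprocessing thresholds (see [filter_trials()]) plus
#'   `participant_max_rejected` for the exclusion fraction.
#' @param analysis list: `bias_step`, `bias_width`, `mixture` (a
#'   [mixture_opts()]), `bonferroni_m` (named family sizes).
#' @param master_seed master seed; overrides `design$rng_seed` when set.
#' @return list of class `wm_pipeline_config`.
#' @export
pipeline_config <- function(design = design_spec(),
                            generation = generative_params(),
                            thresholds = list(probe_rt_ms = 5000, rt_sd = 2.5,
                                              dial_ms = 4000, interrupter_ms = 1000,
                                              participant_max_rejected = 0.10),
                            analysis = list(bias_step = 5, bias_width = 45,
                                            mixture = mixture_opts(),
                                            bonferroni_m = list(default = 1)),
                            master_seed = NULL) {
  if (!is.null(master_seed)) design$rng_seed <- as.integer(master_seed)
  structure(list(design = design, generation = generation,
                 thresholds = thresholds, analysis = analysis),
            class = "wm_pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `wm_pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(
    design = do.call(design_spec, raw$design),
    generation = do.call(generative_params,
                         utils::modifyList(raw$generation,
                                           list(contamination_rates = as.list(raw$generation$contamination_rates),
                                                rt_probe_params = as.list(raw$generation$rt_probe_params),
                                                rt_dial_params = as.list(raw$generation$rt_dial_params),
                                                rt_interrupter_params = as.list(raw$generation$rt_interrupter_params)))),
    thresholds = as.list(raw$thresholds),
    analysis = list(bias_step = raw$analysis$bias_step,
                    bias_width = raw$analysis$bias_width,
                    mixture = do.call(mixture_opts, as.list(raw$analysis$mixture)),
                    bonferroni_m = as.list(raw$analysis$bonferroni_m)))
  cfg
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Simulate a cohort to disk
#'
#' Writes the trial CSV and a config snapshot into `out_dir`, logging the
#' seed and per-participant trial counts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, list with `cohort_path`, `config_path`, `n_trials`.
#' @export
cmd_simulate <- function(config = pipeline_config(), out_dir = ".") {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_io(paste("cmd_simulate: cannot create", out_dir))
  cohort <- simulate_cohort(config$design, config$generation)
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)
  config_path <- file.path(out_dir, "config.json")
  write_pipeline_config(config, config_path)
  message(sprintf("simulate: seed %d, %d participants x %d trials -> %s",
                  config$design$rng_seed, config$design$n_participants,
                  config$design$n_blocks * config$design$trials_per_block,
                  cohort_path))
  invisible(list(cohort_path = cohort_path, config_path = config_path,
                 n_trials = nrow(cohort)))
}

#' Run the full analysis pipeline on a trial CSV
#'
#' Stages: trial filtering and participant exclusion; per-condition
#' reproduction-error summaries; swap-mixture table; bias curves, equated
#' bias and the attraction test; repeated-measures ANOVAs (interference
#' presence x type; predictability x type x onset; interrupter RT
#' predictability x onset; swap rate 2 x 2; equated bias 2 x 2). Every
#' output file is listed in a JSON manifest with md5 hashes.
#'
#' @param input path to a trial CSV in the cohort dialect.
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, the manifest list (also written as JSON).
#' @export
cmd_analyze <- function(input, config = pipeline_config(), out_dir = ".") {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_io(paste("cmd_analyze: cannot create", out_dir))
  records <- read_cohort(input)
  res <- analyze_cohort(records, config)
  paths <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  write_rejection_log(res$rejection_log, file.path(out_dir, "rejections.csv"))
  paths[["rejections.csv"]] <- file.path(out_dir, "rejections.csv")
  paths[["rejections.json"]] <- file.path(out_dir, "rejections.json")
  emit_csv(res$participants, "participants.csv")
  emit_csv(res$summary_presence_type, "summary_presence_type.csv")
  emit_csv(res$summary_pred_type_onset, "summary_pred_type_onset.csv")
  emit_csv(res$swap_table, "swap_table.csv")
  emit_csv(res$equated_bias, "equated_bias.csv")
  emit_csv(res$bias_curve_cohort, "bias_curve_cohort.csv")
  emit_csv(res$anova_tables, "anova_tables.csv")
  ttests <- data.frame(test = "attraction_vs_zero",
                       t = res$attraction$t, df = res$attraction$df,
                       p_raw = res$attraction$p_raw,
                       p_bonferroni = res$attraction$p_bonferroni,
                       cohen_d = res$attraction$cohen_d)
  emit_csv(ttests, "ttests.csv")
  manifest <- list(input = unname(tools::md5sum(input)),
                   n_trials_in = nrow(records),
                   n_trials_kept = nrow(res$kept),
                   participants_in = length(unique(records$participant_id)),
                   participants_kept = length(res$kept_ids),
                   outputs = lapply(paths, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("analyze: %d/%d trials kept, %d/%d participants kept",
                  manifest$n_trials_kept, manifest$n_trials_in,
                  manifest$participants_kept, manifest$participants_in))
  invisible(manifest)
}

#' In-memory cohort analysis (the engine behind [cmd_analyze()])
#'
#' @param records trial records.
#' @param config a [pipeline_config()].
#' @return list with kept records, rejection log, condition summaries, swap
#'   table, bias outputs and ANOVA tables.
#' @export
analyze_cohort <- function(records, config = pipeline_config()) {
  th <- config$thresholds
  flt <- filter_trials(records, th)
  parts <- exclude_participants(flt$log,
                                th$participant_max_rejected %||% 0.10)
  kept_ids <- attr(parts, "kept_ids")
  kept <- flt$kept[flt$kept$participant_id %in% kept_ids, , drop = FALSE]
  kept <- kept[!is.na(kept$report_angle), , drop = FALSE]

  sum_pt <- condition_means(kept, c("interference_present", "interference_type"))
  sum_pto <- condition_means(kept[kept$interference_present, ],
                             c("predictability", "interference_type", "onset_ms"))
  anovas <- list()
  add_anova <- function(label, tab) {
    tab$analysis <- label
    anovas[[label]] <<- tab[, c("analysis", setdiff(names(tab), "analysis"))]
  }
  add_anova("error_presence_x_type",
            rm_anova(sum_pt, "mean_abs_error",
                     c("interference_present", "interference_type"),
                     "participant_id"))
  add_anova("error_pred_x_type_x_onset",
            rm_anova(sum_pto, "mean_abs_error",
                     c("predictability", "interference_type", "onset_ms"),
                     "participant_id"))
  # interrupter RT: interruption interference trials only
  irt <- condition_means(
    kept[kept$interference_type == "interruption" & kept$interference_present, ],
    c("predictability", "onset_ms"))
  add_anova("interrupter_rt_pred_x_onset",
            rm_anova(irt, "mean_interrupter_rt",
                     c("predictability", "onset_ms"), "participant_id"))

  swaps <- swap_table(kept, opts = config$analysis$mixture)
  add_anova("swap_pred_x_type",
            rm_anova(swaps, "p_nontarget",
                     c("predictability", "interference_type"), "participant_id"))

  eq <- equated_bias(kept)
  add_anova("equated_bias_pred_x_type",
            rm_anova(eq, "equated_bias",
                     c("predictability", "interference_type"), "participant_id"))
  eq_all <- equated_bias(kept, cells = character(0))
  attraction <- attraction_test(eq_all$equated_bias)

  # cohort-level bias curve: mean over participant curves per window center
  int_kept <- kept[kept$interference_present, , drop = FALSE]
  err <- demean_signed_errors(kept)[kept$interference_present]
  delta <- signed_diff(int_kept$interference_angle, int_kept$target_angle)
  curves <- lapply(split(seq_len(nrow(int_kept)), int_kept$participant_id),
                   function(i) compute_bias_curve(err[i], delta[i],
                                                  config$analysis$bias_step,
                                                  config$analysis$bias_width))
  allc <- do.call(rbind, curves)
  cohort_curve <- stats::aggregate(value ~ center, data = allc, FUN = mean)
  cohort_curve$n_participants <- stats::aggregate(value ~ center, data = allc,
                                                  FUN = length)$value

  list(kept = kept, rejection_log = flt$log, participants = parts,
       kept_ids = kept_ids,
       summary_presence_type = sum_pt, summary_pred_type_onset = sum_pto,
       interrupter_rt = irt, swap_table = swaps, equated_bias = eq,
       attraction = attraction, bias_curve_cohort = cohort_curve,
       anova_tables = do.call(rbind, anovas))
}

# Expected signed error of a swap trial given delta: the report sits at the
# interfering orientation plus von Mises noise, so the signed error is the
# wrapped sum delta + noise; near +/-90 wrapping pulls the expectation toward
# 0. Computed by quadrature over the noise density.
expected_swap_error <- function(delta, kappa, ngrid = 720) {
  u <- seq(-pi + pi / ngrid, pi - pi / ngrid, length.out = ngrid)
  w <- exp(kappa * cos(u)); w <- w / sum(w)
  ud <- u * 90 / pi
  uniq <- unique(delta)
  ev <- vapply(uniq, function(d) sum(wrap_orientation(d + ud) * w), numeric(1))
  ev[match(delta, uniq)]
}

#' Parameter-recovery study
#'
#' Simulates `n_seeds` independent sets of interference trials from the
#' generative model, refits the swap mixture and the equated bias, and
#' reports each estimator's error against the generative truth. The truth
#' for the mixture proportions is the marginal mixture implied by the
#' generator's conditional structure: `p_uniform = p_guess`,
#' `p_nontarget = (1 - p_guess) * p_swap`. The equated-bias truth is the
#' estimator's estimand under the full generative model: the sinusoidal
#' attraction on target-centred trials plus the wrap-aware expected pull of
#' swap trials, weighted by the component probabilities (guesses contribute
#' zero on average).
#'
#' @param params a [generative_params()].
#' @param n_seeds number of independent replicates.
#' @param n_trials interference trials per replicate.
#' @param base_seed seed for the first replicate; replicate i uses
#'   `base_seed + i - 1`.
#' @param opts a [mixture_opts()].
#' @return data.frame, one row per seed: estimates, truths, errors; mean
#'   absolute errors in `attr(, "summary")`.
#' @export
cmd_recover <- function(params = generative_params(), n_seeds = 20,
                        n_trials = 5000, base_seed = 1L,
                        opts = mixture_opts()) {
  if (n_seeds < 1) stop_invalid_input("cmd_recover: n_seeds must be >= 1")
  grid <- c(-seq(85, 5, by = -5), seq(5, 85, by = 5))
  true_pu <- params$p_guess
  true_pnt <- (1 - params$p_guess) * params$p_swap
  rows <- lapply(seq_len(n_seeds), function(i) {
    withr_seed(as.integer(base_seed) + i - 1L, {
      targets <- sample(grid, n_trials, replace = TRUE)
      nts <- sample(grid, n_trials, replace = TRUE)
      reports <- simulate_reports(targets, nts, params)
      fit <- fit_mixture(reports, targets, nts, opts)
      delta <- signed_diff(nts, targets)
      e <- signed_diff(reports, targets)
      e <- e - mean(e)
      eq <- (mean(e[delta > 0]) - mean(e[delta < 0])) / 2
      cond_bias <- (1 - params$p_guess) *
        ((1 - params$p_swap) * params$bias_amplitude_A * sin(2 * delta * pi / 180) +
           params$p_swap * expected_swap_error(delta, params$kappa_base))
      true_eq <- (mean(cond_bias[delta > 0]) - mean(cond_bias[delta < 0])) / 2
      data.frame(seed = base_seed + i - 1L,
                 p_nontarget = fit$p_nontarget, p_uniform = fit$p_uniform,
                 kappa = fit$kappa, equated_bias = eq,
                 true_p_nontarget = true_pnt, true_p_uniform = true_pu,
                 true_kappa = params$kappa_base, true_equated_bias = true_eq)
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    mae_p_nontarget = mean(abs(out$p_nontarget - out$true_p_nontarget)),
    mae_p_uniform = mean(abs(out$p_uniform - out$true_p_uniform)),
    rel_mae_kappa = mean(abs(out$kappa - out$true_kappa) / out$true_kappa),
    mean_equated_bias_error = mean(out$equated_bias - out$true_equated_bias))
  out
}
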