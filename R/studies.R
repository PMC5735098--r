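#' Validation studies over synthetic cohorts
#'
#' These functions package the pipeline's self-checks as reusable
#' computations over seed grids: planted-clone recovery by the frequency
#' ranking, null calibration of the selection + classification chain, power
#' of the full pipeline at a planted effect, and recovery of a synthetic
#' clinical coupling. The analysis drivers, test suite and acceptance script
#' all call these.
#'
#' @name validation-studies
NULL

# shared worker: simulate -> preprocess -> split -> resample for one seed
cohort_to_selection <- function(seed, n_clones, effect_size, n_planted_up,
                                n_planted_down, n_runs, span = 0.3,
                                fdr_threshold = 0.01,
                                covariate_coupling = NULL) {
  cfg <- cohort_config(n_clones = n_clones, effect_size = effect_size,
                       n_planted_up = n_planted_up,
                       n_planted_down = n_planted_down,
                       covariate_coupling = covariate_coupling,
                       seed = seed)
  cohort <- generate_cohort(cfg)
  prep <- preprocess_cohort(cohort$spots, span = span)
  plan <- make_split_plan(cohort$meta, n_runs = n_runs, seed = seed + 1L)
  records <- run_resampling(prep$matrix, plan, fdr_threshold = fdr_threshold)
  list(cohort = cohort, matrix = prep$matrix, plan = plan, records = records,
       freq = frequency_rank(records))
}

#' @describeIn validation-studies For each seed, generate a cohort with
#'   `n_planted` clones at standardized effect `effect_size`, run the
#'   frequency ranking, and count how many planted clones land in the top
#'   `n_planted` ranks.
#' @param seeds integer vector of cohort seeds.
#' @param n_clones clones per cohort.
#' @param effect_size planted standardized effect.
#' @param n_planted_up,n_planted_down planted clone counts.
#' @param n_runs resampling runs per seed.
#' @param fdr_threshold per-run FDR threshold.
#' @return `planted_recovery_study()`: data.frame with `seed`, `n_planted`,
#'   `recovered` (planted clones in the top `n_planted` ranks).
#' @export
planted_recovery_study <- function(seeds, n_clones = 1070L, effect_size = 1.5,
                                   n_planted_up = 6L, n_planted_down = 14L,
                                   n_runs = 200L, fdr_threshold = 0.01) {
  n_planted <- n_planted_up + n_planted_down
  out <- lapply(seeds, function(s) {
    sel <- cohort_to_selection(s, n_clones, effect_size, n_planted_up,
                               n_planted_down, n_runs,
                               fdr_threshold = fdr_threshold,
                               covariate_coupling = list())
    planted <- c(sel$cohort$truth$planted_up, sel$cohort$truth$planted_down)
    top <- sel$freq$clone_id[seq_len(n_planted)]
    data.frame(seed = s, n_planted = n_planted,
               recovered = length(intersect(top, planted)))
  })
  do.call(rbind, out)
}

#' @describeIn validation-studies Full-pipeline behaviour with
#'   `effect_size = 0`: mean validation AUC (expected near 0.5) and mean
#'   per-run significant-clone count (expected well below
#'   `2 * fdr_threshold * n_clones` under the complete null).
#' @param panel_size panel size for the classification stage.
#' @return `null_calibration_study()`: data.frame with `seed`,
#'   `mean_val_auc`, `mean_sig_count`.
#' @export
null_calibration_study <- function(seeds, n_clones = 200L, n_runs = 50L,
                                   panel_size = 20L, fdr_threshold = 0.01) {
  out <- lapply(seeds, function(s) {
    sel <- cohort_to_selection(s, n_clones, effect_size = 0,
                               n_planted_up = 0L, n_planted_down = 0L,
                               n_runs = n_runs, fdr_threshold = fdr_threshold,
                               covariate_coupling = list())
    panel <- utils::head(sel$freq$clone_id, panel_size)
    perf <- evaluate_validation(sel$matrix, sel$plan, panel)
    data.frame(seed = s,
               mean_val_auc = mean(perf$per_run$auc),
               mean_sig_count = mean(colSums(sel$records$significant)))
  })
  do.call(rbind, out)
}

#' @describeIn validation-studies Full-pipeline power at a planted effect:
#'   mean validation AUC of the top-`panel_size` panel and the accumulating
#'   mean test AUC at panel sizes 1 and `panel_size`.
#' @return `power_study()`: data.frame with `seed`, `mean_val_auc`,
#'   `accum_auc_1`, `accum_auc_k`.
#' @export
power_study <- function(seeds, n_clones = 400L, effect_size = 2,
                        n_planted_up = 6L, n_planted_down = 14L,
                        n_runs = 100L, panel_size = 20L) {
  out <- lapply(seeds, function(s) {
    sel <- cohort_to_selection(s, n_clones, effect_size, n_planted_up,
                               n_planted_down, n_runs,
                               covariate_coupling = list())
    panel <- select_top(sel$freq, k = panel_size)
    perf <- evaluate_validation(sel$matrix, sel$plan, panel)
    accum <- accumulating_performance(sel$matrix, sel$plan, sel$freq,
                                      max_clones = panel_size)
    data.frame(seed = s, mean_val_auc = mean(perf$per_run$auc),
               accum_auc_1 = mean(accum[1L, ]),
               accum_auc_k = mean(accum[panel_size, ]))
  })
  do.call(rbind, out)
}

#' @describeIn validation-studies Recovery of the synthetic sweat-chloride
#'   coupling: per seed, whether the best 5-clone combination for sweat
#'   chloride has negative r and how many of the truly coupled clones it
#'   contains.
#' @param set_size combination size.
#' @return `coupling_recovery_study()`: data.frame with `seed`, `combo_r`,
#'   `n_coupled_recovered`, `panel_has_coupled` (coupled clones present in
#'   the selected panel).
#' @export
coupling_recovery_study <- function(seeds, n_clones = 200L, effect_size = 1.5,
                                    n_runs = 40L, panel_size = 20L,
                                    set_size = 5L) {
  out <- lapply(seeds, function(s) {
    sel <- cohort_to_selection(s, n_clones, effect_size,
                               n_planted_up = 6L, n_planted_down = 14L,
                               n_runs = n_runs)
    k <- min(panel_size, sum(sel$freq$frequency > 0L))
    panel <- select_top(sel$freq, k = k)
    rep_ <- correlate_panel(sel$matrix, panel, sel$cohort$meta,
                            covariates = "sweat_chloride",
                            set_size = set_size)
    coupled <- sel$cohort$truth$couplings$sweat_chloride$clones
    combo <- strsplit(rep_$combo_clones, "\\|")[[1L]]
    data.frame(seed = s, combo_r = rep_$combo_r,
               n_coupled_recovered = length(intersect(combo, coupled)),
               panel_has_coupled = length(intersect(panel, coupled)))
  })
  do.call(rbind, out)
}
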