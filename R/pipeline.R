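#' Default end-to-end pipeline configuration
#'
#' One list holding the cohort generator settings and every analysis knob,
#' with the study's defaults: 1000 resampling runs, FDR threshold 0.01,
#' panel size 20, accumulating curve to 100 clones, combination size 5.
#' A single integer `master_seed` deterministically spawns per-stage seeds.
#'
#' @param master_seed integer master seed.
#' @param ... overrides for any top-level field (`cohort` overrides are given
#'   as a list merged into the cohort configuration).
#' @return nested configuration list.
#' @export
pipeline_config <- function(master_seed = 1L, ...) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    cohort = list(),           # overrides for cohort_config()
    span = 0.3,
    n_runs = 1000L,
    fdr_threshold = 0.01,
    panel_size = 20L,
    max_accum = 100L,
    set_size = 5L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("pipeline_config: unknown field '", nm, "'")
    cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

# deterministic per-stage seeds below 2^31 from one master seed
stage_seeds <- function(master_seed) {
  base <- (as.numeric(master_seed) * 48271) %% (2^31 - 1)
  s <- (base + 10007 * (1:3)) %% (2^31 - 1)
  list(cohort = as.integer(s[1L]), split = as.integer(s[2L]),
       extra = as.integer(s[3L]))
}

#' Run the full pipeline end to end
#'
#' simulate -> preprocess -> select -> classify -> explore -> correlate, with
#' every artifact written under one output directory and a JSON manifest
#' recording the configuration, per-stage seeds, file digests and timings.
#' Deterministic given `config$master_seed`: two runs with the same seed
#' produce identical outputs (manifest timings aside).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); pass `NULL` to skip
#'   writing files and return results only.
#' @return list with `matrix`, `plan`, `freq`, `panel`, `accum` (panel-size x
#'   run AUCs), `validation` (performance summary), `pca`, `heatmap`,
#'   `clinical`, `truth`, `manifest`.
#' @export
run_full <- function(config = pipeline_config(), out_dir = NULL) {
  seeds <- stage_seeds(config$master_seed)
  timings <- c()
  stage_name <- NULL
  tic <- function(name, expr) {
    stage_name <<- name
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    list(val = val, secs = proc.time()[["elapsed"]] - t0)
  }

  st <- tic("simulate", generate_cohort(do.call(cohort_config,
                                    c(config$cohort, list(seed = seeds$cohort)))))
  cohort <- st$val; timings["simulate"] <- st$secs

  st <- tic("preprocess", preprocess_cohort(cohort$spots, span = config$span))
  prep <- st$val; timings["preprocess"] <- st$secs

  st <- tic("select", {
    plan <- make_split_plan(cohort$meta, n_runs = config$n_runs,
                            seed = seeds$split)
    records <- run_resampling(prep$matrix, plan,
                              fdr_threshold = config$fdr_threshold)
    freq <- frequency_rank(records)
    panel <- select_top(freq, k = config$panel_size)
    list(plan = plan, records = records, freq = freq, panel = panel)
  })
  sel <- st$val; timings["select"] <- st$secs

  st <- tic("classify", {
    max_accum <- min(config$max_accum, sum(sel$freq$frequency > 0L),
                     nrow(sel$freq))
    accum <- accumulating_performance(prep$matrix, sel$plan, sel$freq,
                                      max_clones = max_accum)
    validation <- evaluate_validation(prep$matrix, sel$plan, sel$panel)
    list(accum = accum, validation = validation)
  })
  cls <- st$val; timings["classify"] <- st$secs

  st <- tic("explore", {
    pca <- pca_scores(t(prep$matrix[sel$panel, , drop = FALSE]),
                      n_components = 2L)
    hm <- heatmap_order(prep$matrix, sel$panel)
    list(pca = pca, heatmap = hm)
  })
  exp_ <- st$val; timings["explore"] <- st$secs

  st <- tic("correlate", correlate_panel(prep$matrix, sel$panel, cohort$meta,
                            set_size = config$set_size))
  clinical <- st$val; timings["correlate"] <- st$secs

  res <- list(matrix = prep$matrix, plan = sel$plan, freq = sel$freq,
              panel = sel$panel, accum = cls$accum,
              validation = cls$validation, pca = exp_$pca,
              heatmap = exp_$heatmap, clinical = clinical,
              truth = cohort$truth)

  manifest <- list(config = config, seeds = seeds,
                   version = as.character(utils::packageVersion("seroselect")),
                   timings_s = as.list(round(timings, 3)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- write_pipeline_outputs(res, cohort, out_dir)
    manifest$files <- lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res$manifest <- manifest
  res
}

write_pipeline_outputs <- function(res, cohort, out_dir) {
  fp <- function(x) file.path(out_dir, x)
  mat_dt <- data.table::data.table(clone_id = rownames(res$matrix))
  for (j in colnames(res$matrix)) mat_dt[[j]] <- res$matrix[, j]
  data.table::fwrite(mat_dt, fp("matrix.tsv"), sep = "\t")
  data.table::fwrite(cohort$meta, fp("meta.tsv"), sep = "\t", na = "")
  data.table::fwrite(res$freq, fp("frequency_table.tsv"), sep = "\t")
  writeLines(res$panel, fp("panel.txt"))
  acc <- data.table::data.table(panel_size = seq_len(nrow(res$accum)),
                                mean_auc = rowMeans(res$accum))
  data.table::fwrite(acc, fp("accumulating_auc.tsv"), sep = "\t")
  data.table::fwrite(res$validation$per_run, fp("validation_per_run.tsv"),
                     sep = "\t")
  jsonlite::write_json(res$validation$summary, fp("validation_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pca_dt <- data.table::data.table(sample_id = colnames(res$matrix),
                                   PC1 = res$pca$scores[, 1L],
                                   PC2 = res$pca$scores[, 2L])
  data.table::fwrite(pca_dt, fp("pca_scores.tsv"), sep = "\t")
  jsonlite::write_json(list(variance_explained = res$pca$variance_explained,
                            heatmap_rows = res$heatmap$row_order,
                            heatmap_cols = res$heatmap$col_order),
                       fp("explore.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  data.table::fwrite(res$clinical, fp("clinical_correlations.tsv"), sep = "\t")
  c(fp("matrix.tsv"), fp("meta.tsv"), fp("frequency_table.tsv"),
    fp("panel.txt"), fp("accumulating_auc.tsv"), fp("validation_per_run.tsv"),
    fp("validation_summary.json"), fp("pca_scores.tsv"), fp("explore.json"),
    fp("clinical_correlations.tsv"))
}
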