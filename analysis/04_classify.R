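#!/usr/bin/env Rscript
# Gaussian naive Bayes classification of CF vs non-CF: accumulating-clone
# test-set AUC curves (most frequent clone first, one added at a time) and
# validation-set performance of the top-20 panel models at each run's
# Youden-optimal test threshold.
suppressMessages(library(seroselect))
suppressMessages(library(data.table))

seed <- 20260103L   # same split plan as 03_select.R
n_runs <- 200L
max_accum <- 100L

cohort <- read_cohort("results/cohort")
m <- as.data.frame(fread("results/matrix.tsv"))
mat <- as.matrix(m[, -1]); rownames(mat) <- m$clone_id
freq <- as.data.frame(fread("results/frequency_table.tsv"))
panel <- readLines("results/panel.txt")

plan <- make_split_plan(cohort$meta, n_runs = n_runs, seed = seed)
max_accum <- min(max_accum, sum(freq$frequency > 0L))
accum <- accumulating_performance(mat, plan, freq, max_clones = max_accum)
perf <- evaluate_validation(mat, plan, panel)

fwrite(data.table(panel_size = seq_len(nrow(accum)),
                  mean_test_auc = rowMeans(accum),
                  q025 = apply(accum, 1, quantile, 0.025),
                  q975 = apply(accum, 1, quantile, 0.975)),
       "results/accumulating_auc.tsv", sep = "\t")
fwrite(perf$per_run, "results/validation_per_run.tsv", sep = "\t")
jsonlite::write_json(perf$summary, "results/validation_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

s <- perf$summary
message(sprintf("validation (n models = %d): mean AUC %.3f [%.3f, %.3f], sensitivity %.3f, specificity %.3f",
                n_runs, s$auc["mean"], s$auc["q025"], s$auc["q975"],
                s$sensitivity["mean"], s$specificity["mean"]))
message(sprintf("accumulating test AUC: %.3f at 1 clone -> %.3f at %d clones",
                rowMeans(accum)[1], rowMeans(accum)[nrow(accum)],
                nrow(accum)))
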