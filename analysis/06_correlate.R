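#!/usr/bin/env Rscript
# Clinical correlation of the selected panel over CF samples: best single
# clone per covariate by |Spearman rho| and best 5-clone mean-aggregate by
# |Pearson r| from the exhaustive C(20, 5) search.
suppressMessages(library(seroselect))
suppressMessages(library(data.table))

cohort <- read_cohort("results/cohort")
m <- as.data.frame(fread("results/matrix.tsv"))
mat <- as.matrix(m[, -1]); rownames(mat) <- m$clone_id
panel <- readLines("results/panel.txt")

report <- correlate_panel(mat, panel, cohort$meta, set_size = 5L)
fwrite(report, "results/clinical_correlations.tsv", sep = "\t")

for (i in seq_len(nrow(report))) {
  with(report[i, ], message(sprintf(
    "%s: single clone %s rho = %.2f (p = %.3g); 5-clone set r = %.2f (p = %.3g)",
    covariate, single_clone, single_rho, single_p, combo_r, combo_p)))
  truth_cl <- cohort$truth$couplings[[report$covariate[i]]]$clones
  if (!is.null(truth_cl)) {
    got <- strsplit(report$combo_clones[i], "|", fixed = TRUE)[[1]]
    message(sprintf("  (%d of %d truly coupled clones in the selected set)",
                    length(intersect(got, truth_cl)), length(truth_cl)))
  }
}
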