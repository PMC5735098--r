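#!/usr/bin/env Rscript
# Unsupervised structure of the cohort: PCA of all clones and of the
# selected panel (variance explained per component), hierarchical
# clustering, and the heatmap row/column ordering of the panel submatrix.
suppressMessages(library(seroselect))
suppressMessages(library(data.table))

cohort <- read_cohort("results/cohort")
m <- as.data.frame(fread("results/matrix.tsv"))
mat <- as.matrix(m[, -1]); rownames(mat) <- m$clone_id
panel <- readLines("results/panel.txt")

pca_all <- pca_scores(t(mat), n_components = 2L)
pca_panel <- pca_scores(t(mat[panel, ]), n_components = 2L)
hm <- heatmap_order(mat, panel)

fwrite(data.table(sample_id = colnames(mat),
                  group = cohort$meta$group[match(colnames(mat),
                                                  cohort$meta$sample_id)],
                  PC1_all = pca_all$scores[, 1], PC2_all = pca_all$scores[, 2],
                  PC1_panel = pca_panel$scores[, 1],
                  PC2_panel = pca_panel$scores[, 2]),
       "results/pca_scores.tsv", sep = "\t")
jsonlite::write_json(
  list(variance_all_clones = pca_all$variance_explained,
       variance_panel = pca_panel$variance_explained,
       heatmap_rows = hm$row_order, heatmap_cols = hm$col_order),
  "results/explore.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf("PCA, all %d clones: PC1 %.2f / PC2 %.2f of variance",
                nrow(mat), pca_all$variance_explained[1],
                pca_all$variance_explained[2]))
message(sprintf("PCA, %d-clone panel: PC1 %.2f / PC2 %.2f of variance",
                length(panel), pca_panel$variance_explained[1],
                pca_panel$variance_explained[2]))
# how block-like is the heatmap column order?
grp <- cohort$meta$group[match(hm$col_order, cohort$meta$sample_id)]
cf_pos <- which(grp == "CF")
message(sprintf("heatmap: %d CF columns span positions %d-%d of %d",
                length(cf_pos), min(cf_pos), max(cf_pos), length(grp)))
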