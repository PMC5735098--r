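#!/usr/bin/env Rscript
# Generate the synthetic immunoscreening cohort the downstream analyses use:
# 1070 phage clones in quintuplicate on 111 arrays (49 healthy controls,
# 31 CF, 31 lung cancer), 20 planted differential clones (6 up / 14 down in
# CF at d = 1.5) and three clinical covariates coupled to planted clones
# with negative slopes. Writes the GenePix-style spot table, metadata and
# ground truth under results/cohort/.
suppressMessages(library(seroselect))

seed <- 20260101L
out <- "results/cohort"

cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
files <- write_cohort(cohort, out)

message(sprintf("cohort: %d spot rows (%d clones x %d samples x %d replicates)",
                nrow(cohort$spots), cfg$n_clones,
                cfg$n_healthy + cfg$n_cf + cfg$n_lc, cfg$n_replicates))
message(sprintf("planted: %d up, %d down (latent shift %.2f M units)",
                length(cohort$truth$planted_up),
                length(cohort$truth$planted_down), cohort$truth$shift_m))
message("written: ", paste(basename(files), collapse = ", "))
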