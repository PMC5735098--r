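# seroselect

Resampling-based serological biomarker discovery for two-color
phage-antigen microarrays.

## The problem

Phage-display antigen arrays probe patient sera for IgG reactivity against
~1000 displayed peptides, printed in quintuplicate, with a red channel
(Cy5 anti-human IgG: serum reactivity) and a green channel (Cy3
anti-capsid: spot loading). Given spot-level quantifications from a cohort
of cystic fibrosis (CF), healthy control (HC) and lung cancer (LC) sera,
the analysis must (i) normalize the two-channel intensities into a
clones × samples matrix of M = log2(red/green) values, (ii) select a small
panel of clones that discriminate CF, (iii) quantify classification
performance without overfitting, and (iv) relate panel reactivity to
clinical severity (sweat chloride, BMI, FEV1 % predicted).

## The method

* **Preprocessing** — per array and channel, background is corrected under
  the normexp convolution (observed = Normal(μ, σ²) + Exp(mean α), ML fit;
  corrected value E[signal | observed], strictly positive); within-array
  loess of M on A removes dye bias; between-array "scale" normalization
  equalizes the median absolute deviations; quintuplicates collapse by
  median.
* **Selection** — a fixed validation hold-out (10 CF / 16 HC / 16 LC) is
  set aside; the remaining samples are split into train/test 1000 times
  (10 + 11 CF, 16 + 17 HC, 0 + 15 LC). Per split, each clone is tested
  CF-train vs HC-train with a pooled t-test under Benjamini–Hochberg FDR
  < 0.01; clones are ranked by their frequency of significance over all
  splits; the top 20 form the panel.
* **Classification** — per split, a Gaussian naive Bayes model on the
  panel (trained CF vs HC) scores the split's test set (CF vs HC ∪ LC) and
  the fixed validation set; the operating threshold maximizes Youden's J
  on test scores; performance is summarized as mean ± empirical 2.5/97.5%
  quantiles of AUC, sensitivity and specificity over the model ensemble,
  plus accumulating-panel AUC curves (top 1, 2, … 100 clones).
* **Clinical correlation** — over CF samples, best single clone by
  |Spearman ρ| and best 5-clone mean-aggregate by |Pearson r| from the
  exhaustive C(20,5) = 15,504 search, per covariate.

Because no spot-level dataset of this design is deposited, the package
includes a synthetic cohort generator (`generate_cohort()`) that emulates
the assay at the spot level — normexp-consistent noise, quintuplicates,
planted differential clones with calibrated effect sizes, clinical
covariates coupled to planted clones — so the whole chain runs and is
tested end to end against known ground truth.

## Worked example

The numbered drivers under `analysis/` run the whole study on a synthetic
cohort at full array scale (1070 clones × 111 samples × 5 replicates,
20 planted clones at d = 1.5, 200 resampling runs):

```sh
Rscript analysis/01_simulate.R      # spot table + metadata + ground truth
Rscript analysis/02_preprocess.R    # normexp + loess + scale -> matrix.tsv
Rscript analysis/03_select.R        # split plan, per-run t-tests, frequency ranking
Rscript analysis/04_classify.R      # accumulating AUCs + validation performance
Rscript analysis/05_explore.R       # PCA, clustering, heatmap ordering
Rscript analysis/06_correlate.R     # clinical correlations of the panel
Rscript analysis/07_validation_studies.R   # seed-grid self-checks
```

The drivers are seeded, so a fresh run prints exactly:

```
01: cohort: 593850 spot rows (1070 clones x 111 samples x 5 replicates)
01: planted: 6 up, 14 down (latent shift 2.05 M units)
02: matrix: 1070 clones x 111 samples; per-array red signal mean (alpha): median 5438 [4875, 6555]
03: 30 clones significant at least once over 200 runs; top clone clone_0188 in 142/200 runs
03: panel of 20 contains 18 of the 20 planted clones
04: validation (n models = 200): mean AUC 0.995 [0.931, 1.000], sensitivity 0.796, specificity 0.999
04: accumulating test AUC: 0.962 at 1 clone -> 1.000 at 30 clones
05: PCA, all 1070 clones: PC1 0.02 / PC2 0.02 of variance
05: PCA, 20-clone panel: PC1 0.34 / PC2 0.07 of variance
05: heatmap: 31 CF columns span positions 1-31 of 111
06: sweat_chloride: single clone clone_0045 rho = -0.54 (p = 0.00177); 5-clone set r = -0.74 (p = 1.63e-06)
06:   (4 of 5 truly coupled clones in the selected set)
```

Reading: the frequency ranking recovers 18/20 planted clones; the panel
classifies the held-out validation set almost perfectly at this planted
effect size (the lower mean sensitivity reflects thresholds carried over
from test to validation, while ranking-based AUC stays at 0.995); PCA on
the panel concentrates a third of the variance on PC1 where the full-array
PCA is diffuse; the heatmap column order places all 31 CF samples in one
contiguous block; and the planted negative coupling of sweat chloride to
five clones is recovered with the expected (selection-inflated) magnitude.

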