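# Shared small fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small full-structure cohort: 60 clones, study-scale sample groups
tiny_cohort <- function() {
  cached("tiny_cohort", function()
    generate_cohort(cohort_config(n_clones = 60L, n_planted_up = 3L,
                                  n_planted_down = 3L, effect_size = 2,
                                  seed = 42L)))
}

# the tiny cohort preprocessed to a 60 x 111 M matrix
tiny_prep <- function() {
  cached("tiny_prep", function()
    preprocess_cohort(tiny_cohort()$spots))
}

# reduced-sample cohort for preprocessing equivariance tests
mini_cohort <- function(seed = 5L) {
  generate_cohort(cohort_config(
    n_clones = 30L, n_healthy = 5L, n_cf = 4L, n_lc = 3L,
    n_planted_up = 2L, n_planted_down = 1L, effect_size = 1,
    covariate_coupling = list(), seed = seed))
}

# study-scale metadata without intensities (for split-plan tests)
study_meta <- function() {
  data.frame(
    sample_id = sprintf("s%03d", 1:111),
    group = rep(c("HC", "CF", "LC"), c(49, 31, 31)),
    stringsAsFactors = FALSE)
}
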