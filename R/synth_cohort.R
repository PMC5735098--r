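#' Configuration for a synthetic phage-antigen array cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. Defaults
#' emulate the study design the pipeline targets: 1070 phage clones printed in
#' quintuplicate, immunoscreened with sera from 49 healthy controls (HC),
#' 31 cystic fibrosis (CF) and 31 lung cancer (LC) subjects, with a subset of
#' clones planted as differentially reactive in CF and three clinical
#' covariates (sweat chloride, BMI, FEV1 % predicted) coupled to planted
#' clones with negative slopes.
#'
#' The two-channel noise model mirrors what the preprocessing assumes:
#' the red (Cy5, anti-human IgG) spot foreground is a Normal background plus
#' an Exponential signal whose mean carries the clone-by-sample latent
#' reactivity; the green (Cy3, anti-capsid) channel carries clone-specific
#' capsid loading with lognormal spot noise and is independent of group.
#'
#' `effect_size` is a standardized mean difference (Cohen's d) between CF and
#' HC on the scale of the final replicate-aggregated M values: the planted
#' latent shift is calibrated against the total per-clone dispersion
#' (between-sample latent sd plus the spot-noise contribution of the
#' median-of-replicates, estimated internally by Monte Carlo), so the
#' post-preprocessing standardized difference of planted clones matches
#' `effect_size` without attenuation.
#'
#' @param n_clones number of phage clones on the array.
#' @param n_healthy,n_cf,n_lc group sizes (HC / CF / LC sera).
#' @param n_replicates spots printed per clone per array.
#' @param n_planted_up,n_planted_down numbers of clones planted with
#'   increased / decreased reactivity in CF.
#' @param effect_size standardized CF-vs-HC mean difference (d units) of
#'   planted clones on the aggregated M scale; `>= 0`.
#' @param clone_baseline_mean,clone_baseline_sd mean and sd (M units) of
#'   per-clone baseline reactivity across clones.
#' @param reactivity_sd between-sample latent sd (M units) of a clone's
#'   reactivity within a group.
#' @param replicate_sd spot-to-spot sd (M units) within a quintuplicate.
#' @param background_mu,background_sd Normal background mean and sd
#'   (fluorescence units), shared by both channels.
#' @param signal_alpha exponential signal rate (1/fluorescence units); the
#'   baseline signal scale is `1/signal_alpha`.
#' @param covariate_coupling named list (names in `sweat_chloride`, `bmi`,
#'   `fev1_pct`); each element a list with `clones` (indices into the planted
#'   clones' positions), `slope` (covariate units per M unit), `noise_sd` and
#'   `intercept`. `NULL` installs the default negative couplings; pass
#'   `list()` for no coupling.
#' @param seed integer RNG seed; the cohort is a deterministic function of
#'   the configuration.
#' @return a validated `cohort_config` list.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_clones = 1070L,
                          n_healthy = 49L, n_cf = 31L, n_lc = 31L,
                          n_replicates = 5L,
                          n_planted_up = 6L, n_planted_down = 14L,
                          effect_size = 1.5,
                          clone_baseline_mean = 0, clone_baseline_sd = 0.5,
                          reactivity_sd = 1.0,
                          replicate_sd = 0.15,
                          background_mu = 100, background_sd = 20,
                          signal_alpha = 5e-4,
                          covariate_coupling = NULL,
                          seed = 1L) {
  cfg <- list(
    n_clones = as.integer(n_clones),
    n_healthy = as.integer(n_healthy), n_cf = as.integer(n_cf),
    n_lc = as.integer(n_lc), n_replicates = as.integer(n_replicates),
    n_planted_up = as.integer(n_planted_up),
    n_planted_down = as.integer(n_planted_down),
    effect_size = effect_size,
    clone_baseline_mean = clone_baseline_mean,
    clone_baseline_sd = clone_baseline_sd,
    reactivity_sd = reactivity_sd,
    replicate_sd = replicate_sd,
    background_mu = background_mu, background_sd = background_sd,
    signal_alpha = signal_alpha,
    covariate_coupling = covariate_coupling,
    seed = as.integer(seed)
  )
  for (f in c("n_clones", "n_healthy", "n_cf", "n_lc", "n_replicates")) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("cohort_config: field '", f, "' must be a positive count")
  }
  for (f in c("n_planted_up", "n_planted_down")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("cohort_config: field '", f, "' must be a non-negative count")
  }
  if (cfg$n_planted_up + cfg$n_planted_down > cfg$n_clones)
    stop("cohort_config: field 'n_planted_up' + 'n_planted_down' exceeds 'n_clones'")
  if (!is.finite(cfg$effect_size) || cfg$effect_size < 0)
    stop("cohort_config: field 'effect_size' must be >= 0")
  for (f in c("clone_baseline_sd", "reactivity_sd", "replicate_sd",
              "background_sd", "signal_alpha")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("cohort_config: field '", f, "' must be > 0")
  }
  if (is.null(cfg$covariate_coupling))
    cfg$covariate_coupling <- default_coupling(cfg)
  validate_coupling(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

# Default clinical couplings: each covariate driven by 5 planted clones with
# a negative slope. Spot-level measurement noise already decorrelates the
# measured clone aggregates from the latent driver (it caps the achievable
# measured |r| near 0.73 at the default reactivity_sd), so the added
# covariate noise is kept small: these settings give measured five-clone
# aggregate correlations near -0.7 with covariate means and dispersions
# plausible for a CF cohort (sweat chloride ~103 +/- 14 mM/L, BMI ~22.8 +/- 3
# kg/m^2, FEV1 ~59 +/- 17 % predicted).
default_coupling <- function(cfg) {
  n_planted <- cfg$n_planted_up + cfg$n_planted_down
  if (n_planted < 5L) return(list())
  pick <- function(k) ((k - 1L) %% n_planted) + 1L
  list(
    sweat_chloride = list(clones = pick(1:5),  slope = -30, noise_sd = 4,
                          intercept = 103.3),
    bmi            = list(clones = pick(6:10), slope = -6,  noise_sd = 1.2,
                          intercept = 22.8),
    fev1_pct       = list(clones = pick(11:15), slope = -35, noise_sd = 6,
                          intercept = 59.3)
  )
}

validate_coupling <- function(cfg) {
  cc <- cfg$covariate_coupling
  if (length(cc) == 0L) return(invisible(TRUE))
  allowed <- c("sweat_chloride", "bmi", "fev1_pct")
  if (is.null(names(cc)) || !all(names(cc) %in% allowed))
    stop("cohort_config: field 'covariate_coupling' names must be in: ",
         paste(allowed, collapse = ", "))
  n_planted <- cfg$n_planted_up + cfg$n_planted_down
  for (nm in names(cc)) {
    el <- cc[[nm]]
    if (!all(c("clones", "slope", "noise_sd") %in% names(el)))
      stop("cohort_config: coupling '", nm,
           "' needs fields clones, slope, noise_sd")
    if (any(el$clones < 1L | el$clones > n_planted))
      stop("cohort_config: coupling '", nm,
           "' indexes outside the planted clones (1..", n_planted, ")")
    if (!is.finite(el$noise_sd) || el$noise_sd <= 0)
      stop("cohort_config: coupling '", nm, "' field 'noise_sd' must be > 0")
  }
  invisible(TRUE)
}

# Spot-noise contribution to the variance of the aggregated M value:
# variance of the median of n_rep iid draws of
#   log2(Exp(1)) + N(0, sqrt(2) * replicate_sd)
# (exponential signal draw on the red channel, lognormal spot noise on both
# channels). No convenient closed form; estimated by Monte Carlo from a
# sub-stream of the config seed so the whole cohort stays deterministic.
spot_noise_var <- function(n_replicates, replicate_sd, n_mc = 200000L) {
  d <- matrix(log2(stats::rexp(n_replicates * n_mc)) +
                stats::rnorm(n_replicates * n_mc, 0, sqrt(2) * replicate_sd),
              nrow = n_replicates)
  stats::var(apply(d, 2L, stats::median))
}

#' Generate a synthetic spot-level two-color array cohort
#'
#' Simulates the raw input of the pipeline: a spot table of foreground and
#' background intensities for both channels (red = Cy5 anti-human IgG, green
#' = Cy3 anti-capsid), per-sample metadata with clinical covariates for CF
#' samples only, and the ground truth of what was planted.
#'
#' Latent clone reactivity on the M scale is
#' `m[c, s] = baseline[c] + shift[c] * 1(group = CF) + N(0, reactivity_sd^2)`,
#' where `shift` is `+/- effect_size * total_sd` for planted up/down clones
#' and `total_sd` is the calibrated per-clone dispersion of the aggregated M
#' values (see [cohort_config()]). The red spot foreground is
#' `N(background_mu, background_sd^2) + Exp(mean = loading[c] * 2^(m + spot
#' noise))`; the green foreground is background plus `loading[c]` with
#' lognormal spot noise, independent of group. Background columns are
#' independent Normal draws around `background_mu`. Negative intensities are
#' clipped at zero. CF clinical covariates are linear in the centered mean
#' latent reactivity of their coupled clones plus Gaussian noise.
#'
#' @param config a [cohort_config()].
#' @return list with elements `spots` (data.table: `sample_id`, `clone_id`,
#'   `replicate`, `F635`, `B635`, `F532`, `B532`), `meta` (data.table:
#'   `sample_id`, `group`, `sweat_chloride`, `bmi`, `fev1_pct`; covariates
#'   `NA` outside CF) and `truth` (list: `planted_up`, `planted_down` clone
#'   ids, `effect_size`, `shift_m` in M units, `couplings` with clone ids).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, as.list(config))
  cfg <- config
  set.seed(cfg$seed)

  n_grp <- c(HC = cfg$n_healthy, CF = cfg$n_cf, LC = cfg$n_lc)
  n_samp <- sum(n_grp)
  groups <- rep(names(n_grp), n_grp)
  sample_ids <- sprintf("%s_%02d", groups, unlist(lapply(n_grp, seq_len)))
  clone_ids <- sprintf("clone_%04d", seq_len(cfg$n_clones))

  n_planted <- cfg$n_planted_up + cfg$n_planted_down
  planted <- if (n_planted > 0L) sort(sample.int(cfg$n_clones, n_planted)) else integer()
  planted_up <- planted[seq_len(cfg$n_planted_up)]
  planted_down <- setdiff(planted, planted_up)

  total_sd <- sqrt(cfg$reactivity_sd^2 +
                     spot_noise_var(cfg$n_replicates, cfg$replicate_sd))
  shift_m <- cfg$effect_size * total_sd
  shift <- numeric(cfg$n_clones)
  shift[planted_up] <- shift_m
  shift[planted_down] <- -shift_m

  baseline <- stats::rnorm(cfg$n_clones, cfg$clone_baseline_mean,
                           cfg$clone_baseline_sd)
  # capsid loading spans ~2 orders of magnitude across clones (sdlog 1.2),
  # as spotted phage lysates do; a wide A range keeps M and A decoupled so
  # within-array loess removes dye trend, not reactivity signal
  loading <- exp(stats::rnorm(cfg$n_clones, log(1 / cfg$signal_alpha), 1.2))

  is_cf <- groups == "CF"
  m_lat <- baseline +
    outer(shift, as.numeric(is_cf)) +
    matrix(stats::rnorm(cfg$n_clones * n_samp, 0, cfg$reactivity_sd),
           cfg$n_clones, n_samp)

  n_rep <- cfg$n_replicates
  n_spot <- cfg$n_clones * n_samp * n_rep
  # long layout: replicate fastest, then clone, then sample
  m_spot <- rep(as.vector(m_lat), each = n_rep) +
    stats::rnorm(n_spot, 0, cfg$replicate_sd)
  loading_spot <- rep(rep(loading, times = n_samp), each = n_rep)
  red_mean <- loading_spot * 2^m_spot
  fg_red <- stats::rnorm(n_spot, cfg$background_mu, cfg$background_sd) +
    stats::rexp(n_spot, rate = 1 / red_mean)
  bg_red <- stats::rnorm(n_spot, cfg$background_mu, cfg$background_sd)
  fg_green <- stats::rnorm(n_spot, cfg$background_mu, cfg$background_sd) +
    loading_spot * 2^stats::rnorm(n_spot, 0, cfg$replicate_sd)
  bg_green <- stats::rnorm(n_spot, cfg$background_mu, cfg$background_sd)

  spots <- data.table::data.table(
    sample_id = rep(sample_ids, each = cfg$n_clones * n_rep),
    clone_id = rep(rep(clone_ids, each = n_rep), times = n_samp),
    replicate = rep(seq_len(n_rep), times = cfg$n_clones * n_samp),
    F635 = pmax(fg_red, 0), B635 = pmax(bg_red, 0),
    F532 = pmax(fg_green, 0), B532 = pmax(bg_green, 0)
  )

  meta <- data.table::data.table(
    sample_id = sample_ids, group = groups,
    sweat_chloride = NA_real_, bmi = NA_real_, fev1_pct = NA_real_
  )
  couplings <- list()
  m_centered <- m_lat - baseline   # deviations, so intercept = covariate mean
  for (nm in names(cfg$covariate_coupling)) {
    el <- cfg$covariate_coupling[[nm]]
    idx <- planted[el$clones]
    driver <- colMeans(m_centered[idx, is_cf, drop = FALSE])
    intercept <- if (is.null(el$intercept)) 0 else el$intercept
    vals <- intercept + el$slope * driver +
      stats::rnorm(sum(is_cf), 0, el$noise_sd)
    data.table::set(meta, i = which(is_cf), j = nm, value = vals)
    couplings[[nm]] <- list(clones = clone_ids[idx], slope = el$slope,
                            noise_sd = el$noise_sd)
  }

  truth <- list(
    planted_up = clone_ids[planted_up],
    planted_down = clone_ids[planted_down],
    effect_size = cfg$effect_size,
    shift_m = shift_m,
    couplings = couplings
  )
  list(spots = spots, meta = meta, truth = truth)
}

#' Write / read a cohort fixture
#'
#' Tab-separated spot table with GenePix-style column names
#' (`sample_id clone_id replicate F635 B635 F532 B532`), metadata TSV with
#' empty fields for absent covariates, and ground truth as JSON.
#'
#' @param cohort list as returned by [generate_cohort()] (elements `spots`,
#'   `meta`, optionally `truth`).
#' @param path directory to write into (created if needed).
#' @return `write_cohort()` returns the paths invisibly; `read_cohort()`
#'   returns a list with `spots`, `meta` and (if present) `truth`.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  spot_file <- file.path(path, "spots.tsv")
  meta_file <- file.path(path, "meta.tsv")
  data.table::fwrite(cohort$spots, spot_file, sep = "\t", na = "",
                     quote = FALSE)
  data.table::fwrite(cohort$meta, meta_file, sep = "\t", na = "",
                     quote = FALSE)
  files <- c(spots = spot_file, meta = meta_file)
  if (!is.null(cohort$truth)) {
    truth_file <- file.path(path, "truth.json")
    jsonlite::write_json(cohort$truth, truth_file, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, truth = truth_file)
  }
  invisible(files)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  spot_file <- file.path(path, "spots.tsv")
  meta_file <- file.path(path, "meta.tsv")
  spots <- read_spot_table(spot_file)
  if (!file.exists(meta_file)) stop("read_cohort: missing file ", meta_file)
  meta <- data.table::fread(meta_file, sep = "\t",
                            colClasses = list(character = c("sample_id", "group")))
  for (cv in c("sweat_chloride", "bmi", "fev1_pct"))
    if (cv %in% names(meta)) meta[[cv]] <- as.numeric(meta[[cv]])
  out <- list(spots = spots, meta = meta)
  truth_file <- file.path(path, "truth.json")
  if (file.exists(truth_file))
    out$truth <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
  out
}

#' Read and validate a spot-level TSV
#'
#' Enforces the spot-table invariants: required columns, non-negative
#' intensities, and a full replicate set for every (sample, clone) pair.
#'
#' @param file path to a tab-separated spot table.
#' @return a `data.table` with columns `sample_id`, `clone_id`, `replicate`,
#'   `F635`, `B635`, `F532`, `B532`.
#' @export
read_spot_table <- function(file) {
  if (!file.exists(file)) stop("read_spot_table: missing file ", file)
  spots <- tryCatch(
    data.table::fread(file, sep = "\t",
                      colClasses = list(character = c("sample_id", "clone_id"))),
    error = function(e) stop("read_spot_table: parse error in ", file, ": ",
                             conditionMessage(e))
  )
  if (nrow(spots) == 0L) stop("read_spot_table: no records in ", file)
  required <- c("sample_id", "clone_id", "replicate",
                "F635", "B635", "F532", "B532")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols))
    stop("read_spot_table: missing columns: ",
         paste(missing_cols, collapse = ", "))
  for (col in c("F635", "B635", "F532", "B532"))
    if (any(!is.finite(spots[[col]])) || any(spots[[col]] < 0))
      stop("read_spot_table: column ", col,
           " has negative or non-finite intensities")
  validate_replicates(spots)
  spots
}

validate_replicates <- function(spots) {
  n <- NULL # NSE note
  counts <- spots[, list(n = .N), by = c("sample_id", "clone_id")]
  n_rep <- counts$n[1L]
  bad <- counts[counts$n != n_rep, ]
  if (nrow(bad) > 0L)
    stop("spot table: inconsistent replicate counts for (sample, clone): ",
         paste(sprintf("(%s, %s)", utils::head(bad$sample_id, 5L),
                       utils::head(bad$clone_id, 5L)), collapse = ", "),
         if (nrow(bad) > 5L) " ..." else "")
  invisible(n_rep)
}
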