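#' Maximum-likelihood normexp background parameters
#'
#' Fits the normal+exponential convolution model
#' `observed = Normal(mu, sigma^2) + Exponential(mean alpha)` to
#' background-subtracted foreground intensities of one array channel, by
#' maximum likelihood (via `limma::normexp.fit(method = "mle")`).
#'
#' @param foreground numeric vector of foreground intensities (>= 0).
#' @param background optional vector of local background estimates, same
#'   length; subtracted from `foreground` before fitting.
#' @param sigma_floor lower bound for the returned background sd.
#' @return list of class `normexp_params` with `mu`, `sigma` (> 0) and
#'   `alpha` (> 0), all in fluorescence units.
#' @export
estimate_normexp_params <- function(foreground, background = NULL,
                                    sigma_floor = 0.01) {
  if (length(foreground) < 10L)
    stop("estimate_normexp_params: need >= 10 intensities")
  if (any(!is.finite(foreground)) || any(foreground < 0))
    stop("estimate_normexp_params: foreground must be finite and >= 0")
  x <- foreground
  if (!is.null(background)) {
    if (length(background) != length(foreground))
      stop("estimate_normexp_params: foreground/background length mismatch")
    x <- foreground - background
  }
  if (stats::sd(x) < sigma_floor) {
    warning("estimate_normexp_params: (near-)constant input; returning floor params")
    return(new_normexp_params(mean(x), sigma_floor, sigma_floor))
  }
  # exact MLE where the optimizer converges; saddle-point approximation to
  # the same likelihood as fallback on numerically awkward arrays
  fit <- tryCatch(limma::normexp.fit(x, method = "mle"),
                  error = function(e) limma::normexp.fit(x, method = "saddle"))
  p <- fit$par
  new_normexp_params(p[1L], max(exp(p[2L]), sigma_floor),
                     max(exp(p[3L]), sigma_floor))
}

new_normexp_params <- function(mu, sigma, alpha) {
  stopifnot(is.finite(mu), sigma > 0, alpha > 0)
  structure(list(mu = mu, sigma = sigma, alpha = alpha),
            class = "normexp_params")
}

#' Normexp background correction
#'
#' Returns `E[signal | observed = x]` under the normal background +
#' exponential signal convolution model. The conditional mean is strictly
#' positive for every finite `x` and monotone non-decreasing in `x`, which
#' guarantees valid log-ratios downstream.
#'
#' @param x numeric vector of observed (background-subtracted) intensities.
#' @param params a `normexp_params` object from [estimate_normexp_params()].
#' @return corrected intensities, same length as `x`, all > 0.
#' @export
normexp_correct <- function(x, params) {
  if (any(!is.finite(x))) stop("normexp_correct: non-finite intensities")
  stopifnot(inherits(params, "normexp_params"))
  out <- limma::normexp.signal(
    c(params$mu, log(params$sigma), log(params$alpha)), x)
  # guard against numerical underflow far below background
  pmax(out, .Machine$double.xmin)
}

#' M and A values for a two-color spot
#'
#' `M = log2(red/green)`, `A = (1/2) log2(red * green)`; the standard
#' coordinates for two-channel normalization.
#'
#' @param red,green background-corrected channel intensities (> 0).
#' @return list with numeric vectors `M` and `A`.
#' @export
compute_ma <- function(red, green) {
  if (length(red) != length(green))
    stop("compute_ma: length mismatch")
  if (any(!is.finite(red)) || any(!is.finite(green)) ||
      any(red <= 0) || any(green <= 0))
    stop("compute_ma: intensities must be finite and > 0 (background correction guarantees positivity)")
  list(M = log2(red / green), A = 0.5 * log2(red * green))
}

#' Within-array loess normalization
#'
#' Removes the intensity-dependent dye trend by subtracting a robust locally
#' weighted regression of M on A (degree 1, 3 robustifying iterations).
#'
#' @param m,a M and A vectors of one array (same length >= 10).
#' @param span loess span in (0, 1].
#' @return normalized M vector `m - fit(a)`.
#' @export
loess_normalize <- function(m, a, span = 0.3) {
  if (length(m) != length(a) || length(m) < 10L)
    stop("loess_normalize: m and a must have equal length >= 10")
  if (!is.finite(span) || span <= 0 || span > 1)
    stop("loess_normalize: span must be in (0, 1]")
  if (diff(range(a)) < .Machine$double.eps^0.5) {
    warning("loess_normalize: constant A; subtracting median(M)")
    return(m - stats::median(m))
  }
  # iterations = 4 => initial fit + 3 robustness iterations
  fit <- limma::loessFit(y = m, x = a, span = span, iterations = 4L)
  m - fit$fitted
}

#' Between-array scale normalization
#'
#' Scales each array's M values so that all arrays share the same median
#' absolute deviation (MAD), equal to the geometric mean of the original
#' per-array MADs. This is the "scale" step of two-channel workflows,
#' implemented on the MAD.
#'
#' @param arrays list of numeric M vectors, one per array (>= 2 arrays).
#' @return list of rescaled M vectors, same shapes.
#' @export
scale_normalize_between <- function(arrays) {
  if (!is.list(arrays) || length(arrays) < 2L)
    stop("scale_normalize_between: need >= 2 arrays")
  mads <- vapply(arrays, stats::mad, numeric(1))
  if (any(mads == 0)) {
    bad <- which(mads == 0)
    nm <- if (!is.null(names(arrays))) names(arrays)[bad] else bad
    stop("scale_normalize_between: zero MAD in array(s): ",
         paste(nm, collapse = ", "))
  }
  gm <- exp(mean(log(mads)))
  Map(function(x, s) x * (gm / s), arrays, mads)
}

#' Aggregate replicate spots to a clones-by-samples matrix
#'
#' Each matrix cell is the median of that (sample, clone)'s replicate M
#' values; the median makes the summary robust to a single bad spot in the
#' quintuplicate.
#'
#' @param spots data.frame/data.table with columns `sample_id`, `clone_id`,
#'   `M` (one row per spot).
#' @return numeric matrix (clones x samples) with clone ids as rownames and
#'   sample ids as colnames; no missing cells.
#' @export
aggregate_replicates <- function(spots) {
  spots <- data.table::as.data.table(spots)
  stopifnot(all(c("sample_id", "clone_id", "M") %in% names(spots)))
  M <- NULL
  agg <- spots[, list(M = stats::median(M)), by = c("clone_id", "sample_id")]
  clones <- sort(unique(agg$clone_id))
  samples <- unique(spots$sample_id)   # preserve input sample order
  mat <- matrix(NA_real_, length(clones), length(samples),
                dimnames = list(clones, samples))
  mat[cbind(match(agg$clone_id, clones), match(agg$sample_id, samples))] <- agg$M
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)
    stop("aggregate_replicates: missing (sample, clone) pairs: ",
         paste(sprintf("(%s, %s)", samples[utils::head(miss[, 2L], 5L)],
                       clones[utils::head(miss[, 1L], 5L)]), collapse = ", "),
         if (nrow(miss) > 5L) " ..." else "")
  }
  mat
}

#' Full spot-level preprocessing
#'
#' Runs the complete preprocessing chain on a spot table: per-array,
#' per-channel normexp background correction (parameters estimated by maximum
#' likelihood on that array's background-subtracted foregrounds), M/A
#' computation, within-array loess on the MA scale, between-array scale (MAD)
#' normalization, and median aggregation of replicates.
#'
#' @param spots spot table (see [read_spot_table()] for the column contract).
#' @param span loess span.
#' @return list with `matrix` (clones x samples normalized M), and `params`
#'   (per-array list of red/green `normexp_params`).
#' @export
preprocess_cohort <- function(spots, span = 0.3) {
  spots <- data.table::as.data.table(spots)
  validate_replicates(spots)
  samples <- unique(spots$sample_id)
  m_list <- vector("list", length(samples))
  params <- vector("list", length(samples))
  names(m_list) <- names(params) <- samples
  key_list <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    arr <- spots[spots$sample_id == samples[i], ]
    pr <- estimate_normexp_params(arr$F635, arr$B635)
    pg <- estimate_normexp_params(arr$F532, arr$B532)
    red <- normexp_correct(arr$F635 - arr$B635, pr)
    green <- normexp_correct(arr$F532 - arr$B532, pg)
    ma <- compute_ma(red, green)
    m_list[[i]] <- loess_normalize(ma$M, ma$A, span = span)
    params[[i]] <- list(red = pr, green = pg)
    key_list[[i]] <- arr$clone_id
  }
  m_list <- scale_normalize_between(m_list)
  long <- data.table::data.table(
    sample_id = rep(samples, lengths(m_list)),
    clone_id = unlist(key_list, use.names = FALSE),
    M = unlist(m_list, use.names = FALSE)
  )
  list(matrix = aggregate_replicates(long), params = params)
}

#' Per-clone fold change between two groups
#'
#' `2^(mean M in case group - mean M in reference group)`; values above 1
#' indicate increased reactivity in the case group (default CF vs HC).
#'
#' @param matrix clones x samples M matrix.
#' @param groups character vector of group labels, one per matrix column.
#' @param case,ref group labels to contrast.
#' @return named numeric vector of per-clone fold changes.
#' @export
fold_change <- function(matrix, groups, case = "CF", ref = "HC") {
  if (length(groups) != ncol(matrix))
    stop("fold_change: one group label per sample column required")
  if (!case %in% groups || !ref %in% groups)
    stop("fold_change: unknown group label '",
         if (!case %in% groups) case else ref, "'")
  2^(rowMeans(matrix[, groups == case, drop = FALSE]) -
       rowMeans(matrix[, groups == ref, drop = FALSE]))
}
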