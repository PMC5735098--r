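#' Spearman correlation of a clone with a clinical covariate
#'
#' Rank correlation with average ranks for ties; two-sided p-value from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` (as in
#' `stats::cor.test(..., method = "spearman", exact = FALSE)`). Pairs with a
#' missing covariate are dropped.
#'
#' @param values numeric vector of clone M values.
#' @param covariate numeric covariate, same length; may contain `NA`.
#' @return list with `rho`, `p`, `n` (pairs used).
#' @export
spearman_correlate <- function(values, covariate) {
  ok <- is.finite(values) & is.finite(covariate)
  x <- values[ok]; y <- covariate[ok]
  if (length(x) < 4L)
    stop("spearman_correlate: need >= 4 paired non-missing observations")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    stop("spearman_correlate: zero rank variance")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mean-aggregate of a clone set
#'
#' Per-sample unweighted mean of the set's normalized M values — the
#' aggregated vector used in the combination search.
#'
#' @param matrix clones x samples M matrix.
#' @param clone_set character vector of clone ids.
#' @return numeric vector, one value per sample.
#' @export
aggregate_mean <- function(matrix, clone_set) {
  if (length(clone_set) == 0L) stop("aggregate_mean: empty clone set")
  missing <- setdiff(clone_set, rownames(matrix))
  if (length(missing))
    stop("aggregate_mean: clones absent from matrix: ",
         paste(missing, collapse = ", "))
  colMeans(matrix[clone_set, , drop = FALSE])
}

#' Exhaustive best clone combination for a covariate
#'
#' Enumerates all `choose(|panel|, set_size)` subsets of the panel and
#' returns the one whose mean-aggregate has the largest absolute Pearson
#' correlation with the covariate; ties are broken by lexicographic clone
#' ids. The search is exact: subset correlations are computed from the
#' panel's covariance structure (`r(S) = sum(c[S]) / sqrt(sum(C[S, S]) *
#' var(y) * ...)`), identical to correlating each aggregate directly.
#'
#' With a 20-clone panel and sets of 5 this enumerates 15,504 subsets; no
#' multiplicity correction is applied over the search (the reported p-value
#' is the nominal two-sided Pearson p of the winning subset and is
#' selection-inflated; see the permutation utilities in the test-suite for
#' gauging that inflation).
#'
#' @param matrix clones x samples M matrix.
#' @param panel character vector of candidate clone ids (`>= set_size`).
#' @param covariate numeric covariate per sample (`NA` allowed; those samples
#'   are dropped).
#' @param set_size combination size (default 5).
#' @return list with `clones` (sorted ids), `r`, `p`, `n`, `aggregate`
#'   (per-used-sample mean vector), `covariate_name` unset (filled by
#'   [correlate_panel()]).
#' @export
best_combination <- function(matrix, panel, covariate, set_size = 5L) {
  if (length(panel) < set_size)
    stop("best_combination: panel smaller than set_size")
  ok <- is.finite(covariate)
  if (sum(ok) < set_size + 2L)
    stop("best_combination: need >= set_size + 2 non-missing covariate values")
  X <- matrix[panel, ok, drop = FALSE]
  y <- covariate[ok]
  n <- length(y)
  Xc <- X - rowMeans(X)
  yc <- y - mean(y)
  C <- Xc %*% t(Xc)            # clone-pair cross-products
  cv <- as.vector(Xc %*% yc)   # clone-covariate cross-products
  syy <- sum(yc^2)
  combos <- utils::combn(length(panel), set_size)
  num <- colSums(base::matrix(cv[combos], nrow = set_size))
  den <- apply(combos, 2L, function(idx) sum(C[idx, idx]))
  r_all <- num / sqrt(den * syy)
  best <- which(abs(r_all) == max(abs(r_all)))
  if (length(best) > 1L) {
    keys <- apply(combos[, best, drop = FALSE], 2L,
                  function(idx) paste(sort(panel[idx]), collapse = "|"))
    best <- best[order(keys)[1L]]
  }
  idx <- combos[, best]
  r <- r_all[best]
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(clones = sort(panel[idx]), r = r,
       p = 2 * stats::pt(-abs(tstat), n - 2), n = n,
       aggregate = colMeans(X[idx, , drop = FALSE]))
}

#' Clinical correlation report for a clone panel
#'
#' For each clinical covariate (computed over CF samples with non-missing
#' values only): the single panel clone with the largest absolute Spearman
#' rho, and the best `set_size`-clone combination by absolute Pearson r of
#' the mean-aggregate — the "single clone / set of five clones" layout of
#' the biomarker-vs-clinical-measure table.
#'
#' @param matrix clones x samples M matrix.
#' @param panel character vector of clone ids.
#' @param meta data.frame with `sample_id`, `group` and covariate columns.
#' @param covariates covariate column names to report.
#' @param set_size combination size.
#' @return data.frame with one row per covariate: `covariate`, `n`,
#'   `single_clone`, `single_rho`, `single_p`, `combo_clones`
#'   (pipe-separated), `combo_r`, `combo_p`.
#' @export
correlate_panel <- function(matrix, panel, meta,
                            covariates = c("sweat_chloride", "bmi", "fev1_pct"),
                            set_size = 5L) {
  meta <- as.data.frame(meta)
  cf <- meta[meta$group == "CF", , drop = FALSE]
  if (nrow(cf) == 0L) stop("correlate_panel: no CF samples in meta")
  sub <- matrix[, as.character(cf$sample_id), drop = FALSE]
  rows <- list()
  for (cv in covariates) {
    y <- cf[[cv]]
    if (is.null(y) || all(!is.finite(y))) {
      warning("correlate_panel: covariate '", cv, "' all missing; skipped")
      next
    }
    single <- lapply(panel, function(cl)
      spearman_correlate(sub[cl, ], y))
    rhos <- vapply(single, `[[`, numeric(1), "rho")
    b1 <- which.max(abs(rhos))
    combo <- best_combination(sub, panel, y, set_size = set_size)
    rows[[cv]] <- data.frame(
      covariate = cv, n = single[[b1]]$n,
      single_clone = panel[b1], single_rho = rhos[b1],
      single_p = single[[b1]]$p,
      combo_clones = paste(combo$clones, collapse = "|"),
      combo_r = combo$r, combo_p = combo$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
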