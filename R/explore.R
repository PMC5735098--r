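#' PCA score projection of samples
#'
#' Column-centered (not scaled) principal components via singular value
#' decomposition. Variance fractions are squared singular values over the
#' total variance of all components. Sign convention: within each component,
#' the loading of largest magnitude is made positive, so scores are
#' reproducible across platforms.
#'
#' @param matrix samples x clones matrix (samples as rows).
#' @param n_components number of components to return.
#' @return list of class `pca_result` with `scores` (samples x components),
#'   `loadings` (clones x components), `variance_explained` (fractions for
#'   the returned components) and `variance_all` (full spectrum, sums to 1).
#' @export
pca_scores <- function(matrix, n_components = 2L) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L) stop("pca_scores: need >= 2 samples")
  if (n_components > min(dim(matrix)))
    stop("pca_scores: n_components exceeds matrix rank bound")
  centered <- scale(matrix, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2)
  if (total_var < .Machine$double.eps)
    stop("pca_scores: no variance in matrix")
  sv <- svd(centered)
  flip <- vapply(seq_len(ncol(sv$v)), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d, length(sv$d)), 2L, flip, `*`)
  loadings <- sweep(sv$v, 2L, flip, `*`)
  var_all <- sv$d^2 / total_var
  idx <- seq_len(n_components)
  structure(list(scores = scores[, idx, drop = FALSE],
                 loadings = loadings[, idx, drop = FALSE],
                 variance_explained = var_all[idx],
                 variance_all = var_all),
            class = "pca_result")
}

#' Agglomerative hierarchical clustering
#'
#' Standard agglomeration over euclidean or correlation (`1 - r`) distances
#' with average or complete linkage, recording the merge sequence, heights
#' and leaf order.
#'
#' @param matrix items x features matrix (items are clustered).
#' @param metric `"euclidean"` or `"correlation"`.
#' @param linkage `"average"` or `"complete"`.
#' @return list of class `cluster_tree` with `merge`, `height`, `order`,
#'   `labels`, `metric`, `linkage` and the underlying `hclust` object.
#' @export
hier_cluster <- function(matrix, metric = c("euclidean", "correlation"),
                         linkage = c("average", "complete")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L) stop("hier_cluster: need >= 2 items")
  d <- switch(metric,
              euclidean = stats::dist(matrix),
              # constant rows give NA correlations; caught just below
              correlation = stats::as.dist(
                1 - suppressWarnings(stats::cor(t(matrix)))))
  if (any(is.na(d))) stop("hier_cluster: NaN distances (constant items under correlation?)")
  hc <- stats::hclust(d, method = linkage)
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = rownames(matrix), metric = metric,
                 linkage = linkage, hclust = hc),
            class = "cluster_tree")
}

#' Heatmap row/column ordering for a clone panel
#'
#' Restricts the matrix to the panel, standardizes each clone row to
#' z-scores across samples (display only), and orders rows by
#' correlation/average-linkage clustering of clones and columns by
#' euclidean/average-linkage clustering of samples. Zero-variance clone rows
#' are dropped with a warning before standardization.
#'
#' @param matrix clones x samples M matrix.
#' @param panel character vector of clone ids (subset of rownames).
#' @param row_metric,col_metric,row_linkage,col_linkage clustering choices,
#'   see [hier_cluster()].
#' @return list with `row_order` and `col_order` (ids in leaf order),
#'   `values` (standardized panel submatrix, original id order), and the two
#'   `cluster_tree`s.
#' @export
heatmap_order <- function(matrix, panel,
                          row_metric = "correlation", col_metric = "euclidean",
                          row_linkage = "average", col_linkage = "average") {
  if (length(panel) == 0L) stop("heatmap_order: empty panel")
  missing <- setdiff(panel, rownames(matrix))
  if (length(missing))
    stop("heatmap_order: panel clones absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  sub <- matrix[panel, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("heatmap_order: dropping zero-variance clone rows: ",
            paste(panel[sds == 0], collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0L) stop("heatmap_order: no informative rows left")
  }
  z <- t(scale(t(sub)))
  if (nrow(z) >= 2L) {
    row_tree <- hier_cluster(z, metric = row_metric, linkage = row_linkage)
    row_order <- rownames(z)[row_tree$order]
  } else {
    row_tree <- NULL
    row_order <- rownames(z)
  }
  if (nrow(z) >= 2L) {
    col_tree <- hier_cluster(t(z), metric = col_metric, linkage = col_linkage)
    col_order <- colnames(z)[col_tree$order]
  } else {
    # single informative clone: order samples by its value
    col_tree <- NULL
    col_order <- colnames(z)[order(z[1L, ])]
  }
  list(row_order = row_order, col_order = col_order, values = z,
       row_tree = row_tree, col_tree = col_tree)
}
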