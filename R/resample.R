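#' Build the train/test/validation split plan
#'
#' Draws a single fixed validation hold-out per group, then `n_runs`
#' independent random train/test assignments of the remaining samples. At the
#' study's cohort sizes (49 HC / 31 CF / 31 LC) the defaults reproduce the
#' design: CF 10 train / 11 test / 10 validation, HC 16 / 17 / 16, LC 0 test
#' only 15 / validation 16, with 1000 runs.
#'
#' @param meta data.frame with columns `sample_id` and `group`
#'   (`HC`/`CF`/`LC`).
#' @param n_runs number of random train/test resamples.
#' @param seed integer seed; the plan is deterministic given `meta`, `n_runs`
#'   and `seed`.
#' @param sizes named list of `c(train, test, validation)` counts per group.
#' @return list of class `split_plan` with `validation` (per-group id lists),
#'   `runs` (list of `run_id`, `train`, `test` per-group id lists), `sizes`,
#'   `seed`.
#' @export
make_split_plan <- function(meta, n_runs = 1000L, seed = 1L,
                            sizes = list(CF = c(train = 10L, test = 11L, validation = 10L),
                                         HC = c(train = 16L, test = 17L, validation = 16L),
                                         LC = c(train = 0L,  test = 15L, validation = 16L))) {
  meta <- as.data.frame(meta)
  stopifnot(all(c("sample_id", "group") %in% names(meta)))
  groups <- names(sizes)
  ids <- split(as.character(meta$sample_id), factor(meta$group, levels = groups))
  for (g in groups) {
    need <- sum(sizes[[g]])
    if (length(ids[[g]]) < need)
      stop("make_split_plan: group ", g, " needs >= ", need,
           " samples, has ", length(ids[[g]]))
  }
  set.seed(seed)
  validation <- lapply(groups, function(g)
    sort(sample(ids[[g]], sizes[[g]][["validation"]])))
  names(validation) <- groups
  pool <- lapply(groups, function(g) setdiff(ids[[g]], validation[[g]]))
  names(pool) <- groups
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    train <- list(); test <- list()
    for (g in groups) {
      n_tr <- sizes[[g]][["train"]]; n_te <- sizes[[g]][["test"]]
      shuffled <- sample(pool[[g]], n_tr + n_te)
      train[[g]] <- sort(shuffled[seq_len(n_tr)])
      test[[g]] <- sort(shuffled[n_tr + seq_len(n_te)])
    }
    runs[[r]] <- list(run_id = r, train = train, test = test)
  }
  structure(list(validation = validation, runs = runs, sizes = sizes,
                 seed = seed),
            class = "split_plan")
}

#' Pooled-variance two-sample Student t-test
#'
#' Classic Student t with pooled variance and `df = nx + ny - 2`, two-sided
#' p-value. Degenerate zero-variance inputs return `t = 0, p = 1` when the
#' means agree and a p-value floor when they do not.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
student_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("student_t_test: need >= 2 observations per group")
  r <- row_t_test(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  list(t = r$t[1L], df = r$df, p = r$p[1L])
}

#' Row-wise pooled t-tests for a clones-by-samples matrix
#'
#' Vectorized pooled-variance Student t for every row at once; the workhorse
#' behind the resampling runs.
#'
#' @param X,Y matrices with the same number of rows (clones); columns are the
#'   two groups' samples.
#' @return list with vectors `t`, `p` and scalar `df`.
#' @export
row_t_test <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  if (nx < 2L || ny < 2L) stop("row_t_test: need >= 2 columns per group")
  if (nrow(X) != nrow(Y)) stop("row_t_test: row mismatch")
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1L)
  vy <- rowSums((Y - my)^2) / (ny - 1L)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1L) * vx + (ny - 1L) * vy) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- (mx - my) / se
  zero <- se == 0
  if (any(zero)) {
    same <- zero & (mx == my)
    t[same] <- 0
    t[zero & !same] <- sign(mx - my)[zero & !same] * .Machine$double.xmax
  }
  p <- 2 * stats::pt(-abs(t), df)
  p[zero & (mx == my)] <- 1
  p[zero & (mx != my)] <- .Machine$double.xmin
  list(t = t, p = p, df = df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q[i] = min over j >= i of p(j) * m / j`, clipped
#' at 1), via `stats::p.adjust(method = "BH")` after input validation.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted values (q-values), same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential testing across all resampling runs
#'
#' For every run of the plan, tests each clone CF-train vs HC-train with the
#' pooled t-test and applies Benjamini-Hochberg adjustment across clones.
#' Only training columns are ever touched: test and validation samples play
#' no role in selection. LC samples are excluded from selection entirely.
#'
#' @param matrix clones x samples normalized M matrix.
#' @param plan a [make_split_plan()] object.
#' @param fdr_threshold per-run significance threshold on the q-value.
#' @return object of class `significance_records`: list with `p` and `q`
#'   (clones x runs matrices), `significant` (logical matrix), `threshold`.
#' @export
run_resampling <- function(matrix, plan, fdr_threshold = 0.01) {
  stopifnot(inherits(plan, "split_plan"))
  all_ids <- unique(unlist(c(plan$validation,
                             lapply(plan$runs, function(r) c(r$train, r$test)))))
  missing <- setdiff(all_ids, colnames(matrix))
  if (length(missing))
    stop("run_resampling: plan ids absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  n_runs <- length(plan$runs)
  p <- q <- matrix(NA_real_, nrow(matrix), n_runs,
                   dimnames = list(rownames(matrix), NULL))
  for (r in seq_len(n_runs)) {
    run <- plan$runs[[r]]
    res <- row_t_test(matrix[, run$train$CF, drop = FALSE],
                      matrix[, run$train$HC, drop = FALSE])
    p[, r] <- res$p
    q[, r] <- bh_adjust(res$p)
  }
  structure(list(p = p, q = q, significant = q < fdr_threshold,
                 threshold = fdr_threshold),
            class = "significance_records")
}

#' Frequency-of-significance ranking
#'
#' Counts, per clone, the number of runs in which it passed the FDR
#' threshold, and ranks clones by descending frequency; ties are broken by
#' ascending mean p-value across runs, then by clone id.
#'
#' @param records a `significance_records` object from [run_resampling()].
#' @return data.frame with columns `clone_id`, `frequency`, `mean_p`, `rank`,
#'   sorted by rank.
#' @export
frequency_rank <- function(records) {
  stopifnot(inherits(records, "significance_records"))
  if (ncol(records$p) < 1L) stop("frequency_rank: no runs recorded")
  freq <- rowSums(records$significant)
  mean_p <- rowMeans(records$p)
  clone_id <- rownames(records$p)
  ord <- order(-freq, mean_p, clone_id)
  data.frame(clone_id = clone_id[ord],
             frequency = as.integer(freq[ord]),
             mean_p = mean_p[ord],
             rank = seq_along(ord),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the top-ranked clone panel
#'
#' @param freq a [frequency_rank()] table.
#' @param k panel size (default 20, the study's headline panel).
#' @return character vector of `k` clone ids in rank order.
#' @export
select_top <- function(freq, k = 20L) {
  if (k > nrow(freq)) stop("select_top: k exceeds number of ranked clones")
  if (k == 0L) return(character())
  n_pos <- sum(freq$frequency > 0L)
  if (k > n_pos) {
    warning("select_top: only ", n_pos,
            " clones were ever significant; returning those")
    k <- max(n_pos, 0L)
    if (k == 0L) return(character())
  }
  freq$clone_id[seq_len(k)]
}
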