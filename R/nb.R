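#' Fit a Gaussian naive Bayes model
#'
#' Two-class Gaussian naive Bayes: empirical class priors and per-class,
#' per-clone means and variances. Variances are floored at
#' `1e-9 * max(pooled variance)` so zero-variance clones cannot produce
#' infinite likelihoods.
#'
#' @param X samples x clones matrix restricted to the model's panel.
#' @param y labels coercible to a 2-level factor; the *second* level is the
#'   positive (CF) class when `y` is a factor, otherwise `TRUE`/1 is positive.
#' @return list of class `nb_model` with `priors`, `mean` and `var`
#'   (class x clone matrices), `panel`, `classes` (negative, positive).
#' @export
fit_gaussian_nb <- function(X, y) {
  X <- as.matrix(X)
  if (is.logical(y)) y <- factor(y, levels = c(FALSE, TRUE))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L)
    stop("fit_gaussian_nb: exactly two classes required, got ", nlevels(y))
  if (ncol(X) < 1L) stop("fit_gaussian_nb: empty panel")
  classes <- levels(y)
  mu <- var <- matrix(NA_real_, 2L, ncol(X),
                      dimnames = list(classes, colnames(X)))
  for (k in 1:2) {
    Xi <- X[y == classes[k], , drop = FALSE]
    mu[k, ] <- colMeans(Xi)
    var[k, ] <- apply(Xi, 2L, stats::var)
  }
  var[is.na(var)] <- 0
  n <- tabulate(y)
  pooled <- ((n[1L] - 1L) * var[1L, ] + (n[2L] - 1L) * var[2L, ]) /
    max(sum(n) - 2L, 1L)
  eps <- 1e-9 * max(pooled, .Machine$double.eps)
  var <- pmax(var, eps)
  structure(list(priors = as.numeric(table(y) / length(y)),
                 mean = mu, var = var,
                 panel = colnames(X), classes = classes),
            class = "nb_model")
}

#' Posterior probability of the positive class
#'
#' Computed entirely in log space (log-sum-exp), so 20-feature products do
#' not underflow.
#'
#' @param model an `nb_model`.
#' @param X samples x clones matrix; columns must match the model's panel.
#' @return numeric vector of positive-class (CF) probabilities in (0, 1).
#' @export
nb_posterior <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$panel) && !is.null(colnames(X))) {
    if (!all(model$panel %in% colnames(X)))
      stop("nb_posterior: matrix columns do not cover the model panel")
    X <- X[, model$panel, drop = FALSE]
  } else if (ncol(X) != ncol(model$mean)) {
    stop("nb_posterior: panel size mismatch")
  }
  ll <- nb_class_loglik(model, X)
  # log posterior of class 2 via log-sum-exp over the two classes
  m <- pmax(ll[, 1L], ll[, 2L])
  log_den <- m + log(exp(ll[, 1L] - m) + exp(ll[, 2L] - m))
  exp(ll[, 2L] - log_den)
}

# samples x 2 matrix of log prior + log likelihood per class
nb_class_loglik <- function(model, X) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, 2L)
  for (k in 1:2) {
    mu <- matrix(model$mean[k, ], n, ncol(X), byrow = TRUE)
    v <- matrix(model$var[k, ], n, ncol(X), byrow = TRUE)
    out[, k] <- log(model$priors[k]) +
      rowSums(-0.5 * log(2 * pi * v) - (X - mu)^2 / (2 * v))
  }
  out
}

#' ROC curve and trapezoidal AUC
#'
#' Operating points over all distinct score thresholds (rule: predict
#' positive when `score >= threshold`). The trapezoidal AUC equals the
#' Mann-Whitney U statistic over positive/negative pairs, with ties credited
#' 1/2.
#'
#' @param scores numeric classifier scores, higher = more positive.
#' @param labels logical or 2-level labels; see [fit_gaussian_nb()] for the
#'   positive-class convention.
#' @return list of class `roc_curve` with `thresholds`, `tpr`, `fpr`
#'   (ordered from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (is.logical(labels)) labels <- factor(labels, levels = c(FALSE, TRUE))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("roc_curve: both classes must be present")
  pos <- labels == levels(labels)[2L]
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single operating points
  last <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  tpr <- c(0, tp / sum(pos)); fpr <- c(0, fp / sum(!pos))
  thresholds <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Optimal operating threshold by Youden's J
#'
#' Maximizes `J = sensitivity + specificity - 1 = TPR - FPR`; ties are broken
#' toward the higher-sensitivity operating point.
#'
#' @param roc a [roc_curve()] object.
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  best <- best[which.max(roc$tpr[best])]
  list(threshold = roc$thresholds[best],
       sensitivity = roc$tpr[best],
       specificity = 1 - roc$fpr[best])
}

# per-run evaluation sets: positives = CF, negatives = HC (+ LC) per the
# binary CF vs non-CF task
eval_ids <- function(part) {
  list(ids = c(part$CF, part$HC, part$LC),
       pos = c(rep(TRUE, length(part$CF)),
               rep(FALSE, length(part$HC) + length(part$LC))))
}

#' Accumulating-clone classification performance
#'
#' For panel sizes `1..max_clones` (clones added in frequency-rank order,
#' most frequent first), fits per run a Gaussian naive Bayes model on that
#' run's CF-train vs HC-train samples and records the AUC on the run's test
#' set (CF-test vs HC-test plus LC-test). Per-feature log-likelihoods are
#' cumulated over the ranked clones, so all sizes are scored in one pass.
#'
#' @param matrix clones x samples M matrix.
#' @param plan a [make_split_plan()] object.
#' @param freq a [frequency_rank()] table.
#' @param max_clones largest panel size.
#' @return `max_clones` x `n_runs` matrix of test-set AUCs (rows = panel
#'   size).
#' @export
accumulating_performance <- function(matrix, plan, freq, max_clones = 100L) {
  ranked <- freq$clone_id
  if (max_clones > length(ranked)) {
    warning("accumulating_performance: only ", length(ranked),
            " ranked clones; truncating")
    max_clones <- length(ranked)
  }
  ranked <- ranked[seq_len(max_clones)]
  n_runs <- length(plan$runs)
  auc <- matrix(NA_real_, max_clones, n_runs,
                dimnames = list(size = NULL, run = NULL))
  for (r in seq_len(n_runs)) {
    run <- plan$runs[[r]]
    tr_ids <- c(run$train$CF, run$train$HC)
    y_tr <- factor(rep(c("CF", "nonCF"), c(length(run$train$CF), length(run$train$HC))),
                   levels = c("nonCF", "CF"))
    ev <- eval_ids(run$test)
    Xtr <- t(matrix[ranked, tr_ids, drop = FALSE])
    Xte <- t(matrix[ranked, ev$ids, drop = FALSE])
    model <- fit_gaussian_nb(Xtr, y_tr)
    # cumulative per-class log-likelihood over ranked clones
    delta <- matrix(NA_real_, length(ev$ids), max_clones)
    for (k in 1:2) {
      v <- model$var[k, ]; mu <- model$mean[k, ]
      ll_k <- -0.5 * log(2 * pi * matrix(v, nrow(Xte), max_clones, byrow = TRUE)) -
        (Xte - matrix(mu, nrow(Xte), max_clones, byrow = TRUE))^2 /
        (2 * matrix(v, nrow(Xte), max_clones, byrow = TRUE))
      if (max_clones > 1L) ll_k <- t(apply(ll_k, 1L, cumsum))
      ll_k <- ll_k + log(model$priors[k])
      if (k == 1L) delta <- -ll_k else delta <- delta + ll_k
    }
    # delta = cumulative log-likelihood ratio CF vs nonCF: a monotone score
    for (s in seq_len(max_clones))
      auc[s, r] <- roc_curve(delta[, s], ev$pos)$auc
  }
  auc
}

#' Validation-set performance of the panel models
#'
#' Each run's model (Gaussian naive Bayes on the fixed top-k panel, trained
#' on that run's CF/HC training samples) scores the single fixed validation
#' set (CF-validation vs HC-validation plus LC-validation). The operating
#' threshold is chosen per model by Youden's J on that run's *test* scores;
#' validation data never influence threshold or panel choice, and any id
#' overlap between validation and train/test aborts.
#'
#' @param matrix clones x samples M matrix.
#' @param plan a [make_split_plan()] object.
#' @param panel character vector of clone ids (the selected panel).
#' @return list of class `performance_summary`: `per_run` data.frame
#'   (`run_id`, `auc`, `sensitivity`, `specificity`, `threshold`) and
#'   `summary` (per metric: mean, sd, 2.5% and 97.5% quantiles).
#' @export
evaluate_validation <- function(matrix, plan, panel) {
  val <- eval_ids(plan$validation)
  used <- unlist(lapply(plan$runs, function(r) c(unlist(r$train), unlist(r$test))))
  leak <- intersect(val$ids, used)
  if (length(leak))
    stop("evaluate_validation: validation ids leak into train/test: ",
         paste(utils::head(leak, 5L), collapse = ", "))
  Xval <- t(matrix[panel, val$ids, drop = FALSE])
  n_runs <- length(plan$runs)
  per_run <- data.frame(run_id = seq_len(n_runs), auc = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        threshold = NA_real_)
  for (r in seq_len(n_runs)) {
    run <- plan$runs[[r]]
    tr_ids <- c(run$train$CF, run$train$HC)
    y_tr <- factor(rep(c("CF", "nonCF"), c(length(run$train$CF), length(run$train$HC))),
                   levels = c("nonCF", "CF"))
    model <- fit_gaussian_nb(t(matrix[panel, tr_ids, drop = FALSE]), y_tr)
    te <- eval_ids(run$test)
    sc_te <- nb_posterior(model, t(matrix[panel, te$ids, drop = FALSE]))
    thr <- optimal_threshold(roc_curve(sc_te, te$pos))$threshold
    sc_val <- nb_posterior(model, Xval)
    per_run$auc[r] <- roc_curve(sc_val, val$pos)$auc
    pred_pos <- sc_val >= thr
    per_run$sensitivity[r] <- mean(pred_pos[val$pos])
    per_run$specificity[r] <- mean(!pred_pos[!val$pos])
    per_run$threshold[r] <- thr
  }
  summarize <- function(x) c(mean = mean(x), sd = stats::sd(x),
                             q025 = unname(stats::quantile(x, 0.025)),
                             q975 = unname(stats::quantile(x, 0.975)))
  structure(list(per_run = per_run,
                 summary = list(auc = summarize(per_run$auc),
                                sensitivity = summarize(per_run$sensitivity),
                                specificity = summarize(per_run$specificity))),
            class = "performance_summary")
}
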