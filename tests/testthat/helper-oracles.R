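# Independent oracles used across the suite. Each is a direct transcription
# of the defining formula or a brute-force enumeration, kept free of any
# package internals so it can disagree with the implementation.

# Benjamini-Hochberg step-up by definition: q_(i) = min_{j >= i} p_(j)*m/j
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(c(vals, 1))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# two-sided permutation p-value for the difference in means (vectorized:
# all permutation draws as one index matrix)
perm_pvalue <- function(x, y, n_perm = 20000L) {
  obs <- abs(mean(x) - mean(y))
  z <- c(x, y)
  n <- length(z); nx <- length(x)
  idx <- replicate(n_perm, sample.int(n, nx))
  mx <- colMeans(matrix(z[idx], nrow = nx))
  my <- (sum(z) - mx * nx) / (n - nx)
  hits <- sum(abs(mx - my) >= obs - 1e-12)
  (hits + 1) / (n_perm + 1)
}

# AUC by concordant-pair counting with half credit for ties
auc_pairs <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# E[signal | observed = x] under Normal(mu, sigma^2) + Exp(mean alpha) by
# numerical quadrature over the posterior mass window
normexp_cond_mean_quad <- function(x, mu, sigma, alpha) {
  f <- function(s) stats::dexp(s, 1 / alpha) * stats::dnorm(x - s, mu, sigma)
  m0 <- x - mu - sigma^2 / alpha
  lo <- max(0, m0 - 12 * sigma)
  hi <- max(m0, 0) + 12 * sigma
  den <- stats::integrate(f, lo, hi, rel.tol = 1e-12,
                          abs.tol = 0)$value
  num <- stats::integrate(function(s) s * f(s), lo, hi, rel.tol = 1e-12,
                          abs.tol = 0)$value
  num / den
}

# log-likelihood of the normexp convolution model (for the grid MLE oracle)
normexp_loglik <- function(x, mu, sigma, alpha) {
  # density of N(mu, sigma^2) + Exp(mean alpha), computed on the log scale
  z <- (x - mu) / sigma - sigma / alpha
  sum((mu - x) / alpha + sigma^2 / (2 * alpha^2) - log(alpha) +
        stats::pnorm(z, log.p = TRUE))
}

# O(n^3) agglomerative clustering oracle for average/complete linkage:
# merge heights only (merge-tree labelling conventions differ across
# implementations; the height sequence identifies the agglomeration).
hclust_oracle_heights <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      dij <- d[active[[i]], active[[j]], drop = FALSE]
      val <- if (linkage == "average") mean(dij) else max(dij)
      if (val < best_d) { best_d <- val; best <- c(i, j) }
    }
    heights[step] <- best_d
    merged <- c(active[[best[1L]]], active[[best[2L]]])
    active <- active[-best]
    active[[length(active) + 1L]] <- merged
  }
  heights
}

# exhaustive best-|r| subset by plain re-enumeration with cor()
best_combo_bruteforce <- function(X, panel, y, set_size) {
  combos <- utils::combn(panel, set_size, simplify = FALSE)
  rs <- vapply(combos, function(cl)
    stats::cor(colMeans(X[cl, , drop = FALSE]), y), numeric(1))
  best <- which.max(abs(rs))
  list(clones = sort(combos[[best]]), r = rs[best])
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
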