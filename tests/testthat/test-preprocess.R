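test_that("normexp parameter estimation recovers generating values", {
  set.seed(11)
  x <- rnorm(10000, 50, 5) + rexp(10000, 1 / 200)
  p <- estimate_normexp_params(x)
  # tolerances established from repeated simulation at n = 10,000
  expect_lt(abs(p$mu - 50), 3)
  expect_lt(abs(p$sigma - 5), 1.5)
  expect_lt(abs(p$alpha - 200), 10)
})

test_that("zero-signal input falls back to floor parameters", {
  set.seed(12)
  bg <- rnorm(100, 80, 10)
  expect_warning(p <- estimate_normexp_params(bg + 1e-4, bg), "constant")
  expect_lt(abs(p$mu), 1e-3)
  expect_equal(p$alpha, 0.01)  # the sigma/alpha floor
})

test_that("estimated parameters attain at least the coarse-grid likelihood", {
  set.seed(13)
  x <- rnorm(50, 30, 8) + rexp(50, 1 / 150)
  p <- estimate_normexp_params(x)
  ll_hat <- normexp_loglik(x, p$mu, p$sigma, p$alpha)
  grid_mu <- seq(min(x), quantile(x, 0.5), length.out = 20)
  grid_sigma <- seq(1, 2 * sd(x), length.out = 20)
  grid_alpha <- seq(5, 3 * mean(x), length.out = 20)
  ll_grid <- -Inf
  for (mu in grid_mu) for (sg in grid_sigma) for (al in grid_alpha)
    ll_grid <- max(ll_grid, normexp_loglik(x, mu, sg, al))
  expect_gte(ll_hat + 1e-6, ll_grid)
})

test_that("normexp correction equals the quadrature conditional mean", {
  set.seed(14)
  for (i in 1:100) {
    mu <- runif(1, 0, 100)
    sigma <- runif(1, 1, 40)
    alpha <- runif(1, 20, 500)
    p <- structure(list(mu = mu, sigma = sigma, alpha = alpha),
                   class = "normexp_params")
    x <- runif(1, mu - 3 * sigma, mu + alpha + 3 * sigma)
    got <- normexp_correct(x, p)
    want <- normexp_cond_mean_quad(x, mu, sigma, alpha)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("normexp correction is positive and monotone", {
  set.seed(15)
  for (i in 1:20) {
    p <- structure(list(mu = runif(1, -20, 100), sigma = runif(1, 0.5, 50),
                        alpha = runif(1, 5, 1000)),
                   class = "normexp_params")
    x <- sort(runif(50, p$mu - 12 * p$sigma, p$mu + 5 * p$alpha))
    y <- normexp_correct(x, p)
    expect_true(all(y > 0))
    expect_true(all(diff(y) >= -1e-9))
  }
  # far below background: still positive
  p <- structure(list(mu = 100, sigma = 10, alpha = 200),
                 class = "normexp_params")
  expect_gt(normexp_correct(100 - 10 * 10, p), 0)
  # no-background limit: correction is nearly the identity
  p0 <- structure(list(mu = 0, sigma = 0.01, alpha = 1e6),
                  class = "normexp_params")
  expect_equal(normexp_correct(500, p0), 500, tolerance = 1e-3)
  expect_error(normexp_correct(NaN, p), "finite")
})

test_that("MA computation follows the log-ratio identities", {
  ma <- compute_ma(1000, 1000)
  expect_equal(ma$M, 0)
  expect_equal(ma$A, log2(1000))
  ma <- compute_ma(2000, 500)
  expect_equal(ma$M, 2)
  expect_equal(ma$A, 0.5 * log2(2000 * 500))
  expect_error(compute_ma(0, 10), "positivity")
  expect_error(compute_ma(c(1, 2), 1), "length")
})

test_that("loess normalization removes the M-A trend", {
  set.seed(16)
  a <- runif(500, 5, 15)
  # constant M: output ~ 0 everywhere
  out <- loess_normalize(rep(2, 500), a)
  expect_lt(max(abs(out)), 1e-8)
  # injected linear trend: residual sd and slope recovered
  m <- 0.1 * a + rnorm(500, 0, 0.01)
  out <- loess_normalize(m, a)
  expect_lt(abs(coef(lm(out ~ a))[2]), 0.005)
  expect_equal(sd(out), 0.01, tolerance = 0.25)
  # span = 1 on exactly linear data matches a global regression detrend
  m_lin <- 3 + 0.25 * a
  out <- loess_normalize(m_lin, a, span = 1)
  oracle <- residuals(lm(m_lin ~ a))
  expect_equal(out, unname(oracle), tolerance = 1e-6)
  # idempotence on data whose trend the smoother reproduces exactly
  once <- loess_normalize(m_lin + rnorm(500, 0, 1e-4), a, span = 1)
  twice <- loess_normalize(once, a, span = 1)
  expect_lt(sd(twice - once), 1e-6 * max(sd(once), 1))
  # constant A: falls back to median subtraction
  expect_warning(out <- loess_normalize(m[1:20], rep(1, 20)), "constant A")
  expect_equal(median(out), 0)
})

test_that("between-array scale normalization equalizes MADs", {
  set.seed(17)
  a1 <- rnorm(200)            # MAD ~ 1
  a2 <- rnorm(200) * 4        # MAD ~ 4
  out <- scale_normalize_between(list(x = a1, y = a2))
  m1 <- mad(out$x); m2 <- mad(out$y)
  expect_equal(m1, m2, tolerance = 1e-10)
  expect_equal(m1, sqrt(mad(a1) * mad(a2)), tolerance = 1e-10)
  # identical arrays pass through unchanged
  out2 <- scale_normalize_between(list(a1, a1))
  expect_equal(out2[[1]], a1, tolerance = 1e-12)
  # idempotence: applying twice equals applying once
  out3 <- scale_normalize_between(out)
  expect_equal(out3, out, tolerance = 1e-12)
  # order of per-array medians is preserved by the (positive) scaling
  expect_equal(sign(median(out$x)), sign(median(a1)))
  expect_error(scale_normalize_between(list(a = a1, b = rep(1, 50))), "b")
})

test_that("replicate aggregation takes per-cell medians and checks completeness", {
  sp <- data.frame(sample_id = rep("s1", 10),
                   clone_id = rep(c("c1", "c2"), each = 5),
                   M = c(1, 1, 1, 1, 1, 1, 2, 3, 4, 100))
  m <- aggregate_replicates(sp)
  expect_equal(unname(m["c1", "s1"]), 1)
  expect_equal(unname(m["c2", "s1"]), 3)   # robust to the outlier spot
  sp2 <- rbind(sp, data.frame(sample_id = "s2", clone_id = "c1", M = 0))
  expect_error(aggregate_replicates(sp2), "missing .sample, clone.")
})

test_that("full preprocessing yields a complete matrix and is permutation-equivariant", {
  co <- mini_cohort()
  pp <- preprocess_cohort(co$spots)
  expect_equal(dim(pp$matrix), c(30L, 12L))
  expect_false(anyNA(pp$matrix))
  # permute the arrays in the spot table: columns permute identically
  samples <- unique(co$spots$sample_id)
  perm <- rev(samples)
  sp_perm <- co$spots[order(match(co$spots$sample_id, perm)), ]
  pp2 <- preprocess_cohort(sp_perm)
  expect_equal(pp2$matrix[, samples], pp$matrix[, samples], tolerance = 1e-12)
})

test_that("fold change follows the log2 group-mean identity", {
  m <- rbind(c(1, 1, 2, 2), c(0, 0, 1, 1))
  rownames(m) <- c("a", "b"); colnames(m) <- paste0("s", 1:4)
  g <- c("HC", "HC", "CF", "CF")
  fc <- fold_change(m, g)
  expect_equal(unname(fc), c(2, 2))
  expect_equal(unname(fold_change(m, c("CF", "CF", "HC", "HC"))), c(0.5, 0.5))
  m2 <- m; m2[1, ] <- 5
  expect_equal(unname(fold_change(m2, g)["a"]), 1)
  expect_error(fold_change(m, g, case = "XX"), "XX")
})

test_that("planted up-clones show fold change above one", {
  up_fc <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(
      n_clones = 25L, n_planted_up = 3L, n_planted_down = 0L,
      effect_size = 1.5, covariate_coupling = list(), seed = 300L + s))
    sp <- co$spots
    sp$M <- log2((sp$F635 + 1) / (sp$F532 + 1))
    m <- aggregate_replicates(sp[, c("sample_id", "clone_id", "M")])
    g <- co$meta$group[match(colnames(m), co$meta$sample_id)]
    fc <- fold_change(m, g)
    all(fc[co$truth$planted_up] > 1)
  }, logical(1))
  expect_gte(mean(up_fc), 0.95)
})
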