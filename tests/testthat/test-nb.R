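test_that("naive Bayes posterior matches the closed-form Gaussian ratio", {
  # class A ~ N(0,1), class B ~ N(2,1), equal priors; at x = 0 the posterior
  # of A is 1/(1+exp(-2)); at the midpoint it is 1/2
  model <- structure(list(
    priors = c(0.5, 0.5),
    mean = matrix(c(2, 0), 2, 1, dimnames = list(c("B", "A"), "f")),
    var = matrix(c(1, 1), 2, 1, dimnames = list(c("B", "A"), "f")),
    panel = "f", classes = c("B", "A")), class = "nb_model")
  x <- matrix(0, 1, 1, dimnames = list(NULL, "f"))
  expect_equal(nb_posterior(model, x), 1 / (1 + exp(-2)), tolerance = 1e-12)
  x[1] <- 1
  expect_equal(nb_posterior(model, x), 0.5, tolerance = 1e-12)
})

test_that("fitted model separates well-separated classes and validates input", {
  set.seed(41)
  X <- matrix(c(rnorm(20, 0), rnorm(20, 6)), ncol = 1)
  colnames(X) <- "f"
  y <- rep(c("neg", "pos"), each = 20)
  m <- fit_gaussian_nb(X, factor(y, levels = c("neg", "pos")))
  post <- nb_posterior(m, X)
  expect_true(all(post[1:20] < 0.5) && all(post[21:40] > 0.5))
  expect_error(fit_gaussian_nb(X, rep("pos", 40)), "two classes")
  expect_error(nb_posterior(m, matrix(0, 1, 1, dimnames = list(NULL, "g"))),
               "panel")
  # duplicating a feature pushes the posterior away from 1/2
  X2 <- cbind(f = X[, 1], f2 = X[, 1])
  m2 <- fit_gaussian_nb(X2, factor(y, levels = c("neg", "pos")))
  p1 <- nb_posterior(m, X)
  p2 <- nb_posterior(m2, X2)
  away <- abs(p2 - 0.5) >= abs(p1 - 0.5) - 1e-12
  expect_true(all(away))
})

test_that("log-space posterior equals direct-probability computation", {
  set.seed(42)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- factor(rep(c("a", "b"), 30), levels = c("a", "b"))
  m <- fit_gaussian_nb(X, y)
  direct <- function(model, X) {
    lik <- sapply(1:2, function(k) {
      apply(X, 1, function(row)
        prod(dnorm(row, model$mean[k, ], sqrt(model$var[k, ])))) *
        model$priors[k]
    })
    lik[, 2] / rowSums(lik)
  }
  expect_equal(nb_posterior(m, X), direct(m, X), tolerance = 1e-10)
})

test_that("posterior agrees with an independent naive Bayes implementation", {
  set.seed(43)
  X <- matrix(rnorm(80 * 4, sd = 1.3), 80, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(rep(c("a", "b"), each = 40), levels = c("a", "b"))
  X[y == "b", ] <- X[y == "b", ] + 0.8
  m <- fit_gaussian_nb(X, y)
  ref <- e1071::naiveBayes(X, y)
  want <- predict(ref, X, type = "raw")[, "b"]
  expect_equal(nb_posterior(m, X), unname(want), tolerance = 1e-6)
})

test_that("ROC curve and AUC follow pair counting, including ties", {
  r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 0.75)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  # trapezoid over stored points reproduces the reported AUC
  trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
  expect_equal(r$auc, trap)
  # separable and null behaviour
  expect_equal(roc_curve(1:10, rep(c(FALSE, TRUE), each = 5))$auc, 1)
  set.seed(44)
  big <- roc_curve(rnorm(4000), rep(c(TRUE, FALSE), 2000))
  expect_equal(big$auc, 0.5, tolerance = 0.05)
  # oracle equivalence with ties at half credit
  for (i in 1:30) {
    sc <- sample(1:6, 30, replace = TRUE) + sample(c(0, 0.5), 30, TRUE)
    lab <- sample(c(TRUE, FALSE), 30, TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(roc_curve(sc, lab)$auc, auc_pairs(sc, lab),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC matches an independent ROC implementation", {
  set.seed(45)
  sc <- rnorm(60)
  lab <- sc + rnorm(60) > 0
  got <- roc_curve(sc, lab)$auc
  want <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc,
                                         quiet = TRUE, direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("Youden threshold maximizes TPR - FPR with sensitivity tie-break", {
  r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  opt <- optimal_threshold(r)
  expect_equal(opt$sensitivity, 1.0)
  expect_equal(opt$specificity, 0.5)
  opt2 <- optimal_threshold(roc_curve(1:10, rep(c(FALSE, TRUE), each = 5)))
  expect_equal(opt2$sensitivity, 1)
  expect_equal(opt2$specificity, 1)
  # constant scores: J = 0 everywhere; tie rule returns (1, 0)
  opt3 <- optimal_threshold(roc_curve(rep(2, 8), rep(c(TRUE, FALSE), 4)))
  expect_equal(opt3$sensitivity, 1)
  expect_equal(opt3$specificity, 0)
})

test_that("accumulating curve at size one equals single-clone models", {
  co <- tiny_cohort()
  m <- tiny_prep()$matrix
  plan <- make_split_plan(co$meta, n_runs = 4L, seed = 3L)
  rec <- run_resampling(m, plan)
  fr <- frequency_rank(rec)
  acc <- accumulating_performance(m, plan, fr, max_clones = 3L)
  expect_equal(dim(acc), c(3L, 4L))
  # direct single-clone check for run 1
  run <- plan$runs[[1]]
  tr <- c(run$train$CF, run$train$HC)
  y <- factor(rep(c("CF", "nonCF"), c(10, 16)), levels = c("nonCF", "CF"))
  top1 <- fr$clone_id[1]
  mod <- fit_gaussian_nb(t(m[top1, tr, drop = FALSE]), y)
  te <- c(run$test$CF, run$test$HC, run$test$LC)
  pos <- c(rep(TRUE, 11), rep(FALSE, 17 + 15))
  sc <- nb_posterior(mod, t(m[top1, te, drop = FALSE]))
  expect_equal(acc[1, 1], roc_curve(sc, pos)$auc, tolerance = 1e-12)
  expect_warning(accumulating_performance(m, plan, fr, max_clones = 1000L),
                 "truncating")
})

test_that("validation evaluation blocks leakage and reports degenerate dispersion", {
  co <- tiny_cohort()
  m <- tiny_prep()$matrix
  plan <- make_split_plan(co$meta, n_runs = 3L, seed = 4L)
  panel <- rownames(m)[1:5]
  # force identical runs: dispersion must be exactly zero
  plan_dup <- plan
  plan_dup$runs <- rep(plan$runs[1], 3)
  perf <- evaluate_validation(m, plan_dup, panel)
  expect_equal(perf$summary$auc[["sd"]], 0)
  expect_equal(length(unique(perf$per_run$auc)), 1L)
  # metrics are proper proportions
  perf2 <- evaluate_validation(m, plan, panel)
  with(perf2$per_run, {
    expect_true(all(auc >= 0 & auc <= 1))
    expect_true(all(sensitivity >= 0 & sensitivity <= 1))
    expect_true(all(specificity >= 0 & specificity <= 1))
  })
  # leakage: make one training id equal a validation id
  plan_bad <- plan
  plan_bad$runs[[1]]$train$CF[1] <- plan$validation$CF[1]
  expect_error(evaluate_validation(m, plan_bad, panel), "leak")
})
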