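test_that("split plan reproduces the study's hold-out sizes", {
  plan <- make_split_plan(study_meta(), n_runs = 5L, seed = 1L)
  expect_length(plan$validation$CF, 10L)
  expect_length(plan$validation$HC, 16L)
  expect_length(plan$validation$LC, 16L)
  r <- plan$runs[[1]]
  expect_length(r$train$CF, 10L); expect_length(r$test$CF, 11L)
  expect_length(r$train$HC, 16L); expect_length(r$test$HC, 17L)
  expect_length(r$train$LC, 0L);  expect_length(r$test$LC, 15L)
})

test_that("split plan is deterministic and leak-free", {
  a <- make_split_plan(study_meta(), n_runs = 3L, seed = 7L)
  b <- make_split_plan(study_meta(), n_runs = 3L, seed = 7L)
  expect_identical(a, b)
  val <- unlist(a$validation)
  for (r in a$runs) {
    tr <- unlist(r$train); te <- unlist(r$test)
    expect_length(intersect(tr, te), 0L)
    expect_length(intersect(c(tr, te), val), 0L)
  }
})

test_that("split plan rejects under-sized groups with counts", {
  meta <- study_meta()
  meta <- meta[!(meta$group == "CF" & duplicated(meta$group) &
                   seq_len(nrow(meta)) > 58), ]
  small <- rbind(meta[meta$group != "CF", ],
                 meta[meta$group == "CF", ][1:9, ])
  expect_error(make_split_plan(small, n_runs = 2L), ">= 31")
})

test_that("pooled t-test matches the closed form and stats::t.test", {
  r <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.6742, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.0213, tolerance = 1e-3)
  r0 <- student_t_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), 0.5)
    want <- t.test(x, y, var.equal = TRUE)
    got <- student_t_test(x, y)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
  }
  # degenerate zero-variance, unequal means: p at the floor
  rz <- student_t_test(c(1, 1, 1), c(2, 2, 2))
  expect_lt(rz$p, 1e-300)
})

test_that("pooled t p-value agrees with a permutation oracle on small inputs", {
  set.seed(22)
  for (i in 1:10) {
    # group sizes >= 8 keep the permutation null fine-grained enough for the
    # Monte-Carlo band to be the dominant error
    x <- rnorm(sample(8:12, 1)); y <- rnorm(sample(8:12, 1), runif(1, 0, 1))
    p_t <- student_t_test(x, y)$p
    p_perm <- perm_pvalue(x, y, n_perm = 4000L)
    mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
    expect_lt(abs(p_t - p_perm), max(3 * mc_se, 0.02))
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("resampling significance uses training columns only", {
  co <- tiny_cohort()
  m <- tiny_prep()$matrix
  plan <- make_split_plan(co$meta, n_runs = 5L, seed = 2L)
  rec <- run_resampling(m, plan)
  # corrupt every non-training column: results must not change
  m2 <- m
  train_ids <- unique(unlist(lapply(plan$runs, function(r) r$train)))
  other <- setdiff(colnames(m), train_ids)
  m2[, other] <- m2[, other] + 1e6
  rec2 <- run_resampling(m2, plan)
  expect_identical(rec$p, rec2$p)
  expect_identical(rec$significant, rec2$significant)
  expect_true(all(rec$q >= rec$p))
  expect_error(run_resampling(m[, 1:50], plan), "absent")
})

test_that("an isolated strong clone is significant in nearly every run", {
  co <- generate_cohort(cohort_config(
    n_clones = 50L, n_planted_up = 1L, n_planted_down = 0L, effect_size = 3,
    covariate_coupling = list(), seed = 31L))
  m <- preprocess_cohort(co$spots)$matrix
  plan <- make_split_plan(co$meta, n_runs = 50L, seed = 32L)
  rec <- run_resampling(m, plan)
  freq <- rowSums(rec$significant)
  expect_gte(freq[co$truth$planted_up], 45L)
})

test_that("zero resampling runs produce an empty record set", {
  co <- tiny_cohort()
  m <- tiny_prep()$matrix
  plan <- make_split_plan(co$meta, n_runs = 0L, seed = 6L)
  rec <- run_resampling(m, plan)
  expect_equal(ncol(rec$p), 0L)
  expect_equal(ncol(rec$significant), 0L)
})

test_that("frequency ranking orders by frequency, then mean p, then id", {
  rec <- structure(list(
    p = matrix(c(0.001, 0.5, 0.005, 0.001, 0.6, 0.005,
                 0.002, 0.4, 0.005), 3,
               dimnames = list(c("cB", "cC", "cA"), NULL)),
    q = matrix(c(0.004, 0.9, 0.009, 0.004, 0.9, 0.009,
                 0.006, 0.8, 0.009), 3,
               dimnames = list(c("cB", "cC", "cA"), NULL))),
    class = "significance_records")
  rec$significant <- rec$q < 0.01
  fr <- frequency_rank(rec)
  # cB significant 3/3; cA 3/3 with larger mean p; cC 0/3
  expect_equal(fr$clone_id, c("cB", "cA", "cC"))
  expect_equal(fr$frequency, c(3L, 3L, 0L))
  expect_equal(fr$rank, 1:3)
  # invariance to run order
  rec2 <- rec
  rec2$p <- rec$p[, 3:1]; rec2$q <- rec$q[, 3:1]
  rec2$significant <- rec$significant[, 3:1]
  expect_identical(frequency_rank(rec2), fr)
})

test_that("panel selection honours k and the rank order", {
  fr <- data.frame(clone_id = paste0("c", 1:5), frequency = c(9L, 7L, 5L, 3L, 1L),
                   mean_p = seq(0.001, 0.005, length.out = 5), rank = 1:5)
  expect_equal(select_top(fr, 3), c("c1", "c2", "c3"))
  expect_equal(select_top(fr, 0), character())
  expect_equal(select_top(fr, 5), fr$clone_id)
  fr$frequency[4:5] <- 0L
  expect_warning(p <- select_top(fr, 5), "ever significant")
  expect_equal(p, c("c1", "c2", "c3"))
  expect_error(select_top(fr, 6), "exceeds")
})
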