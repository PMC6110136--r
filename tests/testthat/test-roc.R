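test_that("the constant-zero predictor has AUC exactly one half", {
  d <- naive_predictions(make_bench(c(2.5, 0.3, 0.1, 1.9), c(0, 0, 0, 0)))
  r <- roc_curve(d, "naive")
  expect_identical(r$auc, 0.5)
  # and zero sensitivity at the 10-fold cutoff: everything called susceptible
  tt <- truth_table(d, "naive")
  expect_equal(sensitivity(tt), 0)
  expect_equal(tt$fp, 0L)
})

test_that("perfectly separating predictions give AUC 1", {
  d <- make_bench(c(3, 2.5, 0.1, 0.2, 0.3), c(3, 3, 0, 0, 0))
  expect_equal(roc_curve(d, "m1")$auc, 1)
})

test_that("sweep AUC matches the pairwise Mann-Whitney oracle, ties counted half", {
  # tie structure on a coarse grid so the 0.001 sweep resolves every gap
  e <- c(2.0, 1.8, 2.2, 0.1, 0.5, 0.9, 1.0, 0.2)
  p <- c(1.5, 0.5, 2.5, 0.5, 1.5, -0.5, 2.5, 0.0)
  d <- make_bench(e, p)
  r <- roc_curve(d, "m1", step = 0.001)
  cut <- resistance_cutoff(10)$cutoff
  oracle <- pairwise_auc(p[e > cut], p[e <= cut])
  expect_equal(r$auc, oracle, tolerance = 0.001)

  set.seed(51)
  for (i in 1:5) {
    e <- rnorm(20, 1, 1.2)
    p <- round(rnorm(20, e, 1), 1) # rounding induces ties
    d <- make_bench(e, p)
    r <- roc_curve(d, "m1")
    oracle <- pairwise_auc(p[e > cut], p[e <= cut])
    expect_equal(r$auc, oracle, tolerance = 0.002)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(52)
  e <- rnorm(25, 1, 1.2)
  p <- rnorm(25, e, 1)
  base <- roc_curve(make_bench(e, p), "m1")$auc
  expect_equal(roc_curve(make_bench(e, 2 * p + 1), "m1")$auc, base,
               tolerance = 0.002)
  expect_equal(roc_curve(make_bench(e, exp(p)), "m1")$auc, base,
               tolerance = 0.005)
})

test_that("ROC points are anchored, sorted, and inside the unit square", {
  bench <- generate_benchmark(m = 60, seed = 6)
  r <- roc_curve(bench$data, "fep")
  expect_true(all(r$points$fpr >= 0 & r$points$fpr <= 1))
  expect_true(all(r$points$tpr >= 0 & r$points$tpr <= 1))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_true(!is.unsorted(r$points$fpr))
  expect_gte(r$auc, 0)
  expect_lte(r$auc, 1)
  # single experimental class: degenerate
  one_class <- make_bench(c(0.1, 0.2), c(1, 2))
  expect_error(roc_curve(one_class, "m1"), "Both experimental classes")
})

test_that("fit_scale finds the least-squares slope through the origin", {
  e <- c(0.2, 1.4, 2.2, -0.5, 0.8)
  d <- make_bench(e, e)
  s <- fit_scale(d, "m1")
  expect_equal(s$slope, 1)
  expect_equal(s$rmse, 0)
  d2 <- make_bench(e, 2 * e)
  expect_equal(fit_scale(d2, "m1")$slope, 0.5)
  expect_error(fit_scale(make_bench(e, rep(0, 5)), "m1"), "zero")
})

test_that("fit_scale agrees with a grid search and never hurts the RMSE", {
  e <- c(0.3, 1.8, -0.4, 2.6, 1.1)
  p <- c(0.9, 2.5, 0.2, 4.0, 0.6)
  d <- make_bench(e, p)
  s <- fit_scale(d, "m1")
  grid <- seq(-5, 5, by = 1e-4)
  grid_rmse <- vapply(grid, function(g) sqrt(mean((g * p - e)^2)), numeric(1))
  expect_equal(s$slope, grid[which.min(grid_rmse)], tolerance = 1e-4)
  expect_lte(s$rmse, rmse(d, "m1"))
  set.seed(53)
  for (i in 1:10) {
    d <- make_bench(rnorm(15), rnorm(15, 0, 2))
    expect_lte(fit_scale(d, "m1")$rmse, rmse(d, "m1") + 1e-12)
  }
})

test_that("consensus weights scaled predictions by inverse squared RMSE", {
  set.seed(54)
  e <- rnorm(30, 1, 1.2)
  d <- make_bench(e, rnorm(30, e, 0.8), method = "a")
  d$b_ddg <- rnorm(30, e, 1.6)
  d$b_sigma <- 0
  out <- consensus_predictions(d, "a", "b")
  sc <- attr(out, "scaling")
  wa <- 1 / sc$rmse[1]^2
  wb <- 1 / sc$rmse[2]^2
  expected <- (wa * sc$slope[1] * d$a_ddg + wb * sc$slope[2] * d$b_ddg) /
    (wa + wb)
  expect_equal(out$consensus_ddg, expected)
  # the better method dominates
  expect_gt(wa / (wa + wb), 0.5)
})

test_that("two copies of the same method yield their scaled prediction back", {
  set.seed(55)
  e <- rnorm(20, 1, 1.2)
  p <- rnorm(20, e, 1)
  d <- make_bench(e, p, method = "a")
  d$b_ddg <- p
  d$b_sigma <- 0
  out <- consensus_predictions(d, "a", "b")
  expect_equal(out$consensus_ddg, fit_scale(d, "a")$slope * p)
})

test_that("consensus of independent errors beats the worse method on average", {
  set.seed(56)
  diffs <- replicate(60, {
    e <- rnorm(100, 0.5, 1.2)
    d <- make_bench(e, e + rnorm(100, 0, 1.0), method = "a")
    d$b_ddg <- e + rnorm(100, 0, 1.5)
    d$b_sigma <- 0
    out <- consensus_predictions(d, "a", "b")
    sc <- attr(out, "scaling")
    min(sc$rmse) - rmse(out, "consensus")
  })
  # mean inequality: consensus RMSE <= min of the scaled RMSEs in expectation
  expect_gt(mean(diffs), 0)
})
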