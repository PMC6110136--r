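test_that("truth tables match hand enumeration, with censored rows forced resistant", {
  d <- make_bench(
    exp_ddg = c(2.0, 0.5, 1.36, 1.5, 1.0),
    pred = c(1.5, 2.0, 1.36, 0.9, 0.2),
    censored = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  tt <- truth_table(d, "m1")
  # row-by-row: tp, fp, tn, fn, fn (censored row is experimentally resistant)
  expect_equal(tt$tp, 1L)
  expect_equal(tt$fp, 1L)
  expect_equal(tt$tn, 1L)
  expect_equal(tt$fn, 2L)
  expect_equal(tt$tp + tt$fn,
               sum(d$censored | d$exp_ddg > resistance_cutoff(10)$cutoff))
})

test_that("a perfect predictor has no false calls", {
  set.seed(31)
  e <- rnorm(40, 0.5, 1.5)
  tt <- truth_table(make_bench(e, e), "m1")
  expect_equal(tt$fp, 0L)
  expect_equal(tt$fn, 0L)
  expect_equal(accuracy(tt), 1)
})

test_that("missing predictions are reported with their keys", {
  d <- make_bench(c(1, 2), c(0.5, NA))
  expect_error(truth_table(d, "m1"), "tki1/A102V")
  expect_error(truth_table(d, "nope"), "not found")
})

test_that("classification metrics reproduce published worked examples", {
  fep <- as_truth_table(tp = 9, fn = 9, fp = 8, tn = 105)
  expect_equal(round(accuracy(fep), 2), 0.87)
  expect_equal(round(specificity(fep), 2), 0.93)
  expect_equal(round(sensitivity(fep), 2), 0.50)
  prime <- as_truth_table(tp = 9, fn = 9, fp = 28, tn = 85)
  expect_equal(round(accuracy(prime), 2), 0.72)
  expect_equal(round(specificity(prime), 2), 0.75)
  expect_equal(round(sensitivity(prime), 2), 0.50)
})

test_that("sensitivity and specificity go NA when their class is absent", {
  t1 <- as_truth_table(tp = 0, fn = 0, fp = 3, tn = 7)
  expect_true(is.na(sensitivity(t1)))
  expect_equal(specificity(t1), 0.7)
  t2 <- as_truth_table(tp = 3, fn = 1, fp = 0, tn = 0)
  expect_true(is.na(specificity(t2)))
  expect_error(accuracy(as_truth_table(0, 0, 0, 0)), "Empty")
})

test_that("truth tables add, preserving the class identity", {
  a <- as_truth_table(9, 9, 8, 105)
  b <- as_truth_table(0, 1, 0, 12)
  combined <- a + b
  expect_s3_class(combined, "truth_table")
  expect_equal(combined$tp, 9L)
  expect_equal(combined$fn, 10L)
  expect_equal(classification_metrics(combined)$n, 144L)
})

test_that("accuracy decomposes into class-weighted sensitivity and specificity", {
  set.seed(32)
  for (i in 1:10) {
    tt <- truth_table(make_bench(rnorm(30, 1, 1.2), rnorm(30, 1, 1.2)), "m1")
    sn <- sensitivity(tt)
    sp <- specificity(tt)
    if (is.na(sn) || is.na(sp)) next
    n_pos <- tt$tp + tt$fn
    n_neg <- tt$fp + tt$tn
    expect_equal(accuracy(tt), (sn * n_pos + sp * n_neg) / (n_pos + n_neg))
  }
})

test_that("MUE and RMSE match hand arithmetic and exclude censored records", {
  d <- make_bench(c(1, 1), c(2, 0)) # errors +1, -1
  expect_equal(mue(d, "m1"), 1)
  expect_equal(rmse(d, "m1"), 1)
  d2 <- make_bench(c(1, 1), c(1, 3)) # errors 0, 2
  expect_equal(mue(d2, "m1"), 1)
  expect_equal(rmse(d2, "m1"), sqrt(2))
  # perfect predictions
  d3 <- make_bench(c(0.3, 1.2), c(0.3, 1.2))
  expect_equal(mue(d3, "m1"), 0)
  expect_equal(rmse(d3, "m1"), 0)
  # censored rows drop out of the quantitative metrics entirely
  d4 <- make_bench(c(1, 1, 5), c(2, 0, 50),
                   censored = c(FALSE, FALSE, TRUE))
  expect_equal(mue(d4, "m1"), 1)
  expect_equal(rmse(d4, "m1"), 1)
  expect_error(mue(make_bench(1, 1, censored = TRUE), "m1"), "censored")
})

test_that("MUE never exceeds RMSE", {
  set.seed(33)
  for (i in 1:20) {
    d <- make_bench(rnorm(25), rnorm(25))
    expect_lte(mue(d, "m1"), rmse(d, "m1") + 1e-12)
  }
})

test_that("summarize_benchmark separates quantitative and classification Ns", {
  bench <- generate_benchmark(m = 40, censor_at = 1.2, seed = 8)
  n_cens <- sum(bench$data$censored)
  expect_gt(n_cens, 0)
  s <- summarize_benchmark(bench$data)
  expect_equal(unique(s$n_class - s$n_quant), n_cens)
  expect_setequal(s$method, c("fep", "prime"))
  by_tki <- summarize_benchmark(bench$data, by_tki = TRUE)
  expect_setequal(unique(by_tki$dataset), unique(bench$data$tki))
})

test_that("threshold_sweep matches per-fold brute-force enumeration", {
  d <- make_bench(
    exp_ddg = c(0.4, 1.5, 1.9, 2.9, 3.1, -0.2),
    pred = c(0.2, 1.8, 1.1, 3.0, 2.0, 0.1)
  )
  sw <- threshold_sweep(d, "m1", folds = c(10, 20, 100))
  # brute force with plain arithmetic, independently of classify_resistance()
  for (i in seq_len(3)) {
    cut <- sw$cutoff[i]
    e_res <- d$exp_ddg > cut
    p_res <- d$m1_ddg > cut
    expect_equal(sw$tp[i], sum(e_res & p_res))
    expect_equal(sw$fn[i], sum(e_res & !p_res))
    expect_equal(sw$fp[i], sum(!e_res & p_res))
    expect_equal(sw$tn[i], sum(!e_res & !p_res))
  }
  # resistant counts can only shrink as the fold grows
  expect_true(all(diff(sw$tp + sw$fn) <= 0))
  # single fold agrees with truth_table directly
  one <- threshold_sweep(d, "m1", folds = 10)
  tt <- truth_table(d, "m1", resistance_cutoff(10))
  expect_equal(one$tp, tt$tp)
  expect_equal(one$tn, tt$tn)
  expect_error(threshold_sweep(d, "m1", folds = c(10, 1)), "> 1")
})
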