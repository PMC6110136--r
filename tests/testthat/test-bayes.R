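# Minimal hand-built posterior for exercising posterior_metrics() without an
# MCMC run.
fake_fit <- function(mu = 0, sigma_mut = 1.2, rmse = 1, n = 200, M = 150) {
  structure(
    list(
      draws = tibble::tibble(
        .chain = 1L, .iteration = seq_len(n),
        mu_mut = rep(mu, n), sigma_mut = rep(sigma_mut, n),
        rmse_method = rep(rmse, n)
      ),
      M = M, method = "toy", converged = TRUE
    ),
    class = "intrinsic_error_fit"
  )
}

test_that("mue_from_rmse implements the half-normal closed form", {
  expect_equal(mue_from_rmse(0), 0)
  expect_equal(round(mue_from_rmse(0.99), 2), 0.79)
  expect_equal(mue_from_rmse(1), sqrt(2 / pi))
  expect_equal(round(mue_from_rmse(1), 4), 0.7979)
  expect_error(mue_from_rmse(-1), "non-negative")
})

test_that("the intrinsic error of a deterministic predictor is recovered", {
  bench <- generate_benchmark(
    m = 150, mu_mut = 0.5, sigma_mut = 1.2,
    methods = predictor_spec("det", rmse = 1.0, deterministic = TRUE),
    sigma_exp = 0.57, seed = 61
  )
  fit <- fit_intrinsic_error(bench$data, "det", sigma_exp = 0.57, seed = 62)
  expect_true(fit$deterministic)
  expect_true(fit$converged)
  expect_true(all(fit$diagnostics$rhat < 1.05))
  expect_true(all(fit$diagnostics$ess > 400))
  g <- glance(fit)
  expect_lt(abs(g$rmse - 1.0), 0.15)
  expect_true(g$rmse_low <= 1.0 && 1.0 <= g$rmse_high)
  # all scale draws positive; latent truths carry one row per record
  expect_true(all(fit$draws$sigma_mut > 0))
  expect_true(all(fit$draws$rmse_method > 0))
  expect_equal(nrow(fit$ddg_true), 150)
  expect_equal(nrow(fit$draws), 5000)
})

test_that("a perfect predictor drives the intrinsic error to the boundary", {
  bench <- generate_benchmark(
    m = 200, mu_mut = 0.5, sigma_mut = 1.2,
    methods = predictor_spec("perfect", rmse = 0, deterministic = TRUE),
    sigma_exp = 0.57, seed = 63
  )
  # mixing near the boundary is poor; the convergence flag fires by design
  fit <- suppressWarnings(
    fit_intrinsic_error(bench$data, "perfect", sigma_exp = 0.57, seed = 64)
  )
  expect_false(fit$converged)
  expect_lt(median(fit$draws$rmse_method), 0.25)
})

test_that("the stochastic pathway uses per-record replicate noise", {
  bench <- generate_benchmark(
    m = 150, mu_mut = 0.5, sigma_mut = 1.2,
    methods = predictor_spec("fep", rmse = 1.0, deterministic = FALSE,
                             sigma_stat = 0.3),
    sigma_exp = 0.57, seed = 65
  )
  fit <- fit_intrinsic_error(bench$data, "fep", sigma_exp = 0.57, seed = 66)
  expect_false(fit$deterministic)
  expect_true(fit$converged)
  expect_lt(abs(mean(fit$draws$rmse_method) - 1.0), 0.25)
})

test_that("censored records are excluded from the Bayesian fit", {
  bench <- generate_benchmark(m = 80, censor_at = 1.0, seed = 67)
  n_cens <- sum(bench$data$censored)
  expect_gt(n_cens, 0)
  # short runs trip the ESS flag; that is expected at 1000 draws
  fit <- suppressWarnings(
    fit_intrinsic_error(bench$data, "prime", draws = 1000, burn = 200,
                        seed = 68)
  )
  expect_equal(fit$M, 80 - n_cens)
  expect_error(
    fit_intrinsic_error(bench$data[1:4, ], "prime"),
    "at least 5"
  )
})

test_that("tidy and glance expose posterior summaries with diagnostics", {
  bench <- generate_benchmark(m = 60, seed = 69)
  fit <- suppressWarnings(
    fit_intrinsic_error(bench$data, "prime", draws = 1000, burn = 200,
                        seed = 70)
  )
  td <- tidy(fit)
  expect_setequal(td$term, c("mu_mut", "sigma_mut", "rmse_method"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_true(all(c("rhat", "ess") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$mue, mean(mue_from_rmse(fit$draws$rmse_method)))
})

test_that("posterior-predictive MUE agrees with the closed form on a point mass", {
  fit <- fake_fit(rmse = 1, n = 100, M = 150)
  pm <- posterior_metrics(fit, m = 2000, seed = 71)
  expect_equal(pm$mean[pm$metric == "mue"], sqrt(2 / pi), tolerance = 0.01)
  expect_equal(pm$mean[pm$metric == "rmse"], 1, tolerance = 0.01)
})

test_that("posterior-predictive classification metrics respect their ranges", {
  fit <- fake_fit(mu = 0.5, sigma_mut = 1.2, rmse = 1, n = 300)
  pm <- posterior_metrics(fit, seed = 72)
  cls <- pm[pm$metric %in% c("accuracy", "specificity", "sensitivity"), ]
  expect_true(all(cls$mean >= 0 & cls$mean <= 1))
  expect_true(all(cls$conf.low <= cls$mean & cls$mean <= cls$conf.high))
  expect_identical(posterior_metrics(fit, seed = 5),
                   posterior_metrics(fit, seed = 5))
  expect_error(posterior_metrics(fit, replicates_per_draw = 0), ">= 1")
})

test_that("draw-wise MUE tracks sqrt(2/pi) times the RMSE draw as m grows", {
  fit <- fake_fit(rmse = 1.4, n = 50)
  pm_small <- posterior_metrics(fit, m = 50, seed = 73)
  pm_big <- posterior_metrics(fit, m = 5000, seed = 73)
  target <- mue_from_rmse(1.4)
  err_small <- abs(pm_small$mean[pm_small$metric == "mue"] - target)
  err_big <- abs(pm_big$mean[pm_big$metric == "mue"] - target)
  expect_lt(err_big, 0.01)
  expect_lte(err_big, err_small + 1e-3)
})
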