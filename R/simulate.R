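#' Describe a synthetic predictor
#'
#' @param name Method name (used as column prefix in generated tables).
#' @param rmse Intrinsic error of the predictor (kcal/mol): the standard
#'   deviation of the normal, zero-bias error between the predictor's latent
#'   value and the true ddG.
#' @param deterministic If `TRUE` the latent value is observed exactly (e.g.
#'   a single-structure implicit-solvent score); if `FALSE` the observation
#'   is additionally corrupted by replicate statistical noise.
#' @param sigma_stat Statistical standard deviation of the *reported mean*
#'   for a stochastic predictor (kcal/mol). Constant, or one value per
#'   record.
#' @param replicates Number of independent replicate runs emulated for a
#'   stochastic predictor (default 3, mirroring triplicate free-energy runs).
#' @return A `predictor_spec` object.
#' @examples
#' predictor_spec("fep", rmse = 1.0, deterministic = FALSE, sigma_stat = 0.3)
#' @export
predictor_spec <- function(name, rmse, deterministic = TRUE,
                           sigma_stat = 0, replicates = 3) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(rmse), length(rmse) == 1L, rmse >= 0)
  stopifnot(is.numeric(sigma_stat), all(sigma_stat >= 0))
  stopifnot(replicates >= 2)
  if (deterministic && any(sigma_stat > 0)) {
    abort("A deterministic predictor cannot have statistical noise.")
  }
  structure(
    list(
      name = name, rmse = rmse, deterministic = deterministic,
      sigma_stat = sigma_stat, replicates = as.integer(replicates)
    ),
    class = "predictor_spec"
  )
}

default_predictors <- function() {
  list(
    predictor_spec("fep", rmse = 1.0, deterministic = FALSE,
                   sigma_stat = 0.3, replicates = 3),
    predictor_spec("prime", rmse = 1.75, deterministic = TRUE)
  )
}

#' Generate a synthetic benchmark with known ground truth
#'
#' Emulates the statistical structure the analysis assumes, end to end:
#' true per-mutation effects are drawn from a normal background,
#' `ddg_true ~ N(mu_mut, sigma_mut^2)`; each predictor's latent value is the
#' truth plus a zero-bias normal intrinsic error of standard deviation
#' `rmse`; stochastic predictors are observed through `replicates`
#' independent runs whose mean and standard error populate the
#' `{method}_ddg` / `{method}_sigma` columns (the per-run noise is
#' `sigma_stat * sqrt(replicates)` so the reported mean has standard
#' deviation `sigma_stat`); experimental observations are the truth plus
#' normal noise of standard deviation `sigma_exp`. An optional assay ceiling
#' censors experimental values: records with observed `exp_ddg > censor_at`
#' are flagged and truncated to `censor_at`, mimicking potencies beyond the
#' dynamic range of the assay.
#'
#' Defaults mirror a realistic kinase-inhibitor resistance benchmark:
#' `m = 131` mutation/inhibitor pairs over 6 inhibitors, a background with
#' `sigma_mut = 1.2` kcal/mol and mean chosen so that about 14% of true
#' effects exceed the 10-fold (1.36 kcal/mol) resistance cutoff, experimental
#' noise `sigma_exp = 0.57` kcal/mol (an inter-source RMSE of 0.81), one
#' stochastic predictor with intrinsic error 1.0 kcal/mol observed in
#' triplicate, and one deterministic predictor with intrinsic error 1.75
#' kcal/mol.
#'
#' @param m Number of (TKI, mutation) records.
#' @param mu_mut,sigma_mut Mean and standard deviation (kcal/mol) of the true
#'   effect distribution.
#' @param methods List of [predictor_spec()] objects.
#' @param sigma_exp Experimental noise standard deviation (kcal/mol).
#' @param censor_at Optional assay ceiling on experimental ddG (kcal/mol).
#' @param n_tki Number of inhibitor labels to cycle records over.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A `synthetic_benchmark`: list with `data` (benchmark tibble),
#'   `truth` (tibble of `tki`, `mutation`, `ddg_true`) and `config`.
#' @examples
#' bench <- generate_benchmark(m = 20, seed = 1)
#' bench$data
#' @export
generate_benchmark <- function(m = 131, mu_mut = 0.05, sigma_mut = 1.2,
                               methods = default_predictors(),
                               sigma_exp = 0.57, censor_at = NULL,
                               n_tki = 6, seed = NULL) {
  stopifnot(m >= 1, sigma_mut > 0, sigma_exp >= 0, n_tki >= 1)
  if (inherits(methods, "predictor_spec")) methods <- list(methods)
  stopifnot(all(vapply(methods, inherits, logical(1), "predictor_spec")))
  with_seed(seed, {
    tki <- paste0("tki", ((seq_len(m) - 1L) %% n_tki) + 1L)
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    wt <- sample(aa, m, replace = TRUE)
    mt <- sample(aa, m, replace = TRUE)
    mutation <- sprintf("%s%d%s", wt, 200L + ((seq_len(m) - 1L) %/% n_tki), mt)

    ddg_true <- rnorm(m, mu_mut, sigma_mut)
    exp_obs <- ddg_true + rnorm(m, 0, sigma_exp)
    censored <- rep(FALSE, m)
    if (!is.null(censor_at)) {
      censored <- exp_obs > censor_at
      exp_obs[censored] <- censor_at
    }
    data <- tibble::tibble(
      tki = tki, mutation = mutation,
      exp_ddg = exp_obs, exp_sigma = sigma_exp, censored = censored
    )
    for (sp in methods) {
      latent <- ddg_true + rnorm(m, 0, sp$rmse)
      if (sp$deterministic) {
        data[[method_col(sp$name)]] <- latent
        data[[method_sigma_col(sp$name)]] <- 0
      } else {
        k <- sp$replicates
        sigma_run <- rep_len(sp$sigma_stat, m) * sqrt(k)
        reps <- matrix(rnorm(m * k, mean = rep(latent, k),
                             sd = rep(sigma_run, k)), nrow = m)
        data[[method_col(sp$name)]] <- rowMeans(reps)
        data[[method_sigma_col(sp$name)]] <-
          apply(reps, 1, sd) / sqrt(k)
        for (j in seq_len(k)) {
          data[[sprintf("%s_rep%d", sp$name, j)]] <- reps[, j]
        }
      }
    }
    structure(
      list(
        data = data,
        truth = tibble::tibble(tki = tki, mutation = mutation,
                               ddg_true = ddg_true),
        config = list(
          m = m, mu_mut = mu_mut, sigma_mut = sigma_mut,
          methods = methods, sigma_exp = sigma_exp,
          censor_at = censor_at, n_tki = n_tki, seed = seed
        )
      ),
      class = "synthetic_benchmark"
    )
  })
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_benchmark> m = %d, mu_mut = %g, sigma_mut = %g, sigma_exp = %g\n",
    cfg$m, cfg$mu_mut, cfg$sigma_mut, cfg$sigma_exp
  ))
  cat("methods:",
      paste(vapply(cfg$methods, function(s) {
        sprintf("%s (rmse %g%s)", s$name, s$rmse,
                if (s$deterministic) ", deterministic" else "")
      }, character(1)), collapse = "; "), "\n")
  cat(sprintf("censored: %d of %d\n", sum(x$data$censored), cfg$m))
  invisible(x)
}

#' Generate paired measurements of the same effects by two noisy sources
#'
#' Emulates the inter-laboratory cross-comparison used to calibrate
#' experimental variability: each pair is the same true effect observed twice
#' with independent normal noise of standard deviation `sigma_exp`, so the
#' RMSE between the two columns converges to `sigma_exp * sqrt(2)`.
#'
#' @param m Number of pairs (at least 2).
#' @param sigma_exp Per-measurement noise standard deviation (kcal/mol).
#' @param mu_mut,sigma_mut Background distribution of the true effects.
#' @param seed Optional integer seed.
#' @return Tibble with columns `ddg_true`, `value_a`, `value_b`.
#' @seealso [pairwise_rmse()], [sigma_from_pairwise_rmse()]
#' @export
generate_interlab_pairs <- function(m, sigma_exp = 0.57, mu_mut = 0.05,
                                    sigma_mut = 1.2, seed = NULL) {
  stopifnot(m >= 2, sigma_exp >= 0, sigma_mut > 0)
  with_seed(seed, {
    truth <- rnorm(m, mu_mut, sigma_mut)
    tibble::tibble(
      ddg_true = truth,
      value_a = truth + rnorm(m, 0, sigma_exp),
      value_b = truth + rnorm(m, 0, sigma_exp)
    )
  })
}
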