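#' Percentile bootstrap confidence interval for any benchmark statistic
#'
#' Resamples whole (TKI, mutation) rows with replacement, recomputes the
#' statistic on each resample, and reports the empirical 2.5th/97.5th
#' percentiles (for `alpha = 0.05`) around the full-data point estimate.
#' Percentiles use linear interpolation between order statistics
#' (`quantile()` type 7). Resamples on which the statistic is `NA` (e.g. a
#' sensitivity when no resistant record was drawn) are skipped and counted.
#'
#' @param data A data frame; rows are the resampling unit.
#' @param statistic Function `data -> single number`.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param alpha Two-sided miscoverage level (default 0.05 for a 95% CI).
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards. Identical seeds give identical intervals.
#' @param strata Optional column name: resample within each stratum
#'   (e.g. per TKI) instead of pooling all rows.
#' @return One-row tibble: `value`, `ci_low`, `ci_high`, `n`, `n_boot`,
#'   `n_na` (resamples skipped).
#' @examples
#' d <- tibble::tibble(err = c(0, 1, 2))
#' bootstrap_ci(d, function(x) mean(abs(x$err)), seed = 1)
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000, alpha = 0.05,
                         seed = NULL, strata = NULL) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  stopifnot(n_boot >= 1, alpha > 0, alpha < 1)
  value <- statistic(data)
  if (!is.numeric(value) || length(value) != 1L) {
    abort("`statistic` must return a single number.")
  }
  if (is.na(value)) {
    abort("`statistic` is NA on the full dataset.")
  }
  idx_groups <- if (is.null(strata)) {
    list(seq_len(nrow(data)))
  } else {
    if (!strata %in% names(data)) abort(sprintf("No column '%s' to stratify on.", strata))
    split(seq_len(nrow(data)), data[[strata]])
  }
  stats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(idx_groups, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      out <- statistic(data[take, , drop = FALSE])
      if (length(out) != 1L) NA_real_ else as.numeric(out)
    }, numeric(1))
  })
  ok <- !is.na(stats)
  ci <- quantile(stats[ok], c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  tibble::tibble(
    value = value,
    ci_low = ci[1],
    ci_high = ci[2],
    n = nrow(data),
    n_boot = n_boot,
    n_na = sum(!ok)
  )
}

#' Root-mean-square difference between paired measurements
#'
#' For the same (TKI, mutation) measured by two sources (two labs, or an
#' IC50-derived versus a Kd-derived ddG), returns
#' `sqrt(mean((a - b)^2))` — the empirical inter-source RMSE.
#'
#' @param pairs A data frame with at least two numeric columns, or `a`/`b`
#'   column names given explicitly.
#' @param a,b Column names of the two sources; default the first two numeric
#'   columns.
#' @return RMSE (kcal/mol).
#' @examples
#' pairwise_rmse(tibble::tibble(a = c(0, 0), b = c(1, -1))) # 1
#' @export
pairwise_rmse <- function(pairs, a = NULL, b = NULL) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0) abort("`pairs` must contain at least one pair.")
  if (is.null(a) || is.null(b)) {
    num <- names(pairs)[vapply(pairs, is.numeric, logical(1))]
    if (length(num) < 2) abort("`pairs` needs two numeric columns.")
    a <- a %||% num[1]
    b <- b %||% num[2]
  }
  x <- pairs[[a]]
  y <- pairs[[b]]
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("Pairs must be finite.")
  sqrt(mean((x - y)^2))
}

#' Per-measurement noise implied by an inter-source RMSE
#'
#' If two sources each measure the same true value with independent noise of
#' standard deviation `sigma`, the RMSE of their difference is `sigma *
#' sqrt(2)`. Inverting, `sigma = rmse / sqrt(2)`: an inter-lab RMSE of 0.81
#' kcal/mol implies a per-measurement experimental noise of 0.57 kcal/mol.
#'
#' @param rmse Non-negative inter-source RMSE (kcal/mol). Vectorised.
#' @return Per-measurement standard deviation (kcal/mol).
#' @examples
#' sigma_from_pairwise_rmse(0.81) # about 0.57
#' @export
sigma_from_pairwise_rmse <- function(rmse) {
  if (any(!is.finite(rmse)) || any(rmse < 0)) {
    abort("`rmse` must be non-negative and finite.")
  }
  rmse / sqrt(2)
}
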