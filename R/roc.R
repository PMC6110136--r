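#' ROC curve by stepped cutoff sweep with trapezoidal AUC
#'
#' Experimental positives (resistant) and negatives (susceptible) are fixed by
#' `threshold` (censored records count as resistant). The classification
#' cutoff applied to the *predictions* is then swept from the minimum to the
#' maximum predicted ddG in steps of `step` kcal/mol; at each cutoff a
#' prediction is called resistant when it exceeds the cutoff (strict
#' inequality, ties susceptible) and the true/false positive rates are
#' recorded. The corner points (0,0) and (1,1) are always appended so the
#' curve is anchored even when extreme predictions are tied — in particular a
#' constant predictor yields a single interior point and an AUC of exactly
#' 0.50. AUC is computed with the trapezoidal rule over the
#' false-positive-rate-sorted points.
#'
#' @param data A benchmark tibble.
#' @param method Predictor name.
#' @param threshold A [resistance_cutoff()] or numeric cutoff defining the
#'   experimental classes.
#' @param step Cutoff step in kcal/mol (default 0.001).
#' @return A `ddg_roc` object: `points` (tibble of `cutoff`, `fpr`, `tpr`;
#'   anchors have `NA` cutoffs), `auc`, `method`, `n`, `step`.
#' @examples
#' bench <- generate_benchmark(m = 60, seed = 4)
#' r <- roc_curve(bench$data, "fep")
#' r$auc
#' @export
roc_curve <- function(data, method, threshold = resistance_cutoff(10),
                      step = 0.001) {
  data <- validate_benchmark(data)
  check_method(data, method)
  stopifnot(is.numeric(step), length(step) == 1L, step > 0)
  labels <- classify_resistance(data$exp_ddg, threshold, data$censored)
  pos <- data[[method_col(method)]][labels == "resistant"]
  neg <- data[[method_col(method)]][labels == "susceptible"]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("Both experimental classes must be present to sweep a ROC curve.")
  }
  pred <- c(pos, neg)
  lo <- min(pred)
  hi <- max(pred)
  cuts <- seq(lo, hi, by = step)
  if (cuts[length(cuts)] < hi) cuts <- c(cuts, hi)
  # count of predictions strictly above each cutoff, via sorted lookups
  sp <- sort(pos)
  sn <- sort(neg)
  tpr <- (length(sp) - findInterval(cuts, sp)) / length(sp)
  fpr <- (length(sn) - findInterval(cuts, sn)) / length(sn)
  points <- tibble::tibble(cutoff = cuts, fpr = fpr, tpr = tpr)
  points <- dplyr::bind_rows(
    points,
    tibble::tibble(cutoff = NA_real_, fpr = c(0, 1), tpr = c(0, 1))
  )
  points <- dplyr::arrange(points, .data$fpr, .data$tpr)
  auc <- trapezoid_auc(points$fpr, points$tpr)
  structure(
    list(
      points = points,
      auc = auc,
      method = method,
      n = nrow(data),
      n_pos = length(pos),
      n_neg = length(neg),
      step = step
    ),
    class = "ddg_roc"
  )
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.ddg_roc <- function(x, ...) {
  cat(sprintf(
    "<ddg_roc> method = %s, AUC = %.3f (n = %d: %d resistant, %d susceptible)\n",
    x$method, x$auc, x$n, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @export
tidy.ddg_roc <- function(x, ...) x$points

#' @export
glance.ddg_roc <- function(x, ...) {
  tibble::tibble(
    method = x$method, auc = x$auc, n = x$n,
    n_pos = x$n_pos, n_neg = x$n_neg, step = x$step
  )
}

#' Add a naive constant predictor
#'
#' The naive baseline assigns ddG = 0.00 kcal/mol to every mutation: it calls
#' everything susceptible at any positive cutoff (zero sensitivity) and its
#' stepped-sweep ROC-AUC is exactly 0.50.
#'
#' @param data A benchmark tibble.
#' @param name Method name for the added columns (default `"naive"`).
#' @return `data` with `{name}_ddg = 0` and `{name}_sigma = 0` columns.
#' @export
naive_predictions <- function(data, name = "naive") {
  data <- validate_benchmark(data)
  data[[method_col(name)]] <- 0
  data[[method_sigma_col(name)]] <- 0
  data
}

#' Optimal slope scaling of a predictor
#'
#' Finds the multiplicative slope minimising the RMSE between scaled
#' predictions and experiment over the non-censored records: least squares
#' through the origin, `slope = sum(pred * exp) / sum(pred^2)`. Returns the
#' slope and the minimised RMSE; scaling never increases RMSE relative to the
#' unscaled predictions.
#'
#' @param data A benchmark tibble.
#' @param method Predictor name.
#' @return One-row tibble: `method`, `slope`, `rmse` (the minimised RMSE),
#'   `n` (non-censored records used).
#' @export
fit_scale <- function(data, method) {
  data <- validate_benchmark(data)
  check_method(data, method)
  d <- data[!data$censored, , drop = FALSE]
  if (nrow(d) < 2) abort("Need at least 2 non-censored records to fit a slope.")
  p <- d[[method_col(method)]]
  e <- d$exp_ddg
  if (all(p == 0)) abort("All predictions are zero; slope is undefined.")
  slope <- sum(p * e) / sum(p^2)
  tibble::tibble(
    method = method,
    slope = slope,
    rmse = sqrt(mean((slope * p - e)^2)),
    n = nrow(d)
  )
}

#' Inverse-variance consensus of two slope-scaled predictors
#'
#' Each predictor is first slope-scaled against experiment ([fit_scale()],
#' non-censored records only; the learned slope is applied to all records).
#' The consensus prediction is the inverse-variance weighted average of the
#' two scaled predictions, with weights `1 / rmse^2` from each method's
#' minimised RMSE — identical weights across records. With
#' `per_record = TRUE` the weights are instead `1 / sigma_i^2` from each
#' record's own statistical uncertainty (records where both sigmas are zero
#' fall back to the RMSE weights).
#'
#' @param data A benchmark tibble.
#' @param method_a,method_b The two predictor names.
#' @param name Name for the added consensus columns (default `"consensus"`).
#' @param per_record Use per-record `1/sigma_i^2` weights instead of global
#'   `1/RMSE^2` weights.
#' @return `data` with `{name}_ddg` and `{name}_sigma` columns added; the
#'   scaling table is attached as attribute `"scaling"`.
#' @export
consensus_predictions <- function(data, method_a, method_b,
                                  name = "consensus", per_record = FALSE) {
  data <- validate_benchmark(data)
  sa <- fit_scale(data, method_a)
  sb <- fit_scale(data, method_b)
  a <- sa$slope * data[[method_col(method_a)]]
  b <- sb$slope * data[[method_col(method_b)]]
  if (sa$rmse == 0 && sb$rmse == 0) {
    warn("Both scaled RMSEs are zero; falling back to an unweighted mean.")
    wa <- wb <- rep(0.5, nrow(data))
  } else {
    wa <- rep(1 / sa$rmse^2, nrow(data))
    wb <- rep(1 / sb$rmse^2, nrow(data))
  }
  if (per_record) {
    siga <- data[[method_sigma_col(method_a)]] %||% rep(0, nrow(data))
    sigb <- data[[method_sigma_col(method_b)]] %||% rep(0, nrow(data))
    use <- siga > 0 | sigb > 0
    wa[use] <- 1 / pmax(siga[use], 1e-12)^2
    wb[use] <- 1 / pmax(sigb[use], 1e-12)^2
  }
  data[[method_col(name)]] <- (wa * a + wb * b) / (wa + wb)
  data[[method_sigma_col(name)]] <- sqrt(1 / (wa + wb))
  attr(data, "scaling") <- dplyr::bind_rows(sa, sb)
  data
}
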