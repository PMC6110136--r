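#' Build a 2x2 truth table for a predictor
#'
#' Cross-tabulates experimental against predicted resistance calls at a common
#' cutoff. Experimental classes come from `exp_ddg` with the censoring rule of
#' [classify_resistance()]: a censored measurement (assay ceiling exceeded) is
#' experimentally resistant and is *included* in classification analysis even
#' though it is excluded from quantitative error metrics. Predicted classes
#' come from the method's point predictions, which are never censored.
#'
#' @param data A benchmark tibble (see [benchmark-table]).
#' @param method Predictor name, e.g. `"fep"`.
#' @param threshold A [resistance_cutoff()] or numeric cutoff (kcal/mol).
#' @return A `truth_table` object with counts `tp` (resistant, predicted
#'   resistant), `fn`, `fp`, `tn`.
#' @seealso [accuracy()], [classification_metrics()], [threshold_sweep()]
#' @export
truth_table <- function(data, method, threshold = resistance_cutoff(10)) {
  data <- validate_benchmark(data)
  check_method(data, method)
  pred <- data[[method_col(method)]]
  if (any(!is.finite(pred))) {
    key <- paste(data$tki, data$mutation, sep = "/")
    abort(paste0(
      "Missing '", method, "' prediction for: ",
      paste(key[!is.finite(pred)], collapse = ", ")
    ))
  }
  exp_class <- classify_resistance(data$exp_ddg, threshold, data$censored)
  pred_class <- classify_resistance(pred, threshold)
  new_truth_table(
    tp = sum(exp_class == "resistant" & pred_class == "resistant"),
    fn = sum(exp_class == "resistant" & pred_class == "susceptible"),
    fp = sum(exp_class == "susceptible" & pred_class == "resistant"),
    tn = sum(exp_class == "susceptible" & pred_class == "susceptible"),
    method = method,
    threshold = threshold
  )
}

#' Construct a truth table from known counts
#'
#' Useful for recomputing classification metrics from published confusion
#' matrices.
#'
#' @param tp,fn,fp,tn Non-negative counts: rows are experimental classes
#'   (resistant = positive), columns predicted classes.
#' @param method Optional label.
#' @return A `truth_table` object.
#' @examples
#' as_truth_table(tp = 9, fn = 9, fp = 8, tn = 105)
#' @export
as_truth_table <- function(tp, fn, fp, tn, method = NULL) {
  new_truth_table(tp, fn, fp, tn, method = method, threshold = NULL)
}

new_truth_table <- function(tp, fn, fp, tn, method = NULL, threshold = NULL) {
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Truth-table entries must be non-negative integers.")
  }
  structure(
    list(
      tp = as.integer(tp), fn = as.integer(fn),
      fp = as.integer(fp), tn = as.integer(tn),
      method = method, threshold = threshold
    ),
    class = "truth_table"
  )
}

#' @export
print.truth_table <- function(x, ...) {
  hdr <- if (is.null(x$method)) "" else sprintf(" [%s]", x$method)
  cat(sprintf("<truth_table>%s n = %d\n", hdr, truth_table_n(x)))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(
                c("exp resistant", "exp susceptible"),
                c("pred r", "pred s")
              ))
  m["exp susceptible", ] <- c(x$fp, x$tn)
  m["exp resistant", ] <- c(x$tp, x$fn)
  print(m)
  invisible(x)
}

#' Combine truth tables by adding their counts
#'
#' @param e1,e2 `truth_table` objects built at the same threshold.
#' @return A `truth_table` with summed counts.
#' @export
"+.truth_table" <- function(e1, e2) {
  stopifnot(inherits(e1, "truth_table"), inherits(e2, "truth_table"))
  new_truth_table(
    e1$tp + e2$tp, e1$fn + e2$fn, e1$fp + e2$fp, e1$tn + e2$tn,
    method = if (identical(e1$method, e2$method)) e1$method else NULL,
    threshold = e1$threshold
  )
}

truth_table_n <- function(x) x$tp + x$fn + x$fp + x$tn

#' @rdname classification_metrics
#' @export
accuracy <- function(x) {
  stopifnot(inherits(x, "truth_table"))
  n <- truth_table_n(x)
  if (n == 0) abort("Empty truth table.")
  (x$tp + x$tn) / n
}

#' @rdname classification_metrics
#' @export
sensitivity <- function(x) {
  stopifnot(inherits(x, "truth_table"))
  if (truth_table_n(x) == 0) abort("Empty truth table.")
  if (x$tp + x$fn == 0) return(NA_real_)
  x$tp / (x$tp + x$fn)
}

#' @rdname classification_metrics
#' @export
specificity <- function(x) {
  stopifnot(inherits(x, "truth_table"))
  if (truth_table_n(x) == 0) abort("Empty truth table.")
  if (x$fp + x$tn == 0) return(NA_real_)
  x$tn / (x$fp + x$tn)
}

#' Classification metrics from a truth table
#'
#' Accuracy is the fraction of all calls that are correct,
#' `(tp + tn) / n`. Sensitivity (true positive rate) is the fraction of
#' experimentally resistant mutations predicted resistant, `tp / (tp + fn)`.
#' Specificity (true negative rate) is the fraction of experimentally
#' susceptible mutations predicted susceptible, `tn / (fp + tn)`.
#' Sensitivity and specificity are `NA` when their class is absent from the
#' data (e.g. an inhibitor with no resistant mutation).
#'
#' @param x A `truth_table`.
#' @return `classification_metrics()` returns a one-row tibble with `n`, the
#'   four counts, `accuracy`, `specificity` and `sensitivity`; the individual
#'   accessors return bare numbers.
#' @examples
#' tt <- as_truth_table(tp = 9, fn = 9, fp = 8, tn = 105)
#' accuracy(tt)
#' classification_metrics(tt)
#' @export
classification_metrics <- function(x) {
  stopifnot(inherits(x, "truth_table"))
  tibble::tibble(
    method = x$method %||% NA_character_,
    n = truth_table_n(x),
    tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
    accuracy = accuracy(x),
    specificity = specificity(x),
    sensitivity = sensitivity(x)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
tidy.truth_table <- function(x, ...) classification_metrics(x)

#' Quantitative error metrics
#'
#' Mean unsigned error (`mue()`) is the average absolute difference between
#' predicted and experimental ddG; root-mean-square error (`rmse()`) is the
#' square root of the average squared difference. Censored experimental
#' records carry only a lower bound on ddG and are excluded from both.
#' `MUE <= RMSE` always, with equality iff all absolute errors are equal.
#'
#' @param data A benchmark tibble.
#' @param method Predictor name.
#' @return A single number (kcal/mol).
#' @examples
#' bench <- generate_benchmark(m = 50, seed = 1)
#' mue(bench$data, "fep")
#' rmse(bench$data, "fep")
#' @export
mue <- function(data, method) {
  err <- prediction_errors(data, method)
  mean(abs(err))
}

#' @rdname mue
#' @export
rmse <- function(data, method) {
  err <- prediction_errors(data, method)
  sqrt(mean(err^2))
}

prediction_errors <- function(data, method) {
  data <- validate_benchmark(data)
  check_method(data, method)
  keep <- !data$censored
  if (!any(keep)) {
    abort("All records are censored; quantitative metrics are undefined.")
  }
  data[[method_col(method)]][keep] - data$exp_ddg[keep]
}

#' Quantitative and classification metrics for one or more methods
#'
#' A convenience wrapper producing one row per method (optionally per TKI)
#' with the quantitative-subset size `n_quant` (censored records excluded),
#' MUE, RMSE, the classification-set size `n_class` (censored included) and
#' accuracy/specificity/sensitivity at the given cutoff.
#'
#' @param data A benchmark tibble.
#' @param methods Character vector of method names; default all methods found.
#' @param threshold A [resistance_cutoff()] or numeric cutoff.
#' @param by_tki Also stratify by inhibitor?
#' @return A tibble.
#' @export
summarize_benchmark <- function(data, methods = NULL,
                                threshold = resistance_cutoff(10),
                                by_tki = FALSE) {
  data <- validate_benchmark(data)
  methods <- methods %||% benchmark_methods(data)
  groups <- if (by_tki) split(data, data$tki) else list(all = data)
  purrr::map_dfr(names(groups), function(g) {
    d <- groups[[g]]
    purrr::map_dfr(methods, function(m) {
      tt <- truth_table(d, m, threshold)
      tibble::tibble(
        dataset = g,
        method = m,
        n_quant = sum(!d$censored),
        mue = mue(d, m),
        rmse = rmse(d, m),
        n_class = nrow(d),
        accuracy = accuracy(tt),
        specificity = specificity(tt),
        sensitivity = sensitivity(tt)
      )
    })
  })
}

#' Re-evaluate classification across fold-change cutoffs
#'
#' Both the experimental and the predicted classes are re-thresholded at each
#' fold (e.g. 10-, 20-, 100-fold affinity change), and the truth-table counts
#' and metrics recomputed. Censored experimental records remain resistant at
#' every fold.
#'
#' @param data A benchmark tibble.
#' @param method Predictor name.
#' @param folds Numeric vector of fold changes, all > 1.
#' @param constants [thermo_constants()] used to convert folds to cutoffs.
#' @return A tibble with one row per fold: `fold`, `cutoff`, the four counts
#'   and `accuracy`, `specificity`, `sensitivity`.
#' @export
threshold_sweep <- function(data, method, folds = c(10, 20, 100),
                            constants = thermo_constants()) {
  if (any(folds <= 1)) abort("All folds must be > 1.")
  purrr::map_dfr(folds, function(f) {
    th <- resistance_cutoff(f, constants)
    tt <- truth_table(data, method, th)
    dplyr::bind_cols(
      tibble::tibble(fold = f, cutoff = th$cutoff),
      dplyr::select(classification_metrics(tt), -"method")
    )
  })
}
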