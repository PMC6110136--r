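#' @export
autoplot.ddg_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("%s: ROC-AUC = %.2f (n = %d)",
                      object$method, object$auc, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.intrinsic_error_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$draws, c("mu_mut", "sigma_mut", "rmse_method"),
    names_to = "term", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(
      x = "kcal/mol", y = "posterior density",
      title = sprintf("Intrinsic-error posterior: %s (M = %d)",
                      object$method, object$M)
    ) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-experimental scatter plot with combined error bars
#'
#' Plots predictions against experimental ddG values. Vertical error bars
#' show the total estimated error `sqrt(sigma_ff^2 + sigma^2)` combining the
#' assumed random forcefield error with the method's per-record statistical
#' uncertainty; horizontal bars show the experimental variability. The shaded
#' band marks agreement within the resistance cutoff; dashed lines mark the
#' cutoff itself, splitting the plane into classification quadrants.
#'
#' @param data A benchmark tibble.
#' @param method Predictor name.
#' @param threshold A [resistance_cutoff()] or numeric cutoff.
#' @param constants [thermo_constants()]; `sigma_ff` feeds the error bars.
#' @param sigma_exp Experimental error bar half-width (kcal/mol).
#' @return A ggplot object.
#' @export
plot_benchmark <- function(data, method, threshold = resistance_cutoff(10),
                           constants = thermo_constants(), sigma_exp = 0.57) {
  data <- validate_benchmark(data)
  check_method(data, method)
  cutoff <- cutoff_value(threshold)
  sig_col <- method_sigma_col(method)
  sigma_calc <- if (sig_col %in% names(data)) data[[sig_col]] else 0
  df <- tibble::tibble(
    exp = data$exp_ddg,
    pred = data[[method_col(method)]],
    total_err = combined_error(constants$sigma_ff, sigma_calc),
    censored = data$censored
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exp, y = .data$pred)) +
    ggplot2::geom_ribbon(
      data = tibble::tibble(
        exp = range(df$exp) + c(-0.5, 0.5)
      ),
      ggplot2::aes(x = .data$exp, ymin = .data$exp - cutoff,
                   ymax = .data$exp + cutoff),
      inherit.aes = FALSE, fill = "gold", alpha = 0.25
    ) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$pred - .data$total_err,
                   ymax = .data$pred + .data$total_err),
      width = 0, colour = "grey70"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$exp - sigma_exp, xmax = .data$exp + sigma_exp),
      height = 0, colour = "grey70"
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(paste("experimental ", Delta * Delta * G, " (kcal/mol)")),
      y = expression(paste("predicted ", Delta * Delta * G, " (kcal/mol)")),
      title = method
    ) +
    ggplot2::theme_minimal()
}
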