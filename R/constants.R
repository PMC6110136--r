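#' Thermodynamic constants for potency-to-energy conversion
#'
#' Bundles the ideal gas constant, the temperature at which fold changes in
#' potency are converted to free energies, and the assumed random forcefield
#' error used when drawing combined error bars for physics-based predictions.
#'
#' The default temperature is 298.15 K: the widely quoted resistance cutoffs
#' (10-fold = 1.36 kcal/mol, 20-fold = 1.77 kcal/mol) are RT ln(fold) evaluated
#' at room temperature, and 298.15 K reproduces those printed constants.
#'
#' @param temperature Temperature in Kelvin. Must be positive.
#' @param gas_constant Ideal gas constant in kcal/(mol K).
#' @param sigma_ff Assumed forcefield error treated as a random error,
#'   kcal/mol. Used by [combined_error()] callers and plotting helpers.
#' @return An object of class `thermo_constants`.
#' @examples
#' thermo_constants()
#' thermo_constants(temperature = 300)
#' @export
thermo_constants <- function(temperature = 298.15,
                             gas_constant = 1.9872e-3,
                             sigma_ff = 0.9) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  stopifnot(is.numeric(gas_constant), length(gas_constant) == 1L, gas_constant > 0)
  stopifnot(is.numeric(sigma_ff), length(sigma_ff) == 1L, sigma_ff >= 0)
  structure(
    list(
      temperature = temperature,
      gas_constant = gas_constant,
      sigma_ff = sigma_ff
    ),
    class = "thermo_constants"
  )
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat(
    sprintf(
      "<thermo_constants> T = %g K, R = %g kcal/(mol K), sigma_ff = %g kcal/mol\n",
      x$temperature, x$gas_constant, x$sigma_ff
    )
  )
  invisible(x)
}

# RT in kcal/mol
rt_energy <- function(constants) {
  stopifnot(inherits(constants, "thermo_constants"))
  constants$gas_constant * constants$temperature
}

#' Combine two independent error components in quadrature
#'
#' Returns `sqrt(sigma_a^2 + sigma_b^2)`, the standard deviation of the sum of
#' two independent zero-mean errors. Typical use: combining an assumed
#' forcefield error with experimental variability or a replicate statistical
#' uncertainty when drawing total error bars.
#'
#' @param sigma_a,sigma_b Non-negative error magnitudes (kcal/mol). Vectorised
#'   and recycled.
#' @return Numeric vector of combined errors.
#' @examples
#' combined_error(0.9, 0.57)
#' combined_error(3, 4) # 5
#' @export
combined_error <- function(sigma_a, sigma_b) {
  if (any(!is.finite(sigma_a)) || any(!is.finite(sigma_b))) {
    abort("`sigma_a` and `sigma_b` must be finite.")
  }
  if (any(sigma_a < 0) || any(sigma_b < 0)) {
    abort("Error components must be non-negative.")
  }
  sqrt(sigma_a^2 + sigma_b^2)
}
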