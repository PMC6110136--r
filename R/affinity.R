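#' Convert IC50 to an inhibition constant under ATP competition
#'
#' For an ATP-competitive inhibitor obeying Michaelis-Menten kinetics, the
#' measured half-maximal inhibitory concentration is related to the
#' inhibition constant Ki through the substrate (ATP) concentration `s0` and
#' the Michaelis constant `km` via `ic50 = ki / (1 + s0/km)`, so
#' `ki = ic50 * (1 + s0/km)`.
#'
#' Note: the conventional Cheng-Prusoff relation for a competitive inhibitor
#' is `ic50 = ki * (1 + s0/km)`; the form implemented here is its reciprocal
#' correction, used by some benchmark compilations. Both coincide in the limit
#' `km >> s0`, where `ic50 -> ki`, which is the regime usually invoked when
#' equating ddG values derived from delta-pIC50 with binding free-energy
#' changes; relative free energies are unaffected when `s0/km` is shared
#' between wild type and mutant.
#'
#' @param ic50 Measured IC50 (nM). Must be positive. Vectorised.
#' @param s0 Substrate (ATP) concentration, same units as `km`. Non-negative.
#' @param km Michaelis constant for ATP. Positive.
#' @return Ki in the same units as `ic50`.
#' @examples
#' ki_from_ic50(5, s0 = 0, km = 10) # 5: no-substrate limit
#' ki_from_ic50(5, s0 = 10, km = 10) # 10
#' @export
ki_from_ic50 <- function(ic50, s0 = 0, km = 1) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    abort("`ic50` must be positive and finite.")
  }
  stopifnot(is.numeric(s0), all(s0 >= 0), is.numeric(km), all(km > 0))
  ic50 * (1 + s0 / km)
}

#' Binding free-energy change from wild-type and mutant potencies
#'
#' Computes `ddG = -RT * log(wt / mut)` in kcal/mol from paired potency
#' measurements (IC50 or Kd, any common concentration unit). A positive value
#' means the mutant binds the inhibitor more weakly (potency loss, candidate
#' resistance); the function is antisymmetric under swapping `wt` and `mut`.
#'
#' @param wt,mut Positive potencies for the wild-type and mutant protein.
#'   Vectorised and recycled.
#' @param constants A [thermo_constants()] object; the temperature sets RT.
#' @return ddG in kcal/mol.
#' @examples
#' ddg_from_potencies(5, 50) # 10-fold loss: about 1.36 kcal/mol
#' ddg_from_potencies(5, 5) # 0
#' @export
ddg_from_potencies <- function(wt, mut, constants = thermo_constants()) {
  if (any(!is.finite(wt)) || any(!is.finite(mut)) || any(wt <= 0) || any(mut <= 0)) {
    abort("Potencies must be positive and finite.")
  }
  -rt_energy(constants) * log(wt / mut)
}

#' Binding free-energy change from pIC50 values
#'
#' `ddG = RT * ln(10) * (pic50_wt - pic50_mut)` kcal/mol, algebraically
#' identical to [ddg_from_potencies()] applied to the corresponding IC50s
#' (`pIC50 = -log10 IC50`). A mutant with a lower pIC50 (weaker inhibition)
#' yields a positive ddG.
#'
#' @param pic50_wt,pic50_mut pIC50 of the wild-type and mutant protein.
#' @inheritParams ddg_from_potencies
#' @return ddG in kcal/mol.
#' @export
ddg_from_pic50 <- function(pic50_wt, pic50_mut, constants = thermo_constants()) {
  if (any(!is.finite(pic50_wt)) || any(!is.finite(pic50_mut))) {
    abort("pIC50 values must be finite.")
  }
  rt_energy(constants) * log(10) * (pic50_wt - pic50_mut)
}

#' Resistance cutoff from a fold change in affinity
#'
#' A mutation is called resistant when it weakens binding by more than a given
#' fold change; the equivalent free-energy cutoff is `RT * log(fold)`. At
#' 298.15 K, folds 10 / 20 / 100 give 1.36 / 1.77 / 2.73 kcal/mol (2 d.p.).
#'
#' @param fold Fold change in affinity, > 1.
#' @param constants A [thermo_constants()] object.
#' @return An object of class `fold_threshold` with fields `fold`, `cutoff`
#'   (kcal/mol) and `constants`.
#' @examples
#' resistance_cutoff(10)
#' resistance_cutoff(20)$cutoff
#' @export
resistance_cutoff <- function(fold = 10, constants = thermo_constants()) {
  if (!is.numeric(fold) || length(fold) != 1L || !is.finite(fold) || fold <= 1) {
    abort("`fold` must be a single finite number greater than 1.")
  }
  structure(
    list(
      fold = fold,
      cutoff = rt_energy(constants) * log(fold),
      constants = constants
    ),
    class = "fold_threshold"
  )
}

#' @export
print.fold_threshold <- function(x, ...) {
  cat(sprintf(
    "<fold_threshold> %g-fold affinity change = %.2f kcal/mol at %g K\n",
    x$fold, x$cutoff, x$constants$temperature
  ))
  invisible(x)
}

# Accept a fold_threshold or a bare numeric cutoff (kcal/mol).
cutoff_value <- function(threshold) {
  if (inherits(threshold, "fold_threshold")) {
    threshold$cutoff
  } else if (is.numeric(threshold) && length(threshold) == 1L && is.finite(threshold)) {
    threshold
  } else {
    abort("`threshold` must be a `fold_threshold` or a single finite number.")
  }
}

#' Classify mutations as resistant or susceptible
#'
#' Susceptible means the affinity loss does not exceed the threshold
#' (`ddg <= cutoff`, ties susceptible); resistant means `ddg > cutoff`.
#' A censored measurement (potency beyond the assay ceiling, so the reported
#' ddG is only a lower bound) is always called resistant regardless of its
#' recorded value.
#'
#' @param ddg Free-energy changes, kcal/mol. Vectorised.
#' @param threshold A [resistance_cutoff()] object or a numeric cutoff in
#'   kcal/mol.
#' @param censored Logical vector, recycled: is the measurement only a lower
#'   bound?
#' @return Factor with levels `susceptible`, `resistant`.
#' @examples
#' classify_resistance(c(0.5, 1.36, 1.4), resistance_cutoff(10))
#' classify_resistance(1.0, resistance_cutoff(10), censored = TRUE)
#' @export
classify_resistance <- function(ddg, threshold = resistance_cutoff(10),
                                censored = FALSE) {
  cutoff <- cutoff_value(threshold)
  if (any(!is.finite(ddg))) {
    abort("`ddg` must be finite.")
  }
  censored <- rep_len(as.logical(censored), length(ddg))
  resistant <- censored | (ddg > cutoff)
  factor(
    ifelse(resistant, "resistant", "susceptible"),
    levels = c("susceptible", "resistant")
  )
}
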