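#' Thermodynamic-cycle composition of decoupling free energies
#'
#' Sorption (or hydration) free energies follow from a thermodynamic cycle:
#' the free energy of transferring a sorbate from vacuum into an environment
#' equals the difference between the decoupling free energy in vacuum and in
#' that environment, dG_sorb = dG_vac - dG_env. Uncertainties combine in
#' quadrature.
#'
#' @param dG_vac Decoupling free energy in vacuum ([fe_estimate()] or numeric).
#' @param dG_env Decoupling free energy in the environment (humic-acid matrix
#'   for sorption, water for hydration).
#' @return A [fe_estimate()] with method `"derived"`.
#' @export
sorption_free_energy <- function(dG_vac, dG_env) {
  a <- as_fe(dG_vac); b <- as_fe(dG_env)
  fe_estimate(a$value - b$value, sqrt(a$uncertainty^2 + b$uncertainty^2),
              method = "derived")
}

#' @rdname sorption_free_energy
#' @export
hydration_free_energy <- function(dG_vac, dG_env) {
  sorption_free_energy(dG_vac, dG_env)
}

#' Relative sorption free energy between hydration states
#'
#' Difference between the hydrated-matrix and dry-matrix sorption free
#' energies of a compound, with errors propagated in quadrature. Report
#' output is conventionally rounded to 0.1 kJ/mol; the returned object is
#' unrounded.
#'
#' @param hyd,dry [fe_estimate()] (or numeric) sorption free energies.
#' @return A [fe_estimate()].
#' @export
relative_sorption <- function(hyd, dry) {
  h <- as_fe(hyd); d <- as_fe(dry)
  fe_estimate(h$value - d$value, sqrt(h$uncertainty^2 + d$uncertainty^2),
              method = "derived")
}

#' Water activity from a transfer free energy
#'
#' The hydration level of the matrix is characterised by the water activity
#' a_w = exp(dG_water->matrix / RT), computed from the free energy of
#' transferring one water molecule from bulk water into the matrix.
#'
#' @param dG_water_to_env Transfer free energy, kJ/mol.
#' @param temperature Temperature in K.
#' @return Dimensionless activity.
#' @export
water_activity <- function(dG_water_to_env, temperature = 300) {
  exp(dG_water_to_env / rt_kj(temperature))
}

#' Convert a partition coefficient to a sorption free energy scale
#'
#' Experimental humic-acid/air partition coefficients relate to the sorption
#' free energy as -RT log K + c, where c is an unknown additive constant.
#' The constant is never estimated here; all comparisons against calculated
#' values use correlations and fixed-slope offsets, which are invariant to c.
#'
#' @param K Partition coefficient, > 0.
#' @param temperature Temperature in K.
#' @param c Additive offset, kJ/mol (default 0).
#' @return Energy in kJ/mol.
#' @export
partition_to_free_energy <- function(K, temperature = 300, c = 0) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("partition_to_free_energy: K must be positive", call. = FALSE)
  -rt_kj(temperature) * log(K) + c
}

#' Anchor a set of energies to be non-positive
#'
#' Shifts a vector of free energies by its maximum so the largest value is 0,
#' preserving ordering and all pairwise differences. Used to put experimental
#' sorption free energies, known only up to an additive constant, on a common
#' non-positive scale.
#'
#' @param values Numeric vector of energies.
#' @return The shifted vector, max exactly 0.
#' @export
anchor_nonpositive <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("anchor_nonpositive: empty input", call. = FALSE)
  values - max(values)
}
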