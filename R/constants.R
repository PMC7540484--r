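#' Physical constants
#'
#' Constants used throughout the package, in the unit system of the
#' simulation conventions adopted here: energies in kJ/mol, lengths in nm,
#' charges in elementary charges, temperatures in K.
#'
#' @format `GAS_CONSTANT` is the molar gas constant in kJ/(mol K);
#'   `COULOMB_CONSTANT` is 1/(4 pi eps0) in kJ mol^-1 nm e^-2.
#' @name constants
NULL

#' @rdname constants
#' @export
GAS_CONSTANT <- 8.314e-3

#' @rdname constants
#' @export
COULOMB_CONSTANT <- 138.935458

# thermal energy RT in kJ/mol
rt_kj <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  GAS_CONSTANT * temperature
}
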