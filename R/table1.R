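#' Reference compound set: sorption free energies in dry and hydrated LHA
#'
#' The embedded benchmark of 18 chemically diverse small organic compounds
#' with calculated sorption free energies (bootstrap errors) in the dry and
#' hydrated Leonardite-humic-acid model and relative experimental sorption
#' free energies for both hydration states (anchored so the full
#' experimental source set is non-positive). The relative calculated value
#' `ddG` is the hydrated-minus-dry difference with errors propagated in
#' quadrature; every row satisfies that identity within print rounding.
#' All energies in kJ/mol.
#'
#' @return Data frame of class `compound_table` with columns `name`,
#'   `group`, `dG_dry`, `err_dry`, `dG_hyd`, `err_hyd`, `ddG`, `err_ddG`,
#'   `ddG_exp_dry`, `ddG_exp_hyd`.
#' @export
table1_fixture <- function() {
  df <- data.frame(
    name = c("propan-2-ol", "3-methylbutan-1-ol", "2-methylpropan-1-ol",
             "propan-1-ol", "pentan-1-ol", "heptan-1-ol", "phenol",
             "cyclopentanol", "p-xylene", "benzaldehyde", "acetophenone",
             "2-propanone", "4-methylpentan-2-one", "2-hexanone",
             "2,4-pentanedione", "isopropylether", "dimethyl succinate",
             "1-undecene"),
    group = c("alcohol", "alcohol", "alcohol", "alcohol", "alcohol",
              "alcohol", "aromatic", "alcohol", "aromatic", "aromatic",
              "aromatic", "ketone", "ketone", "ketone", "ketone", "ether",
              "ester", "alkene"),
    dG_dry = c(-36.8, -45.0, -41.6, -41.4, -46.5, -50.4, -45.8, -40.2,
               -19.6, -38.5, -39.2, -24.2, -32.2, -34.8, -41.1, -29.9,
               -63.6, -35.1),
    err_dry = c(0.5, 1.8, 0.8, 1.1, 1.1, 1.4, 3.4, 1.7, 2.4, 1.2, 2.4,
                1.2, 0.8, 1.1, 2.0, 1.6, 2.0, 2.2),
    dG_hyd = c(-15.2, -18.1, -16.7, -23.5, -20.3, -22.2, -30.3, -16.9,
               3.6, -21.2, -17.1, -9.9, -5.5, -8.4, -20.0, -0.1, -39.9,
               5.9),
    err_hyd = c(1.1, 1.1, 1.9, 1.1, 2.4, 1.3, 1.1, 1.4, 1.4, 0.8, 1.5,
                1.0, 1.2, 1.0, 1.2, 1.2, 1.4, 1.7),
    ddG = c(21.6, 26.9, 24.9, 17.9, 26.2, 28.2, 15.5, 23.3, 23.2, 17.3,
            22.1, 14.3, 26.7, 26.4, 21.1, 29.8, 23.7, 41.0),
    err_ddG = c(1.2, 2.1, 2.1, 1.6, 2.6, 1.9, 3.6, 2.2, 2.8, 1.4, 2.8,
                1.6, 1.4, 1.5, 2.3, 2.0, 2.4, 2.8),
    ddG_exp_dry = c(-5.2, -11.6, -7.6, -8.3, -12.4, -17.8, -19.8, -11.3,
                    -5.6, -12.0, -17.9, -5.2, -7.8, -9.9, -10.2, -1.8,
                    -19.3, -11.6),
    ddG_exp_hyd = c(-9.0, -11.3, -6.5, -9.1, -12.7, -16.8, -22.0, -14.1,
                    -3.4, -14.8, -17.7, -4.5, -5.5, -7.3, -11.6, -1.8,
                    -19.4, -10.6),
    stringsAsFactors = FALSE
  )
  class(df) <- c("compound_table", "data.frame")
  df
}
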