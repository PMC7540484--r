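#' Pairwise nonbonded interaction energy between two groups
#'
#' Sums electrostatic and Lennard-Jones energies over unique pairs (one atom
#' from each group, self pairs excluded) within a cutoff under the minimum-
#' image convention. Electrostatics use a reaction-field correction for a
#' homogeneous dielectric continuum outside the cutoff sphere:
#' E_elec = f q_i q_j (1/r + C_rf r^2 / (2 R_c^3) - (1 + C_rf/2) / R_c),
#' with C_rf = (2 eps_rf - 2) / (2 eps_rf + 1) at zero ionic strength and f
#' the Coulomb constant in kJ mol^-1 nm e^-2. Lennard-Jones parameters
#' combine geometrically: C6_ij = sqrt(C6_i C6_j), C12_ij = sqrt(C12_i C12_j),
#' and E_LJ = C12/r^12 - C6/r^6.
#'
#' @param frame An [md_frame()] with charges and LJ parameters.
#' @param group_A,group_B Integer particle indices.
#' @param cutoff Interaction cutoff R_c, nm (default 1.4).
#' @param eps_rf Reaction-field dielectric permittivity (default 61).
#' @return Named numeric vector `c(electrostatic = , vdw = )` in kJ/mol.
#' @export
pair_interaction_energy <- function(frame, group_A, group_B, cutoff = 1.4,
                                    eps_rf = 61) {
  stopifnot(inherits(frame, "md_frame"))
  if (length(group_A) == 0L || length(group_B) == 0L)
    stop("pair_interaction_energy: empty group", call. = FALSE)
  if (any(!is.finite(frame$charge[c(group_A, group_B)])) ||
      any(!is.finite(frame$c6[c(group_A, group_B)])) ||
      any(!is.finite(frame$c12[c(group_A, group_B)])))
    stop("pair_interaction_energy: missing charges or LJ parameters",
         call. = FALSE)
  crf <- (2 * eps_rf - 2) / (2 * eps_rf + 1)
  rf_const <- (1 + crf / 2) / cutoff
  X <- frame$coordinates
  elec <- 0; vdw <- 0
  seen <- new.env(hash = TRUE)
  for (i in group_A) {
    js <- group_B[group_B != i]
    if (length(js) == 0L) next
    d <- min_image(sweep(X[js, , drop = FALSE], 2, X[i, ]), frame$box)
    r <- sqrt(rowSums(d^2))
    ok <- which(r <= cutoff & r > 1e-12)
    for (k in ok) {
      j <- js[k]
      key <- paste(min(i, j), max(i, j))
      if (!is.null(seen[[key]])) next        # count each unordered pair once
      seen[[key]] <- TRUE
      rij <- r[k]
      elec <- elec + COULOMB_CONSTANT * frame$charge[i] * frame$charge[j] *
        (1 / rij + crf * rij^2 / (2 * cutoff^3) - rf_const)
      c6 <- sqrt(frame$c6[i] * frame$c6[j])
      c12 <- sqrt(frame$c12[i] * frame$c12[j])
      vdw <- vdw + c12 / rij^12 - c6 / rij^6
    }
  }
  c(electrostatic = elec, vdw = vdw)
}
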