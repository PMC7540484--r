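#' Molar fractions by heavy-atom count
#'
#' Species molar fractions computed as the normalised number of heavy
#' (non-hydrogen) particles, the convention used for preferential-solvation
#' and starred Kirkwood-Buff quantities.
#'
#' @param frame An [md_frame()].
#' @param species Optional subset of species to normalise over; default all.
#' @return Named numeric vector summing to 1.
#' @export
heavy_molar_fractions <- function(frame, species = NULL) {
  heavy <- frame$element_class != "hydrogen"
  sp <- frame$species[heavy]
  if (!is.null(species)) sp <- sp[sp %in% species]
  tab <- table(sp)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' Preferential-solvation coefficient from Kirkwood-Buff quantities
#'
#' The elementary formula behind [preferential_solvation()]:
#' delta_B = x_B (G_AB - S) / (V_corr + S) with S the molar-fraction-weighted
#' sum of the sorbate-species KB integrals and V_corr the correlation-sphere
#' volume.
#'
#' @param x_B Heavy-atom molar fraction of species B.
#' @param G_AB Kirkwood-Buff integral of B around the sorbate, nm^3.
#' @param sum_xG S = sum over alpha of x_alpha G_A,alpha, nm^3.
#' @param v_corr_radius Correlation-sphere radius, nm.
#' @return The dimensionless coefficient delta_B.
#' @export
prefsolv_delta <- function(x_B, G_AB, sum_xG, v_corr_radius = 1.5) {
  v_corr <- 4 / 3 * pi * v_corr_radius^3
  x_B * (G_AB - sum_xG) / (v_corr + sum_xG)
}

#' Preferential solvation around a sorbate
#'
#' Quantifies whether each surrounding species B is enriched or depleted
#' around the sorbate A relative to the bulk composition:
#' delta_B = x_B (G_AB - S) / (V_corr + S), where S = sum over species alpha
#' of x_alpha G_A,alpha, the G are Kirkwood-Buff integrals of the sorbate-
#' species RDFs up to the correlation radius, x are heavy-atom molar
#' fractions, and V_corr is the volume of the correlation sphere. Positive
#' delta_B means the sorbate is preferentially surrounded by B.
#'
#' All RDFs use heavy atoms only, consistent with the heavy-atom molar
#' fractions; the molar fractions are normalised over the full system.
#'
#' @param traj Frame or list of frames.
#' @param sorbate Species label of the solute (default `"sorbate"`).
#' @param species Character vector of surrounding species to evaluate.
#' @param v_corr_radius Correlation-sphere radius, nm (default 1.5).
#' @param bin_width RDF bin width, nm.
#' @return Named numeric vector of delta values, one per species, with the
#'   underlying KB integrals and molar fractions as attributes.
#' @export
preferential_solvation <- function(traj, sorbate = "sorbate",
                                   species = c("LHA", "water", "calcium"),
                                   v_corr_radius = 1.5, bin_width = 0.02) {
  frames <- as_trajectory(traj)
  f1 <- frames[[1]]
  sel_A <- select_atoms(f1, species = sorbate, heavy = TRUE)
  if (length(sel_A) == 0L)
    stop("preferential_solvation: sorbate species not present", call. = FALSE)
  missing_sp <- species[!species %in% f1$species]
  if (length(missing_sp))
    stop("preferential_solvation: species not present: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  x <- heavy_molar_fractions(f1)
  G <- vapply(species, function(sp) {
    sel_B <- select_atoms(f1, species = sp, heavy = TRUE)
    rdf <- radial_distribution(frames, sel_A, sel_B, bin_width = bin_width,
                               r_max = v_corr_radius)
    kb_integral(rdf, v_corr_radius)$G
  }, numeric(1))
  v_corr <- 4 / 3 * pi * v_corr_radius^3
  S <- sum(x[species] * G)
  delta <- prefsolv_delta(x[species], G, S, v_corr_radius)
  names(delta) <- species
  attr(delta, "G") <- G
  attr(delta, "molar_fractions") <- x
  attr(delta, "v_corr") <- v_corr
  delta
}
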