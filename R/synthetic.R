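#' Crooks-consistent Gaussian work sets
#'
#' Generates forward and reverse non-equilibrium work samples from the
#' Gaussian pair that exactly satisfies the Crooks fluctuation relation for
#' a planted free-energy difference: forward works ~ N(dG + sigma^2/(2RT),
#' sigma) and reverse works ~ N(-dG + sigma^2/(2RT), sigma), so the negated
#' reverse distribution is N(dG - sigma^2/(2RT), sigma) and the two Gaussians
#' cross at dG. The dissipated-work gap between the forward and negated-
#' reverse means is sigma^2/RT.
#'
#' @param dG_true Planted free-energy difference, kJ/mol.
#' @param sigma Work standard deviation, kJ/mol (> 0).
#' @param temperature Temperature, K.
#' @param n_per_direction Samples per direction (>= 2).
#' @param seed Integer seed (mandatory; generators are bit-reproducible).
#' @param n_models Number of replicate model labels to cycle over (default 3).
#' @return A [work_set()] with attribute `truth` = `dG_true`.
#' @export
crooks_gaussian_workset <- function(dG_true, sigma, temperature = 300,
                                    n_per_direction = 75, seed, n_models = 3) {
  if (missing(seed)) stop("crooks_gaussian_workset: seed is mandatory", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0)
    stop("crooks_gaussian_workset: sigma must be positive", call. = FALSE)
  if (n_per_direction < 2)
    stop("crooks_gaussian_workset: need at least 2 samples per direction",
         call. = FALSE)
  set.seed(seed)
  rt <- rt_kj(temperature)
  diss <- sigma^2 / (2 * rt)
  wf <- stats::rnorm(n_per_direction, dG_true + diss, sigma)
  wr <- stats::rnorm(n_per_direction, -dG_true + diss, sigma)
  models <- sprintf("m%d", rep_len(seq_len(n_models), n_per_direction))
  ws <- work_set(
    work = c(wf, wr),
    direction = rep(c("forward", "reverse"), each = n_per_direction),
    model_id = c(models, models),
    run_id = c(seq_len(n_per_direction), seq_len(n_per_direction)),
    temperature = temperature
  )
  attr(ws, "truth") <- dG_true
  ws
}

#' Polynomial lambda curves with known integral
#'
#' Each run's dH/dlambda values are a polynomial in lambda plus iid Gaussian
#' noise; the analytic integral of the polynomial over [0, 1] is stored as
#' the ground truth.
#'
#' @param coefficients Polynomial coefficients `c(c0, c1, ...)` for
#'   c0 + c1 l + c2 l^2 + ...
#' @param noise_sd Noise standard deviation, kJ/mol.
#' @param n_runs Number of independent runs.
#' @param n_lambda Grid size (>= 2; default 21 equally spaced points).
#' @param seed Integer seed.
#' @return A [lambda_curve()] with attribute `truth` = analytic integral.
#' @export
polynomial_lambda_curve <- function(coefficients, noise_sd = 0, n_runs = 5,
                                    n_lambda = 21, seed) {
  if (missing(seed)) stop("polynomial_lambda_curve: seed is mandatory", call. = FALSE)
  if (n_lambda < 2) stop("polynomial_lambda_curve: n_lambda >= 2", call. = FALSE)
  set.seed(seed)
  l <- seq(0, 1, length.out = n_lambda)
  f <- vapply(l, function(x) sum(coefficients * x^(seq_along(coefficients) - 1)),
              numeric(1))
  vals <- matrix(rep(f, each = n_runs), nrow = n_runs) +
    matrix(stats::rnorm(n_runs * n_lambda, 0, noise_sd), nrow = n_runs)
  curve <- lambda_curve(l, vals)
  attr(curve, "truth") <- sum(coefficients / seq_along(coefficients))
  curve
}

# default element class for a species label
species_element_class <- function(species) {
  ifelse(species %in% c("water", "calcium"), "heteroatom", "carbon")
}

#' Ideal-gas particle box
#'
#' Uniformly random positions with species labels drawn from stated
#' fractions: the null model for RDF, Kirkwood-Buff and preferential-
#' solvation analyses (g = 1, G = 0, delta = 0 in expectation). Water and
#' calcium particles are heteroatom class; other species default to carbon
#' unless listed in `heteroatom_fraction`, which assigns that fraction of a
#' species' particles to the heteroatom class.
#'
#' @param n Total particle count (>= 2).
#' @param box_edges Box edge length(s), nm.
#' @param species_mix Named fractions summing to 1.
#' @param seed Integer seed.
#' @param n_frames Number of independent frames to generate (default 1).
#' @param heteroatom_fraction Optional named fractions per species.
#' @return An `md_frame` (or list of frames when `n_frames > 1`) with
#'   attribute `truth = "ideal"`.
#' @export
ideal_gas_box <- function(n, box_edges = 5,
                          species_mix = c(LHA = 0.6, water = 0.35, calcium = 0.05),
                          seed, n_frames = 1, heteroatom_fraction = NULL) {
  if (missing(seed)) stop("ideal_gas_box: seed is mandatory", call. = FALSE)
  if (n < 2) stop("ideal_gas_box: n >= 2", call. = FALSE)
  set.seed(seed)
  box <- if (length(box_edges) == 1) rep(box_edges, 3) else box_edges
  # deterministic composition: largest-remainder apportionment of n
  counts <- floor(species_mix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(species_mix * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  species <- rep(names(counts), counts)
  frames <- lapply(seq_len(n_frames), function(k) {
    coords <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                    stats::runif(n, 0, box[3]))
    cls <- species_element_class(species)
    if (!is.null(heteroatom_fraction)) {
      for (sp in names(heteroatom_fraction)) {
        idx <- which(species == sp)
        nh <- round(heteroatom_fraction[[sp]] * length(idx))
        if (nh > 0) cls[idx[seq_len(nh)]] <- "heteroatom"
      }
    }
    fr <- md_frame(coords, box, species, element_class = cls)
    attr(fr, "truth") <- "ideal"
    fr
  })
  if (n_frames == 1) frames[[1]] else frames
}

#' Two-region clustered mixture box
#'
#' Emulates micro-segregated water-rich and matrix-rich sub-volumes: the box
#' is split along x into a water region and an LHA region, each species is
#' placed in its preferred region with probability growing with the
#' association strength (strength 0 degenerates to the ideal-gas box), and a
#' compact sorbate cluster is planted at the centre of the requested region.
#' The expected signs of the preferential-solvation coefficients are stored
#' as ground truth.
#'
#' @param n_per_species Named counts, e.g. `c(LHA = 400, water = 300,
#'   calcium = 20)`.
#' @param association_strength Non-negative; preference probability is
#'   0.5 + 0.5 s/(1+s).
#' @param sorbate_placement `"water_patch"` or `"LHA_patch"`.
#' @param box Edge length(s), nm.
#' @param seed Integer seed.
#' @param n_sorbate_atoms Heavy atoms in the planted sorbate cluster.
#' @param n_frames Independent frames (default 1).
#' @return Frame or list of frames with attribute `truth`, a named list of
#'   expected delta signs.
#' @export
clustered_mixture_box <- function(n_per_species = c(LHA = 400, water = 300,
                                                    calcium = 20),
                                  association_strength = 4,
                                  sorbate_placement = c("water_patch", "LHA_patch"),
                                  box = 6, seed, n_sorbate_atoms = 6,
                                  n_frames = 1) {
  if (missing(seed)) stop("clustered_mixture_box: seed is mandatory", call. = FALSE)
  sorbate_placement <- match.arg(sorbate_placement)
  if (association_strength < 0)
    stop("clustered_mixture_box: association strength must be >= 0", call. = FALSE)
  set.seed(seed)
  box <- if (length(box) == 1) rep(box, 3) else as.numeric(box)
  p <- 0.5 + 0.5 * association_strength / (1 + association_strength)
  # box is split along x: water region [0, Lx/2), LHA region [Lx/2, Lx)
  place <- function(n, prefer_water) {
    in_pref <- stats::runif(n) < p
    want_water <- xor(!prefer_water, in_pref)
    x <- ifelse(want_water, stats::runif(n, 0, box[1] / 2),
                stats::runif(n, box[1] / 2, box[1]))
    cbind(x, stats::runif(n, 0, box[2]), stats::runif(n, 0, box[3]))
  }
  truth <- if (sorbate_placement == "water_patch")
    list(water = +1, LHA = -1) else list(water = -1, LHA = +1)
  frames <- lapply(seq_len(n_frames), function(k) {
    coords <- NULL; species <- NULL
    for (sp in names(n_per_species)) {
      nsp <- n_per_species[[sp]]
      prefer_water <- sp %in% c("water", "calcium")
      coords <- rbind(coords, place(nsp, prefer_water))
      species <- c(species, rep(sp, nsp))
    }
    centre_x <- if (sorbate_placement == "water_patch") box[1] / 4 else 3 * box[1] / 4
    centre <- c(centre_x, box[2] / 2, box[3] / 2)
    sorb <- sweep(matrix(stats::rnorm(3 * n_sorbate_atoms, 0, 0.08), ncol = 3),
                  2, centre, "+")
    coords <- rbind(coords, sorb)
    species <- c(species, rep("sorbate", n_sorbate_atoms))
    cls <- species_element_class(species)
    cls[species == "sorbate"] <- rep_len(c("carbon", "heteroatom"), n_sorbate_atoms)
    fr <- md_frame(coords, box, species, element_class = cls)
    attr(fr, "truth") <- truth
    fr
  })
  if (n_frames == 1) frames[[1]] else frames
}

#' Frame with planted hydrogen bonds and decoys
#'
#' Places `k_bonds` ideal donor-hydrogen-acceptor triples (H...A distance in
#' 0.18-0.24 nm, angle in 150-180 degrees), `m_distance_decoys` triples that
#' violate only the distance criterion (H...A in 0.30-0.40 nm, ideal angle)
#' and `m_angle_decoys` triples that violate only the angle criterion
#' (ideal distance, angle in 90-120 degrees). Triples sit on a sparse grid
#' so they cannot interfere; the true count is exactly `k_bonds`.
#'
#' @param k_bonds,m_distance_decoys,m_angle_decoys Non-negative counts.
#' @param seed Integer seed.
#' @return An `md_frame` with attributes `donors`, `hydrogens`, `acceptors`
#'   (index vectors) and `truth` = `k_bonds`.
#' @export
planted_hbond_frame <- function(k_bonds, m_distance_decoys = 0,
                                m_angle_decoys = 0, seed) {
  if (missing(seed)) stop("planted_hbond_frame: seed is mandatory", call. = FALSE)
  if (any(c(k_bonds, m_distance_decoys, m_angle_decoys) < 0))
    stop("planted_hbond_frame: counts must be >= 0", call. = FALSE)
  set.seed(seed)
  n_triples <- k_bonds + m_distance_decoys + m_angle_decoys
  spacing <- 2
  side <- max(1L, ceiling(n_triples^(1 / 3)))
  box <- rep(max(4, spacing * (side + 1)), 3)
  coords <- matrix(0, 0, 3)
  kinds <- c(rep("bond", k_bonds), rep("dist_decoy", m_distance_decoys),
             rep("angle_decoy", m_angle_decoys))
  make_triple <- function(origin, kind) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    D <- origin
    H <- D + 0.1 * u
    d_ha <- if (kind == "dist_decoy") stats::runif(1, 0.30, 0.40)
            else stats::runif(1, 0.18, 0.24)
    ang <- if (kind == "angle_decoy") stats::runif(1, 90, 120)
           else stats::runif(1, 150, 180)
    # acceptor in the plane spanned by u and a perpendicular direction,
    # at angle `ang` (D-H...A, measured at H) from the H->D direction
    w <- stats::rnorm(3); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
    theta <- ang * pi / 180
    dir <- cos(theta) * (-u) + sin(theta) * w   # H->D direction is -u
    A <- H + d_ha * dir
    rbind(D, H, A)
  }
  idx <- 0
  for (t in seq_len(n_triples)) {
    gx <- (t - 1) %% side
    gy <- ((t - 1) %/% side) %% side
    gz <- (t - 1) %/% (side * side)
    origin <- c(gx, gy, gz) * spacing + spacing / 2
    coords <- rbind(coords, make_triple(origin, kinds[t]))
  }
  if (n_triples == 0) {
    fr <- md_frame(matrix(c(1, 1, 1), 1, 3), box, "sorbate",
                   element_class = "heteroatom")
    attr(fr, "donors") <- integer(); attr(fr, "hydrogens") <- integer()
    attr(fr, "acceptors") <- integer(); attr(fr, "truth") <- 0L
    return(fr)
  }
  cls <- rep(c("heteroatom", "hydrogen", "heteroatom"), n_triples)
  fr <- md_frame(coords, box, "sorbate", element_class = cls)
  base <- 3 * (seq_len(n_triples) - 1)
  attr(fr, "donors") <- base + 1L
  attr(fr, "hydrogens") <- base + 2L
  attr(fr, "acceptors") <- base + 3L
  attr(fr, "truth") <- as.integer(k_bonds)
  fr
}
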