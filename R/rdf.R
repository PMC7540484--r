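#' Radial distribution function under periodic boundaries
#'
#' Histograms minimum-image distances between two selections over the frames
#' of a trajectory and normalises each shell by the ideal-gas expectation
#' (pair density times exact shell volume), yielding g(r). Self pairs are
#' excluded when the selections overlap.
#'
#' @param traj An [md_frame()] or list of frames.
#' @param selection_A,selection_B Integer particle indices (see
#'   [select_atoms()]).
#' @param bin_width Bin width in nm.
#' @param r_max Largest distance considered; must not exceed half the
#'   smallest box edge.
#' @return Object of class `rdf_profile` with `bin_centers`, `g`,
#'   `bin_width`, `n_frames` and the mean particle numbers of the selections.
#' @export
radial_distribution <- function(traj, selection_A, selection_B,
                                bin_width = 0.02, r_max = NULL) {
  frames <- as_trajectory(traj)
  box0 <- frames[[1]]$box
  half <- min(box0) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9)
    stop(sprintf("radial_distribution: r_max = %.3f nm exceeds half the smallest box edge (%.3f nm)",
                 r_max, half), call. = FALSE)
  if (length(selection_A) == 0L || length(selection_B) == 0L)
    stop("radial_distribution: empty selection", call. = FALSE)
  nbin <- ceiling(r_max / bin_width)
  edges <- seq(0, nbin * bin_width, by = bin_width)
  counts <- numeric(nbin)
  npairs_tot <- 0
  vol_tot <- 0
  for (fr in frames) {
    A <- fr$coordinates[selection_A, , drop = FALSE]
    B <- fr$coordinates[selection_B, , drop = FALSE]
    n_shared <- length(intersect(selection_A, selection_B))
    # chunk rows of A to bound memory on large selections
    chunk <- max(1L, floor(2e6 / max(1L, nrow(B))))
    for (s in seq(1L, nrow(A), by = chunk)) {
      ii <- s:min(s + chunk - 1L, nrow(A))
      d <- cross_distances(A[ii, , drop = FALSE], B, fr$box)
      # drop self distances (exact zeros from shared particles)
      d <- d[d > 1e-12 & d < edges[nbin + 1L]]
      if (length(d))
        counts <- counts + tabulate(pmin(nbin, floor(d / bin_width) + 1L), nbin)
    }
    npairs_tot <- npairs_tot + (length(selection_A) * length(selection_B) - n_shared)
    vol_tot <- vol_tot + prod(fr$box)
  }
  nfr <- length(frames)
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbin + 1L)]^3)
  # ideal expectation: pair density (averaged over frames) times shell volume
  pair_density <- (npairs_tot / nfr) / (vol_tot / nfr)
  expected <- pair_density * shell_vol * nfr
  g <- counts / expected
  structure(list(
    bin_centers = (edges[-1] + edges[-(nbin + 1L)]) / 2,
    g = g, bin_width = bin_width, n_frames = nfr,
    n_A = length(selection_A), n_B = length(selection_B)
  ), class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf("RDF: %d bins of %.3f nm up to %.3f nm, %d frame(s)\n",
              length(x$g), x$bin_width, max(x$bin_centers) + x$bin_width / 2,
              x$n_frames))
  invisible(x)
}

#' Kirkwood-Buff integral of an RDF
#'
#' G = integral over 0..R of 4 pi r^2 (g(r) - 1) dr by trapezoid on the
#' binned profile. The integrand is anchored at r = 0 with g(0) = 0 (the
#' innermost shell is empty, contributing g - 1 = -1), and g is linearly
#' interpolated at the upper boundary when it falls between bin centers.
#' The starred (non-normalised) variant multiplies by the molar fractions
#' x_A x_B and measures contact numbers rather than excess volumes.
#'
#' @param rdf An `rdf_profile`.
#' @param upper_boundary Integration limit R in nm (conventionally 0.3, 0.4,
#'   0.5 for the local environment or 1.5 nm for the full correlation range).
#' @param molar_fractions Optional `c(x_A, x_B)`; required when
#'   `starred = TRUE`.
#' @param starred Multiply by x_A x_B.
#' @return Object of class `kb_result` with `G` (nm^3), `upper_boundary`,
#'   `starred`.
#' @export
kb_integral <- function(rdf, upper_boundary, molar_fractions = NULL,
                        starred = FALSE) {
  stopifnot(inherits(rdf, "rdf_profile"))
  r <- rdf$bin_centers
  if (upper_boundary <= 0)
    stop("kb_integral: upper boundary must be positive", call. = FALSE)
  if (upper_boundary > max(r) + rdf$bin_width / 2 + 1e-9)
    stop(sprintf("kb_integral: boundary %.3f nm beyond the profile (max %.3f nm)",
                 upper_boundary, max(r)), call. = FALSE)
  keep <- r < upper_boundary
  rr <- c(0, r[keep])
  gg <- c(0, rdf$g[keep])
  if (upper_boundary > max(rr)) {
    g_end <- stats::approx(c(rr, max(r) + rdf$bin_width), c(gg, gg[length(gg)]),
                           xout = upper_boundary, rule = 2)$y
    rr <- c(rr, upper_boundary)
    gg <- c(gg, g_end)
  }
  G <- trapezoid(rr, 4 * pi * rr^2 * (gg - 1))
  if (starred) {
    if (is.null(molar_fractions) || length(molar_fractions) != 2L)
      stop("kb_integral: starred variant needs molar_fractions = c(x_A, x_B)",
           call. = FALSE)
    G <- G * molar_fractions[1] * molar_fractions[2]
  }
  structure(list(G = G, upper_boundary = upper_boundary, starred = starred),
            class = "kb_result")
}

#' @export
print.kb_result <- function(x, ...) {
  cat(sprintf("Kirkwood-Buff integral%s: G = %.4f nm^3 (R = %.2f nm)\n",
              if (x$starred) " (starred)" else "", x$G, x$upper_boundary))
  invisible(x)
}
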