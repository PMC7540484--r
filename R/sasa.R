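#' Solvent-accessible surface area by sphere sampling
#'
#' Shrake-Rupley style numeric SASA: each atom's accessible sphere (radius +
#' probe) is covered with an approximately uniform point set (golden-spiral
#' lattice) and the fraction of points not buried inside any neighbour's
#' accessible sphere gives its exposed area. Hydrogen-class particles are
#' merged with their heavy atoms in the united-atom convention and are
#' excluded from the sphere set. Per-atom areas are attributed to the carbon
#' or heteroatom class and reported as fractions of the total.
#'
#' @param frame An [md_frame()]; atom radii must be positive for the
#'   selection.
#' @param selection Integer indices of the atoms whose surface is evaluated
#'   (default: all particles).
#' @param probe_radius Solvent probe radius, nm (default 0.14, a water-sized
#'   probe).
#' @param n_sphere_points Sample points per atom (default 960).
#' @param periodic Apply minimum-image convention to neighbour displacements.
#' @return Object of class `sasa_result`: `total` (nm^2), `carbon_fraction`,
#'   `heteroatom_fraction`, and per-atom areas.
#' @export
sasa <- function(frame, selection = NULL, probe_radius = 0.14,
                 n_sphere_points = 960, periodic = TRUE) {
  stopifnot(inherits(frame, "md_frame"))
  if (is.null(selection)) selection <- seq_len(n_atoms(frame))
  selection <- selection[frame$element_class[selection] != "hydrogen"]
  if (length(selection) == 0L)
    stop("sasa: selection contains no heavy atoms", call. = FALSE)
  radii <- frame$radius[selection]
  if (any(radii <= 0))
    stop("sasa: zero or negative radius in selection", call. = FALSE)
  pts <- golden_sphere_points(n_sphere_points)
  X <- frame$coordinates[selection, , drop = FALSE]
  R <- radii + probe_radius
  n <- length(selection)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d <- sweep(X, 2, X[i, ])
    if (periodic) d <- min_image(d, frame$box)
    dist <- sqrt(rowSums(d^2))
    nb <- which(dist < R[i] + R & seq_len(n) != i)
    surf <- pts * R[i]                       # points on atom i's sphere
    exposed <- rep(TRUE, nrow(surf))
    for (j in nb) {
      dd <- sweep(surf, 2, d[j, ])
      exposed <- exposed & rowSums(dd^2) > R[j]^2
      if (!any(exposed)) break
    }
    area[i] <- 4 * pi * R[i]^2 * mean(exposed)
  }
  total <- sum(area)
  cls <- frame$element_class[selection]
  cf <- if (total > 0) sum(area[cls == "carbon"]) / total else NA_real_
  hf <- if (total > 0) sum(area[cls == "heteroatom"]) / total else NA_real_
  structure(list(total = total, carbon_fraction = cf, heteroatom_fraction = hf,
                 atom_area = area, selection = selection),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.4f nm^2 (carbon %.1f%%, heteroatom %.1f%%)\n",
              x$total, 100 * x$carbon_fraction, 100 * x$heteroatom_fraction))
  invisible(x)
}

# near-uniform unit-sphere point set (golden-spiral lattice); deterministic
golden_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
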