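#' Geometric hydrogen-bond criterion
#'
#' A hydrogen bond D-H...A is counted when the hydrogen-acceptor distance is
#' at most `max_HA_distance` (minimum image) and the angle at the hydrogen
#' between the donor and the acceptor is at least `min_donor_angle`. Both
#' boundaries are inclusive.
#'
#' @param max_HA_distance Maximum H...A distance, nm (default 0.25).
#' @param min_donor_angle Minimum D-H...A angle, degrees (default 135).
#' @return Object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_HA_distance = 0.25, min_donor_angle = 135) {
  if (max_HA_distance <= 0)
    stop("hbond_criterion: distance must be positive", call. = FALSE)
  if (min_donor_angle <= 0 || min_donor_angle > 180)
    stop("hbond_criterion: angle must lie in (0, 180]", call. = FALSE)
  structure(list(max_HA_distance = max_HA_distance,
                 min_donor_angle = min_donor_angle),
            class = "hbond_criterion")
}

#' Count geometric hydrogen bonds in a frame
#'
#' @param frame An [md_frame()].
#' @param donors Integer indices of donor heavy atoms D; parallel to
#'   `hydrogens`.
#' @param hydrogens Integer indices of the hydrogens attached to the donors.
#' @param acceptors Integer indices of acceptor atoms.
#' @param criterion An [hbond_criterion()].
#' @return Integer count of (D, H, A) triples satisfying the criterion;
#'   acceptor identical to the donor is skipped.
#' @export
hydrogen_bonds <- function(frame, donors, hydrogens, acceptors,
                           criterion = hbond_criterion()) {
  stopifnot(inherits(frame, "md_frame"), inherits(criterion, "hbond_criterion"))
  if (length(donors) != length(hydrogens))
    stop("hydrogen_bonds: donors and hydrogens must be parallel vectors",
         call. = FALSE)
  if (length(donors) == 0L || length(acceptors) == 0L) return(0L)
  X <- frame$coordinates
  box <- frame$box
  count <- 0L
  cos_min <- cos(criterion$min_donor_angle * pi / 180)
  for (i in seq_along(donors)) {
    D <- X[donors[i], ]; H <- X[hydrogens[i], ]
    acc <- setdiff(acceptors, donors[i])
    if (length(acc) == 0L) next
    # minimum-image vectors H -> A and H -> D
    va <- min_image(sweep(X[acc, , drop = FALSE], 2, H), box)
    da <- sqrt(rowSums(va^2))
    near <- which(da <= criterion$max_HA_distance + 1e-12)
    if (length(near) == 0L) next
    vd <- min_image(matrix(D - H, 1), box)[1, ]
    nd <- sqrt(sum(vd^2))
    for (j in near) {
      # angle D-H...A at the hydrogen; 180 deg = linear
      ct <- sum(vd * va[j, ]) / (nd * da[j])
      ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
      if (ang >= criterion$min_donor_angle - 1e-9) count <- count + 1L
    }
  }
  count
}
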