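#' Periodic particle configurations
#'
#' An `md_frame` is one configuration of a rectangular periodic box:
#' coordinates in nm plus per-particle annotations used by the structural
#' descriptors (species label, element class, partial charge, Lennard-Jones
#' C6/C12 parameters and a radius for surface-area calculations). A
#' trajectory is simply a list of frames sharing the same annotation layout.
#'
#' @param coordinates n x 3 numeric matrix, nm.
#' @param box Length-3 positive edge lengths, nm (rectangular, periodic).
#' @param species Character label per particle (e.g. `"sorbate"`, `"LHA"`,
#'   `"water"`, `"calcium"`).
#' @param element_class `"carbon"`, `"heteroatom"` or `"hydrogen"` per
#'   particle. In the united-atom convention aliphatic CHn sites are single
#'   carbon-class particles; explicit hydrogens only appear on polar groups.
#' @param charge Partial charges, e.
#' @param c6,c12 Lennard-Jones dispersion/repulsion parameters
#'   (kJ mol^-1 nm^6 and kJ mol^-1 nm^12).
#' @param radius Atomic radius for SASA, nm.
#' @param names Optional atom names (used by the GRO writer).
#' @return Object of class `md_frame`.
#' @export
md_frame <- function(coordinates, box, species,
                     element_class = "carbon", charge = 0,
                     c6 = 0, c12 = 0, radius = 0.15, names = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L || any(!is.finite(coordinates)))
    stop("md_frame: coordinates must be a finite n x 3 matrix", call. = FALSE)
  n <- nrow(coordinates)
  box <- as.numeric(box)
  if (length(box) == 1L) box <- rep(box, 3)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("md_frame: box must be three positive edge lengths", call. = FALSE)
  species <- rep_len(as.character(species), n)
  element_class <- rep_len(as.character(element_class), n)
  bad <- setdiff(unique(element_class), c("carbon", "heteroatom", "hydrogen"))
  if (length(bad))
    stop("md_frame: unknown element_class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(
    coordinates = coordinates, box = box, species = species,
    element_class = element_class,
    charge = rep_len(as.numeric(charge), n),
    c6 = rep_len(as.numeric(c6), n),
    c12 = rep_len(as.numeric(c12), n),
    radius = rep_len(as.numeric(radius), n),
    names = if (is.null(names)) sprintf("P%d", seq_len(n)) else rep_len(names, n)
  ), class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("Periodic frame: %d particles, box %.3f x %.3f x %.3f nm\n",
              nrow(x$coordinates), x$box[1], x$box[2], x$box[3]))
  sp <- table(x$species)
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

n_atoms <- function(frame) nrow(frame$coordinates)

# coerce frame-or-list-of-frames to a list of frames
as_trajectory <- function(traj) {
  if (inherits(traj, "md_frame")) return(list(traj))
  if (is.list(traj) && all(vapply(traj, inherits, TRUE, "md_frame"))) return(traj)
  stop("expected an md_frame or a list of md_frame objects", call. = FALSE)
}

#' Select particles of a frame
#'
#' @param frame An [md_frame()].
#' @param species Optional species label(s) to keep.
#' @param element_class Optional element class(es) to keep.
#' @param heavy If `TRUE`, drop hydrogen-class particles.
#' @return Integer indices.
#' @export
select_atoms <- function(frame, species = NULL, element_class = NULL,
                         heavy = FALSE) {
  keep <- rep(TRUE, n_atoms(frame))
  if (!is.null(species)) keep <- keep & frame$species %in% species
  if (!is.null(element_class)) keep <- keep & frame$element_class %in% element_class
  if (heavy) keep <- keep & frame$element_class != "hydrogen"
  which(keep)
}

# minimum-image displacement of points (matrix) relative to one reference row
min_image <- function(d, box) {
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

# minimum-image distances between coordinates rows idx_a (matrix A) and all
# rows of B; returns |A| x |B| matrix. Chunked by callers for large sets.
cross_distances <- function(A, B, box) {
  nA <- nrow(A); nB <- nrow(B)
  out <- matrix(0, nA, nB)
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  sqrt(out)
}
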