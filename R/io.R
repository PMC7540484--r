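#' Read a GRO coordinate file
#'
#' Fixed-column GRO: a title line, an atom count, one line per atom
#' (`%5d%-5s%5s%5d%8.3f%8.3f%8.3f` - residue number/name, atom name, atom
#' number, x y z in nm) and a trailing box line with the three rectangular
#' edge lengths. Residue names become species labels; structural annotations
#' (element class, charges, LJ parameters, radii) come from a sidecar TSV
#' via [annotate_frame()].
#'
#' @param path File path.
#' @return An [md_frame()] with species taken from residue names.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("read_gro: file too short to be a GRO file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n))
    stop("read_gro: line 2 is not an atom count", call. = FALSE)
  if (length(lines) < 2 + n + 1)
    stop("read_gro: truncated file; expected ", n, " atom lines plus a box ",
         "line, got ", length(lines) - 2, " (line ", length(lines) + 1, ")",
         call. = FALSE)
  atom_lines <- lines[3:(2 + n)]
  parse_num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v)))
      stop("read_gro: malformed ", what, " at line ",
           lineno[which(is.na(v))[1]], call. = FALSE)
    v
  }
  linenos <- 3:(2 + n)
  resname <- trimws(substr(atom_lines, 6, 10))
  atname <- trimws(substr(atom_lines, 11, 15))
  x <- parse_num(substr(atom_lines, 21, 28), "x coordinate", linenos)
  y <- parse_num(substr(atom_lines, 29, 36), "y coordinate", linenos)
  z <- parse_num(substr(atom_lines, 37, 44), "z coordinate", linenos)
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[2 + n + 1]),
                                              "\\s+")[[1]]))
  if (length(box) < 3 || any(is.na(box[1:3])))
    stop("read_gro: missing or malformed box line (line ", 2 + n + 1, ")",
         call. = FALSE)
  md_frame(cbind(x, y, z), box[1:3], species = resname, names = atname)
}

#' Write a frame as a GRO file
#'
#' Positions are written with 3-decimal precision in nm (the GRO fixed
#' format); re-reading a written file reproduces the written, quantised
#' coordinates exactly.
#'
#' @param frame An [md_frame()].
#' @param path Output path.
#' @param title Title line.
#' @export
write_gro <- function(frame, path, title = "frame written by sorbfe") {
  stopifnot(inherits(frame, "md_frame"))
  n <- n_atoms(frame)
  lines <- c(title, sprintf("%5d", n))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              i %% 100000L, substr(frame$species[i], 1, 5),
                              substr(frame$names[i], 1, 5), i %% 100000L,
                              frame$coordinates[i, 1], frame$coordinates[i, 2],
                              frame$coordinates[i, 3]))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                            frame$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Attach per-particle annotations from a sidecar TSV
#'
#' The sidecar is a headered TSV (comment lines start with `#`) with one row
#' per particle: columns `species`, `element_class`, `charge`, `c6`, `c12`,
#' `radius` (any subset; present columns override the frame's values).
#'
#' @param frame An [md_frame()].
#' @param path TSV path.
#' @return The annotated frame.
#' @export
annotate_frame <- function(frame, path) {
  ann <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(ann) != n_atoms(frame))
    stop("annotate_frame: sidecar has ", nrow(ann), " rows for ",
         n_atoms(frame), " particles", call. = FALSE)
  for (col in intersect(c("species", "element_class", "charge", "c6", "c12",
                          "radius"), names(ann)))
    frame[[col]] <- ann[[col]]
  md_frame(frame$coordinates, frame$box, frame$species, frame$element_class,
           frame$charge, frame$c6, frame$c12, frame$radius, frame$names)
}

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

#' Read a non-equilibrium work table
#'
#' Headered TSV with columns `compound`, `direction` (forward|reverse),
#' `model_id`, `run_id`, `work_kJ_per_mol`; `#` comment lines allowed.
#'
#' @param path TSV path.
#' @param temperature Temperature in K assigned to the set.
#' @param compound Optional compound to filter; required when the table
#'   holds several.
#' @return A [work_set()].
#' @export
read_work_table <- function(path, temperature = 300, compound = NULL) {
  df <- read_tsv_checked(path, c("compound", "direction", "model_id",
                                 "run_id", "work_kJ_per_mol"))
  if (!is.null(compound)) df <- df[df$compound == compound, , drop = FALSE]
  if (nrow(df) == 0L) stop("read_work_table: no rows", call. = FALSE)
  if (length(unique(df$compound)) > 1L)
    stop("read_work_table: several compounds present; pass `compound`",
         call. = FALSE)
  w <- suppressWarnings(as.numeric(df$work_kJ_per_mol))
  if (any(is.na(w)))
    stop("read_work_table: non-numeric work value at row ",
         which(is.na(w))[1], call. = FALSE)
  work_set(w, df$direction, df$model_id, df$run_id, temperature)
}

#' Write a work set as TSV
#'
#' @param ws A [work_set()].
#' @param path Output path.
#' @param compound Compound label for the `compound` column.
#' @export
write_work_table <- function(ws, path, compound = "compound") {
  df <- data.frame(compound = compound, direction = ws$direction,
                   model_id = ws$model_id, run_id = ws$run_id,
                   work_kJ_per_mol = ws$work)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lambda-curve table
#'
#' Headered TSV with columns `run_id`, `lambda`, `dHdl_kJ_per_mol`.
#' Duplicate (run, lambda) pairs are an error; every run must cover the same
#' grid.
#'
#' @param path TSV path.
#' @return A [lambda_curve()].
#' @export
read_lambda_table <- function(path) {
  df <- read_tsv_checked(path, c("run_id", "lambda", "dHdl_kJ_per_mol"))
  v <- suppressWarnings(as.numeric(df$dHdl_kJ_per_mol))
  if (any(is.na(v)))
    stop("read_lambda_table: non-numeric dH/dlambda at row ",
         which(is.na(v))[1], call. = FALSE)
  if (anyDuplicated(df[c("run_id", "lambda")]))
    stop("read_lambda_table: duplicate (run_id, lambda) entries", call. = FALSE)
  lambdas <- sort(unique(df$lambda))
  runs <- unique(df$run_id)
  vals <- matrix(NA_real_, length(runs), length(lambdas))
  for (i in seq_along(runs)) {
    sub <- df[df$run_id == runs[i], ]
    m <- match(lambdas, sub$lambda)
    if (any(is.na(m)))
      stop("read_lambda_table: run ", runs[i], " does not cover the full ",
           "lambda grid", call. = FALSE)
    vals[i, ] <- v[df$run_id == runs[i]][m]
  }
  lambda_curve(lambdas, vals)
}

#' Write a lambda curve as TSV
#'
#' @param curve A [lambda_curve()].
#' @param path Output path.
#' @export
write_lambda_table <- function(curve, path) {
  df <- data.frame(
    run_id = rep(seq_len(curve$n_runs), each = length(curve$lambdas)),
    lambda = rep(curve$lambdas, curve$n_runs),
    dHdl_kJ_per_mol = as.vector(t(curve$values))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a property table
#'
#' Plain headered TSV of compounds x properties, `#` comments allowed.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_property_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname read_property_table
#' @param pt Data frame to write.
#' @export
write_property_table <- function(pt, path) {
  utils::write.table(pt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
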