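#' Pearson correlation
#'
#' Thin wrapper around [stats::cor()] with the validation the property
#' ledger requires: at least three finite pairs and nonzero variance in both
#' series.
#'
#' @param x,y Numeric series of equal length.
#' @return Product-moment correlation coefficient.
#' @export
pearson <- function(x, y) {
  check_pairs(x, y)
  stats::cor(x, y)
}

check_pairs <- function(x, y) {
  if (length(x) != length(y))
    stop("series differ in length", call. = FALSE)
  if (length(x) < 3L || any(!is.finite(x)) || any(!is.finite(y)))
    stop("need at least 3 finite paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined statistic: a series has zero variance", call. = FALSE)
  invisible(TRUE)
}

#' Ordinary least-squares line
#'
#' @param x,y Numeric series.
#' @return Named vector `c(slope = , intercept = )` from [stats::lm()].
#' @export
linear_fit <- function(x, y) {
  check_pairs(x, y)
  cf <- stats::coef(stats::lm(y ~ x))
  c(slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Best-fitting line with slope fixed at 1
#'
#' The least-squares intercept at unit slope is mean(y - x). Comparisons
#' built on it are invariant to any additive constant in either series,
#' which makes it the right summary for experimental free energies known
#' only up to an offset.
#'
#' @param x,y Numeric series.
#' @return The offset.
#' @export
unit_slope_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) == 0L)
    stop("unit_slope_fit: series must be non-empty and equal length",
         call. = FALSE)
  mean(y - x)
}

#' Correlation ledger of microscopic properties vs sorption free energy
#'
#' Correlates every property column of a table against the response column
#' of sorption free energies, reporting the Pearson coefficient, the OLS
#' line, the unit-slope offset and a reporting strength class
#' (|r| >= 0.7 strong, 0.4-0.7 moderate, else weak). Constant columns are
#' flagged, not fatal.
#'
#' @param pt Data frame of compounds x properties.
#' @param response Name of the response column (default `"dG_sorb"`).
#' @return Data frame of class `correlation_report`: one row per property
#'   with columns `property`, `r`, `slope`, `intercept`, `offset`,
#'   `strength`, `flag`.
#' @export
correlation_table <- function(pt, response = "dG_sorb") {
  stopifnot(is.data.frame(pt))
  if (!response %in% names(pt))
    stop("correlation_table: response column '", response, "' not found",
         call. = FALSE)
  y <- pt[[response]]
  if (any(!is.finite(y)))
    stop("correlation_table: missing response values", call. = FALSE)
  if (nrow(pt) < 3L)
    stop("correlation_table: need at least 3 rows", call. = FALSE)
  props <- setdiff(names(pt)[vapply(pt, is.numeric, TRUE)], response)
  rows <- lapply(props, function(p) {
    x <- pt[[p]]
    if (!all(is.finite(x)) || stats::sd(x) == 0) {
      return(data.frame(property = p, r = NA_real_, slope = NA_real_,
                        intercept = NA_real_, offset = NA_real_,
                        strength = NA_character_, flag = "constant_or_missing",
                        stringsAsFactors = FALSE))
    }
    r <- pearson(x, y)
    lf <- linear_fit(x, y)
    data.frame(property = p, r = r, slope = lf["slope"],
               intercept = lf["intercept"], offset = unit_slope_fit(x, y),
               strength = strength_class(r), flag = "",
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_report", "data.frame")
  out
}

strength_class <- function(r) {
  a <- abs(r)
  if (a >= 0.7) "strong" else if (a >= 0.4) "moderate" else "weak"
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat("Correlation ledger (", nrow(x), " properties)\n", sep = "")
  df <- as.data.frame(x)
  df$r <- round(df$r, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
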