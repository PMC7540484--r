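#' Free-energy estimate objects
#'
#' A `fe_estimate` holds a free-energy difference in kJ/mol together with its
#' uncertainty (bootstrap standard deviation, standard error over runs, or a
#' propagated error) and a tag recording the estimator that produced it.
#' Estimates combine linearly through the thermodynamic-cycle operations in
#' [sorption_free_energy()] and [relative_sorption()].
#'
#' @param value Free-energy difference, kJ/mol.
#' @param uncertainty Non-negative uncertainty, kJ/mol.
#' @param method One of `"CGI"`, `"Jarzynski_forward"`, `"Jarzynski_reverse"`,
#'   `"TI"`, `"derived"`.
#' @param n_boot Number of bootstrap resamples behind the uncertainty, or
#'   `NA` when the uncertainty is not bootstrap-based.
#' @param flags Character vector of diagnostic flags (e.g. `"poor_overlap"`,
#'   `"single_run"`).
#' @return An object of class `fe_estimate`.
#' @export
fe_estimate <- function(value, uncertainty = 0, method = "derived",
                        n_boot = NA_integer_, flags = character()) {
  method <- match.arg(method, c("CGI", "Jarzynski_forward", "Jarzynski_reverse",
                                "TI", "derived"))
  if (!is.finite(value)) stop("fe_estimate: value must be finite", call. = FALSE)
  if (!is.finite(uncertainty) || uncertainty < 0)
    stop("fe_estimate: uncertainty must be finite and >= 0", call. = FALSE)
  structure(
    list(value = value, uncertainty = uncertainty, method = method,
         n_boot = n_boot, flags = flags),
    class = "fe_estimate"
  )
}

#' @export
format.fe_estimate <- function(x, digits = 2, ...) {
  s <- sprintf("%.*f +/- %.*f kJ/mol [%s]", digits, x$value, digits,
               x$uncertainty, x$method)
  if (!is.na(x$n_boot)) s <- paste0(s, sprintf(" (n_boot = %d)", x$n_boot))
  if (length(x$flags)) s <- paste0(s, " flags: ", paste(x$flags, collapse = ", "))
  s
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat("Free-energy estimate:", format(x, ...), "\n")
  invisible(x)
}

#' @export
coef.fe_estimate <- function(object, ...) {
  c(value = object$value, uncertainty = object$uncertainty)
}

#' @export
summary.fe_estimate <- function(object, ...) {
  cat("Free-energy estimate (", object$method, ")\n", sep = "")
  cat("  value       : ", sprintf("%.4f kJ/mol", object$value), "\n", sep = "")
  cat("  uncertainty : ", sprintf("%.4f kJ/mol", object$uncertainty), "\n", sep = "")
  if (!is.na(object$n_boot))
    cat("  n_boot      : ", object$n_boot, "\n", sep = "")
  if (length(object$flags))
    cat("  flags       : ", paste(object$flags, collapse = ", "), "\n", sep = "")
  invisible(object)
}

# coerce numeric or fe_estimate to fe_estimate
as_fe <- function(x) {
  if (inherits(x, "fe_estimate")) return(x)
  if (is.numeric(x) && length(x) == 1) return(fe_estimate(x))
  stop("expected a fe_estimate or a single numeric value", call. = FALSE)
}
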