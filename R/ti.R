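#' Lambda curves for thermodynamic integration
#'
#' A `lambda_curve` stores per-run ensemble averages of dH/dlambda on a
#' common grid of coupling-parameter values in [0, 1]. The default protocol
#' uses 21 equally spaced points and 5 independent runs.
#'
#' @param lambdas Strictly increasing grid in [0, 1]; first value 0, last 1.
#' @param values Numeric matrix (n_runs x n_lambda) of dH/dlambda averages in
#'   kJ/mol, or a vector for a single run.
#' @return Object of class `lambda_curve`.
#' @export
lambda_curve <- function(lambdas, values) {
  lambdas <- as.numeric(lambdas)
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  values <- as.matrix(values)
  if (ncol(values) != length(lambdas))
    stop("lambda_curve: each run must cover every grid point", call. = FALSE)
  if (length(lambdas) < 2 || any(diff(lambdas) <= 0))
    stop("lambda_curve: lambdas must be strictly increasing", call. = FALSE)
  if (abs(lambdas[1]) > 1e-12 || abs(lambdas[length(lambdas)] - 1) > 1e-12)
    stop("lambda_curve: grid must start at 0 and end at 1", call. = FALSE)
  if (any(!is.finite(values)))
    stop("lambda_curve: non-finite dH/dlambda values", call. = FALSE)
  structure(list(lambdas = lambdas, values = values, n_runs = nrow(values)),
            class = "lambda_curve")
}

#' @export
print.lambda_curve <- function(x, ...) {
  cat(sprintf("Lambda curve: %d runs x %d lambda points on [0, 1]\n",
              x$n_runs, length(x$lambdas)))
  invisible(x)
}

#' Composite trapezoidal quadrature
#'
#' @param lambdas Abscissae (strictly increasing).
#' @param values Ordinates, same length.
#' @return The integral of `values` over `lambdas`.
#' @export
trapezoid <- function(lambdas, values) {
  if (length(lambdas) != length(values))
    stop("trapezoid: lambdas and values differ in length", call. = FALSE)
  pracma::trapz(as.numeric(lambdas), as.numeric(values))
}

#' Thermodynamic-integration free energy
#'
#' Integrates each run's dH/dlambda curve by the trapezoidal rule and reports
#' the mean over runs; the uncertainty is the standard error over the per-run
#' integrals (sd / sqrt(n_runs)). A single run yields uncertainty 0 with a
#' `single_run` flag and a warning.
#'
#' @param curve A [lambda_curve()].
#' @return A [fe_estimate()] with method `"TI"`.
#' @export
ti_free_energy <- function(curve) {
  stopifnot(inherits(curve, "lambda_curve"))
  ints <- apply(curve$values, 1, function(v) trapezoid(curve$lambdas, v))
  flags <- character()
  if (curve$n_runs == 1L) {
    warning("ti_free_energy: single run; uncertainty reported as 0")
    u <- 0
    flags <- "single_run"
  } else {
    u <- stats::sd(ints) / sqrt(curve$n_runs)
  }
  fe_estimate(mean(ints), u, method = "TI", flags = flags)
}
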