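# FNV-1a hash of a character string, returned as 8 hex digits; used to stamp
# pipeline outputs with a configuration fingerprint.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep the state as a double
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), b)
    # 32-bit modular multiply by the FNV prime 16777619, split to stay exact
    # in double arithmetic
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles the physical and numerical parameters of a full analysis run.
#' Inputs may be in-memory objects or file paths to the TSV formats of the
#' readers in this package.
#'
#' @param work_vac,work_env [work_set()] objects or work-table paths:
#'   decoupling in vacuum and in the environment (matrix or water).
#' @param lambda_table Optional [lambda_curve()] or lambda-table path for a
#'   thermodynamic-integration estimate.
#' @param property_table Optional data frame or TSV path for the correlation
#'   ledger.
#' @param response Response column of the property table.
#' @param temperature Temperature, K.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed (recorded in every output).
#' @param estimator Work estimator for the bootstrap stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(work_vac, work_env, lambda_table = NULL,
                            property_table = NULL, response = "dG_sorb",
                            temperature = 300, n_boot = 1000, seed = 1,
                            estimator = "cgi") {
  if (temperature <= 0 || n_boot < 1)
    stop("pipeline_config: physical parameters must be positive", call. = FALSE)
  structure(list(work_vac = work_vac, work_env = work_env,
                 lambda_table = lambda_table,
                 property_table = property_table, response = response,
                 temperature = temperature, n_boot = n_boot,
                 seed = as.integer(seed), estimator = estimator),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

load_ws <- function(x, temperature) {
  if (inherits(x, "work_set")) return(x)
  read_work_table(x, temperature = temperature)
}

#' Run the end-to-end analysis pipeline
#'
#' Bootstraps the decoupling free energies in vacuum and in the environment,
#' composes them into the sorption free energy through the thermodynamic
#' cycle, optionally adds a thermodynamic-integration estimate and a
#' correlation ledger, and returns (optionally writes as JSON) a report that
#' embeds the seed and a configuration hash so identical inputs yield
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out Optional JSON output path.
#' @return The report, a nested list.
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ws_vac <- stage("load_work_vac", load_ws(config$work_vac, config$temperature))
  ws_env <- stage("load_work_env", load_ws(config$work_env, config$temperature))
  est_vac <- stage("estimate_vacuum",
                   bootstrap_estimate(ws_vac, config$estimator,
                                      n_boot = config$n_boot,
                                      seed = config$seed))
  est_env <- stage("estimate_environment",
                   bootstrap_estimate(ws_env, config$estimator,
                                      n_boot = config$n_boot,
                                      seed = config$seed + 1L))
  sorb <- stage("thermo_cycle", sorption_free_energy(est_vac, est_env))
  report <- list(
    seed = config$seed,
    temperature = config$temperature,
    config_hash = fnv1a_hash(paste(deparse(unclass(config)), collapse = "")),
    package_version = as.character(utils::packageVersion("sorbfe")),
    free_energy = list(
      dG_vac = list(value = est_vac$value, uncertainty = est_vac$uncertainty,
                    method = est_vac$method),
      dG_env = list(value = est_env$value, uncertainty = est_env$uncertainty,
                    method = est_env$method),
      dG_sorb = list(value = sorb$value, uncertainty = sorb$uncertainty)
    )
  )
  if (!is.null(config$lambda_table)) {
    curve <- stage("load_lambda_table",
                   if (inherits(config$lambda_table, "lambda_curve"))
                     config$lambda_table else read_lambda_table(config$lambda_table))
    ti <- stage("thermodynamic_integration", ti_free_energy(curve))
    report$ti <- list(value = ti$value, uncertainty = ti$uncertainty)
  }
  if (!is.null(config$property_table)) {
    pt <- stage("load_property_table",
                if (is.data.frame(config$property_table)) config$property_table
                else read_property_table(config$property_table))
    ct <- stage("correlation_ledger",
                correlation_table(pt, response = config$response))
    report$correlations <- lapply(seq_len(nrow(ct)), function(i)
      list(property = ct$property[i], r = ct$r[i], slope = ct$slope[i],
           strength = ct$strength[i]))
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  report
}
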