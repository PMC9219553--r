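## Serialization: CSV exports (comma-separated, header row, '.' decimal,
## no locale formatting) and JSON for equilibria and run configuration.

write_plain_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory as CSV
#'
#' Columns: time, TRH, TSH, FT4, FT3.
#'
#' @param trajectory an [hpt_integrate()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
hpt_write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "hpt_trajectory"))
  write_plain_csv(trajectory$data[, c("time", HPT_HORMONES)], path)
}

#' Export a sweep branch as CSV
#'
#' Columns: param_value, TRH, TSH, FT4, FT3, max_re_eigenvalue, stable —
#' the data behind the homeostasis figures.
#'
#' @param sweep an [hpt_sweep()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
hpt_write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "hpt_sweep"))
  write_plain_csv(sweep$branch[, c("param_value", HPT_HORMONES,
                                   "max_re_eigenvalue", "stable")], path)
}

#' Export an equilibrium as JSON
#'
#' Keys: variant, params, state, residual, eigenvalues (as [re, im]
#' pairs), stable, method.
#'
#' @param equilibrium an [hpt_equilibrium()] result.
#' @param path output file path, or \code{NULL} to return the JSON text.
#' @return the path (or JSON string), invisibly.
#' @export
hpt_write_equilibrium <- function(equilibrium, path = NULL) {
  stopifnot(inherits(equilibrium, "hpt_equilibrium"))
  obj <- list(
    variant = equilibrium$variant_id,
    params = as.list(unclass(equilibrium$parameters)),
    state = as.list(unclass(equilibrium$state)),
    residual = equilibrium$residual,
    eigenvalues = lapply(equilibrium$eigenvalues,
                         function(z) c(Re(z), Im(z))),
    stable = equilibrium$stable,
    method = equilibrium$method)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Export a scenario result
#'
#' Writes a long-format CSV (scenario, k32, quantity in {FT3, FT4}, stat
#' in {min, median, max}, value, normalized_value) and, optionally, a
#' JSON metadata file echoing the specification and seed.
#'
#' @param result an [hpt_run_scenario()] result.
#' @param path CSV output path.
#' @param meta_path optional JSON metadata path.
#' @return the CSV path, invisibly.
#' @export
hpt_write_scenario <- function(result, path, meta_path = NULL) {
  stopifnot(inherits(result, "hpt_scenario"))
  long_one <- function(env, pct, quantity) {
    do.call(rbind, lapply(c("min", "median", "max"), function(st) {
      data.frame(scenario = result$spec$name, k32 = env$k32,
                 quantity = quantity, stat = st, value = env[[st]],
                 normalized_value = pct[[st]])
    }))
  }
  tab <- rbind(long_one(result$ft3_envelope, result$normalized_ft3, "FT3"),
               long_one(result$ft4_envelope, result$normalized_ft4, "FT4"))
  write_plain_csv(tab, path)
  if (!is.null(meta_path)) {
    meta <- unclass(result$spec)
    meta$n_used <- result$n_used
    meta$ft3_protected <- result$ft3_protected
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                null = "null"), meta_path)
  }
  invisible(path)
}

#' Read / write a run configuration
#'
#' A run configuration is a flat named list mirroring the command-line
#' flags (command, system, param, from, to, points, scenario, samples,
#' subjects, noise_sd, seed, out, set).  The JSON round-trip is lossless.
#'
#' @param path JSON file path.
#' @return the configuration list.
#' @export
hpt_read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$set)) cfg$set <- as.list(cfg$set)
  cfg
}

#' @rdname hpt_read_config
#' @param config a configuration list.
#' @export
hpt_write_config <- function(config, path) {
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}
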