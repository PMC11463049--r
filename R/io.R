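#' Read a JSON or YAML configuration file
#'
#' JSON is the canonical format; YAML is accepted by extension (`.yaml`,
#' `.yml`).
#'
#' @param path file path.
#' @return parsed list.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format '.", ext, "' (use .json, .yaml or .yml)")
  }
}

#' Read and validate a parameter configuration
#'
#' Flat keys must exactly match the parameter field names; unknown keys are
#' errors (typo protection).
#'
#' @param path JSON or YAML file.
#' @return validated parameter list.
#' @export
read_parameter_config <- function(path) {
  raw <- read_config_file(path)
  if (!is.list(raw)) stop("parameter config must be a flat mapping")
  assert_valid_parameters(lapply(raw, function(x) {
    if (is.numeric(x) && length(x) == 1L) as.numeric(x) else x
  }))
}

#' Write a model definition dump as JSON
#'
#' Introspectable structure listing, per variable: name, kind, units,
#' dependency list and (for stocks) inflows/outflows and the non-negativity
#' flag.
#'
#' @param model an [sd_model()].
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
model_structure_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "sd_model"))
  obj <- lapply(model$variables, function(v) {
    out <- list(name = v$name, kind = v$kind, units = v$units,
                depends_on = as.list(model$depends_on[[v$name]]))
    if (v$kind == "stock") {
      out$inflows <- as.list(v$inflows)
      out$outflows <- as.list(v$outflows)
      out$non_negative <- v$non_negative
    }
    out
  })
  js <- jsonlite::toJSON(unname(obj), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a run manifest
#'
#' Records tool version, configuration checksum, seed, command and simulation
#' window alongside a set of outputs, so a run can be reproduced bit-exactly.
#'
#' @param path manifest file path (JSON).
#' @param command the command that produced the outputs.
#' @param config a [sim_config()].
#' @param outputs character vector of output file paths.
#' @param config_path optional configuration file the run used (its MD5 is
#'   recorded).
#' @param seed seed used, if any.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, outputs,
                           config_path = NULL, seed = NULL) {
  manifest <- list(
    tool = "pharmsd",
    version = as.character(utils::packageVersion("pharmsd")),
    command = command,
    seed = seed,
    config_checksum = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA,
    start_time = config$start_time,
    stop_time = config$stop_time,
    dt = config$dt,
    outputs = as.list(outputs)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              na = "null"), path)
  invisible(path)
}
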