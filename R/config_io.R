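# Configuration files (JSON or YAML) and CSV reporting.

CONFIG_DEFAULTS <- list(
  preset = "conservative",
  n0 = 2e6,
  harvest_rate = 0,
  egg_harvest_rate = 0,
  dd = FALSE,
  dd_floor = 0.5,
  horizon = 350L,
  replicates = 100L,
  seed = 1L,
  extinction_rule = "one_sex_remains",
  extinction_threshold = 50,
  harvest_policy = "all_ages",
  egg_max = NULL,
  escape_multiple = 1000,
  label = NULL)

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(CONFIG_DEFAULTS, cfg)
  if (!cfg$preset %in% c("conservative", "realistic"))
    stop("config key 'preset' must be 'conservative' or 'realistic'")
  num_pos <- function(key, lo = 0) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo)
      stop(sprintf("config key '%s' must be a number >= %g", key, lo))
  }
  num_pos("n0", 2); num_pos("harvest_rate"); num_pos("egg_harvest_rate")
  num_pos("horizon", 1); num_pos("replicates", 1); num_pos("seed", 0)
  num_pos("extinction_threshold", 0)
  if (!is.logical(cfg$dd) || is.na(cfg$dd))
    stop("config key 'dd' must be true or false")
  if (!(cfg$dd_floor > 0 && cfg$dd_floor <= 1))
    stop("config key 'dd_floor' must lie in (0, 1]")
  if (!cfg$extinction_rule %in% c("one_sex_remains", "below_threshold"))
    stop("config key 'extinction_rule' must be 'one_sex_remains' or 'below_threshold'")
  if (!cfg$harvest_policy %in% c("all_ages", "adults_only"))
    stop("config key 'harvest_policy' must be 'all_ages' or 'adults_only'")
  structure(cfg, class = "auk_config")
}

#' Load and validate a run configuration
#'
#' Reads a JSON (`.json`) or YAML (`.yaml`/`.yml`) scenario configuration,
#' rejects unknown keys, validates values and fills defaults (350-year
#' horizon, 100 replicates, "one sex remains" extinction rule, conservative
#' preset).
#'
#' @param path Path to the configuration file.
#' @return An `auk_config` (validated named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported configuration format '.", ext,
                     "' (use .json, .yaml or .yml)"))
  if (is.null(cfg)) cfg <- list()
  validate_config(as.list(cfg))
}

#' Write a run configuration
#'
#' @param config An `auk_config` (or plain named list of known keys).
#' @param path Destination path; format chosen from the extension as in
#'   [load_config()].
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- validate_config(as.list(unclass(config)))
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                                     digits = NA),
         yaml = ,
         yml = yaml::write_yaml(cfg, path),
         stop("unsupported configuration format '.", ext, "'"))
  invisible(path)
}

#' Turn a configuration into a scenario and its preset
#'
#' @param config An `auk_config` from [load_config()].
#' @return List with `scenario`, `life_table`, `breeding` and `preset`.
#' @export
config_to_scenario <- function(config) {
  stopifnot(inherits(config, "auk_config"))
  preset <- switch(config$preset,
                   conservative = conservative_preset(),
                   realistic = realistic_preset())
  dd <- if (isTRUE(config$dd))
    density_dependence(floor = config$dd_floor, reference = config$n0)
  else FALSE
  scn <- scenario(config$n0, config$harvest_rate, config$egg_harvest_rate,
                  dd = dd, horizon = config$horizon,
                  replicates = config$replicates, seed = config$seed,
                  extinction_rule = config$extinction_rule,
                  extinction_threshold = config$extinction_threshold,
                  harvest_policy = config$harvest_policy,
                  egg_max = config$egg_max,
                  escape_multiple = config$escape_multiple,
                  label = config$label)
  list(scenario = scn, life_table = preset$life_table,
       breeding = preset$breeding, preset = preset)
}

#' Write a results table as CSV
#'
#' Writes the data frame unquoted and at full precision (probabilities are
#' never rounded on disk; two-decimal display is presentation only). The
#' output is byte-identical for identical inputs.
#'
#' @param table A data frame, e.g. from [run_grid()].
#' @param path Destination CSV path.
#' @return The path, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
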