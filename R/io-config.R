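#' Read and write scenario configurations
#'
#' Scenario configurations serialise to YAML (or JSON) with every default
#' materialised, so a written file documents the exact run conditions.
#' Reading validates the physics ranges before returning.
#'
#' @param cfg A [scenario_config()].
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `write_scenario()`: `path` invisibly; `read_scenario()`: a
#'   validated `scenario_config`.
#' @export
write_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_assrmix(sprintf("No such config file: %s", path))
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("profile", "seed", "stimulus", "cochlea", "network", "forward",
            "analysis")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_assrmix(paste0("Config file missing group(s): ",
                        paste(miss, collapse = ", ")))
  }
  # rebuild over current defaults so new fields get defaults, then validate
  cfg <- scenario_config(x$profile, seed = x$seed)
  for (g in c("stimulus", "cochlea", "network", "forward", "analysis")) {
    cfg[[g]] <- modifyList(cfg[[g]], x[[g]])
  }
  # JSON has no Inf literal; "Inf" round-trips as a string
  cfg$analysis$n_segments <- as.numeric(cfg$analysis$n_segments)
  validate_scenario(cfg)
  cfg
}

#' Run manifest
#'
#' A small record sufficient to reproduce a run bit-exactly: the full
#' configuration, its hash, the seeds in force and the package version.
#'
#' @param cfg A [scenario_config()].
#' @param extra Named list of additional fields (e.g. algorithm settings).
#' @return A list with `config`, `config_hash`, `seed`, `package_version`,
#'   `r_version` and any `extra` fields.
#' @export
run_manifest <- function(cfg, extra = list()) {
  stopifnot(inherits(cfg, "scenario_config"))
  c(list(
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("assrmix")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  ), extra)
}
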