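# Declarative pipeline configuration from a single YAML or JSON document.

#' Read a pipeline configuration file
#'
#' One document configures the whole pipeline. Recognised top-level keys
#' (all optional; omitted keys fall back to the package defaults):
#' `geometry` (fields of [chip_geometry()]), `preanalytics`
#' ([preanalytics_params()]), `kinetics` ([cycle_kinetics()]), `policy`
#' ([sufficiency_policy()]), `matching_radius` (um), and
#' `composition_preset` (name for [composition_preset()]).
#'
#' @param path Path to a `.yaml`/`.yml` (requires the yaml package) or
#'   `.json` file.
#' @return A `pipeline_config` list with elements `geometry`,
#'   `preanalytics`, `kinetics`, `policy`, `matching_radius`,
#'   `composition` (NULL when no preset named).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) param_error("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      param_error("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  build <- function(fun, args) do.call(fun, as.list(args %||% list()))
  structure(list(
    geometry = build(chip_geometry, raw$geometry),
    preanalytics = build(preanalytics_params, raw$preanalytics),
    kinetics = build(cycle_kinetics, raw$kinetics),
    policy = build(sufficiency_policy, raw$policy),
    matching_radius = raw$matching_radius %||% 5,
    composition = if (!is.null(raw$composition_preset)) {
      composition_preset(raw$composition_preset)
    }
  ), class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
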