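#' Default run configuration
#'
#' The run configuration gathers every tunable the pipeline exposes:
#' masking parameters, the chromaticity median convention, model options
#' and the gradability thresholds. It is serialised (YAML) into every
#' output directory for provenance.
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    masking = list(border_percentile = 0.5, dilation_scale = 4,
                   reference_width = 600, connectivity = 2),
    chromaticity = list(median = "median_rgb"),
    model = list(variables = c("a", "b")),
    gradability = list(min_background_frac = 0.10,
                       max_saturated_frac = 0.20, min_iqr = 5),
    seed = 1L), class = "run_config")
}

CONFIG_SECTIONS <- c("masking", "chromaticity", "model", "gradability",
                     "seed")

#' Read and validate a YAML run configuration
#'
#' Unknown top-level sections or unknown keys within a section are refused
#' rather than ignored, so typos cannot silently fall back to defaults.
#' Missing keys take their default values.
#'
#' @param path Path to a YAML file (may specify any subset of keys).
#' @return A complete `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    stop("rps_io_error: no such config file: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  bad <- setdiff(names(user), CONFIG_SECTIONS)
  if (length(bad) > 0) {
    stop("rps_config_error: unknown config section(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (sec in intersect(names(user), setdiff(CONFIG_SECTIONS, "seed"))) {
    badkey <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(badkey) > 0) {
      stop("rps_config_error: unknown key(s) in '", sec, "': ",
           paste(badkey, collapse = ", "), call. = FALSE)
    }
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  if (!is.null(user$seed)) cfg$seed <- as.integer(user$seed)
  cfg
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config` list.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_masking_params <- function(config) {
  masking_params(border_percentile = config$masking$border_percentile,
                 dilation_scale = config$masking$dilation_scale,
                 reference_width = config$masking$reference_width,
                 connectivity = config$masking$connectivity)
}
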