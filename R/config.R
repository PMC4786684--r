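#' Analysis configuration
#'
#' One flat set of tunable parameters shared by the analysis stages, with
#' validation. Values can be loaded from a YAML or JSON file with
#' [read_config()]; arguments given here override file values.
#'
#' @param threshold_method "triangle" or "fixed".
#' @param threshold_value fixed threshold (required when
#'   `threshold_method = "fixed"`).
#' @param min_component_px artefact filter: smallest foreground component
#'   kept after thresholding, in pixels.
#' @param sholl_step_um Sholl sampling-radius step, micrometres.
#' @param sholl_max_um largest Sholl radius, micrometres.
#' @param projection_depth_um depth of the maximum projection per time point.
#' @param inner_radius_um,outer_radius_um ablation annulus radii (X and Y).
#' @param core_exclusion_um radius around the ablation centre excluded from
#'   pixel counts (the lesion itself).
#' @param min_punctum_px puncta must be strictly larger than this many pixels.
#' @param stim_frequency_hz stimulus repetition frequency for iOS analysis.
#' @param grubbs_alpha significance level for the one-pass Grubbs test.
#' @param seed integer seed for synthetic generation.
#' @return a validated `analysis_config` list.
#' @export
analysis_config <- function(threshold_method = "triangle",
                            threshold_value = NULL,
                            min_component_px = 4L,
                            sholl_step_um = 5,
                            sholl_max_um = 50,
                            projection_depth_um = 15,
                            inner_radius_um = 40,
                            outer_radius_um = 80,
                            core_exclusion_um = 5,
                            min_punctum_px = 1L,
                            stim_frequency_hz = NULL,
                            grubbs_alpha = 0.05,
                            seed = 1L) {
  threshold_method <- match.arg(threshold_method, c("triangle", "fixed"))
  if (threshold_method == "fixed" && is.null(threshold_value)) {
    stop("threshold_value required when threshold_method = 'fixed'", call. = FALSE)
  }
  for (nm in c("sholl_step_um", "sholl_max_um", "projection_depth_um",
               "inner_radius_um", "outer_radius_um", "grubbs_alpha")) {
    check_positive(get(nm), nm)
  }
  if (inner_radius_um >= outer_radius_um) {
    stop("inner_radius_um must be smaller than outer_radius_um", call. = FALSE)
  }
  if (min_component_px < 0 || min_punctum_px < 0) {
    stop("component/punctum sizes must be non-negative", call. = FALSE)
  }
  if (!is.null(stim_frequency_hz)) check_positive(stim_frequency_hz, "stim_frequency_hz")
  structure(
    list(threshold_method = threshold_method,
         threshold_value = threshold_value,
         min_component_px = as.integer(min_component_px),
         sholl_step_um = sholl_step_um, sholl_max_um = sholl_max_um,
         projection_depth_um = projection_depth_um,
         inner_radius_um = inner_radius_um, outer_radius_um = outer_radius_um,
         core_exclusion_um = core_exclusion_um,
         min_punctum_px = as.integer(min_punctum_px),
         stim_frequency_hz = stim_frequency_hz,
         grubbs_alpha = grubbs_alpha, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path file ending in .yaml/.yml or .json holding one flat mapping
#'   of [analysis_config()] keys.
#' @param ... overrides applied on top of the file values.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(analysis_config, vals)
}
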