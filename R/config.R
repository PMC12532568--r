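#' Default analysis configuration
#'
#' Every tunable of the pipeline lives in one nested list with per-module
#' sections, so a whole analysis is reproducible from a single YAML (or JSON)
#' document. Values passed to individual functions always win over the
#' config; the config wins over these package defaults.
#'
#' Sections and defaults:
#' * `puncta`: `median_size` (3 px), `smooth_sigma` (10 px),
#'   `body_threshold` (`"otsu"` or a fixed intensity), `min_body_area`
#'   (5000 px^2), `shrink_radius` (5 px), `threshold_factor` (1.0),
#'   `min_punctum_area` (4 px^2), `containment` (`"fully_inside"` or
#'   `"centroid_inside"`), `max_larvae` (3), `head_tail_offset` (40 px),
#'   `roi_margin` (20 px), `min_larva_area_lowmag` (400 px^2).
#' * `screen`: `vehicle_label` (`"DMSO"`), `summary` (`"mean"` or
#'   `"median"`), `normalization` (`"per_phase"` or `"pre_vehicle"`),
#'   `hit_fc_threshold` (1.5).
#' * `ratiometrics`: `epsilon` (1 intensity unit), `ratio_threshold` (2.0 or
#'   `"otsu"`), `min_focus_area` (4 px^2), `mode` (`"area"` or `"count"`).
#' * `physiology`: `maximal_rule` (`"mean_last3_before_raa"` or
#'   `"max_after_fccp"`), `active_threshold` (0.5), `activity_method`
#'   (`"vacated"` or `"symmetric"`).
#' * `io`: `pixel_size_um` fallback for TIFFs without resolution metadata.
#'
#' @return Nested named list of defaults.
#' @export
#' @examples
#' cfg <- lc3_config()
#' cfg$puncta$smooth_sigma
lc3_config <- function() {
  list(
    io = list(pixel_size_um = NULL),
    puncta = list(
      median_size = 3,
      smooth_sigma = 10,
      body_threshold = "otsu",
      min_body_area = 5000,
      shrink_radius = 5,
      threshold_factor = 1.0,
      min_punctum_area = 4,
      containment = "fully_inside",
      max_larvae = 3,
      head_tail_offset = 40,
      roi_margin = 20,
      min_larva_area_lowmag = 400
    ),
    screen = list(
      vehicle_label = "DMSO",
      summary = "mean",
      normalization = "per_phase",
      hit_fc_threshold = 1.5
    ),
    ratiometrics = list(
      epsilon = 1,
      ratio_threshold = 2.0,
      min_focus_area = 4,
      mode = "area"
    ),
    physiology = list(
      maximal_rule = "mean_last3_before_raa",
      active_threshold = 0.5,
      activity_method = "vacated"
    )
  )
}

#' Read an analysis configuration from YAML or JSON
#'
#' Values present in the file override the package defaults from
#' [lc3_config()]; everything else keeps its default, so partial configs are
#' fine.
#'
#' @param path Path to a YAML (or JSON, which YAML parses) document.
#' @return Nested named list, same shape as [lc3_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "lc3_io_error")
  }
  user <- yaml::read_yaml(path)
  modifyList(lc3_config(), user)
}
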