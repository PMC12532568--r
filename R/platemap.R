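PHASES <- c("pre_nh4cl", "post_nh4cl")

#' Read and validate a plate map
#'
#' The plate map describes each well: which compound it received, at which
#' dose, in which acquisition phase (before or after NH4Cl addition),
#' whether it is a vehicle, treatment or blank well, and whether the
#' treatment was toxic (toxicity is an input call, it is never computed
#' here). The `role` column is optional; when absent, wells whose compound
#' equals `vehicle_label` become `vehicle`, everything else `treatment`.
#'
#' Validation enforces: unique `(plate, well, phase)` rows, at least one
#' vehicle well per plate, doses >= 0, and dose 0 on vehicle rows.
#'
#' @param path CSV with columns `plate, well, compound, dose_um, phase`
#'   (required) and `role, toxic, notes` (optional).
#' @param vehicle_label Compound name treated as vehicle (default "DMSO").
#' @return A tibble of class `lc3_platemap`.
#' @export
read_platemap <- function(path, vehicle_label = "DMSO") {
  if (!file.exists(path)) {
    abort(paste0("plate map not found: ", path), class = "lc3_io_error")
  }
  pm <- readr::read_csv(path, show_col_types = FALSE)
  as_platemap(pm, vehicle_label = vehicle_label)
}

#' Validate a plate-map data frame
#'
#' @param pm Data frame with the plate-map columns (see [read_platemap()]).
#' @param vehicle_label Compound name treated as vehicle.
#' @return A tibble of class `lc3_platemap`.
#' @export
as_platemap <- function(pm, vehicle_label = "DMSO") {
  required <- c("plate", "well", "compound", "dose_um", "phase")
  missing_cols <- setdiff(required, names(pm))
  if (length(missing_cols) > 0) {
    abort(paste0("plate map is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "lc3_schema_error")
  }
  pm <- as_tibble(pm)
  pm$phase <- normalize_phase(pm$phase)
  if (!"role" %in% names(pm)) {
    pm$role <- ifelse(pm$compound == vehicle_label, "vehicle", "treatment")
  }
  if (!"toxic" %in% names(pm)) pm$toxic <- FALSE
  pm$toxic <- as.logical(pm$toxic)
  if (!"notes" %in% names(pm)) pm$notes <- NA_character_

  key <- paste(pm$plate, pm$well, pm$phase, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- pm[duplicated(key), c("plate", "well", "phase")][1, ]
    abort(sprintf("duplicate plate-map row for (%s, %s, %s)",
                  dup$plate, dup$well, dup$phase),
          class = "lc3_validation_error")
  }
  if (any(!is.finite(pm$dose_um)) || any(pm$dose_um < 0)) {
    abort("doses must be finite and >= 0", class = "lc3_validation_error")
  }
  if (any(pm$role == "vehicle" & pm$dose_um != 0)) {
    abort("vehicle rows must have dose 0", class = "lc3_validation_error")
  }
  no_vehicle <- setdiff(unique(pm$plate),
                        unique(pm$plate[pm$role == "vehicle"]))
  if (length(no_vehicle) > 0) {
    abort(paste0("plate(s) without a vehicle well: ",
                 paste(no_vehicle, collapse = ", ")),
          class = "lc3_validation_error")
  }
  class(pm) <- c("lc3_platemap", class(pm))
  pm
}

normalize_phase <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("pre", "pre_nh4cl", "-nh4cl", "baseline")] <- "pre_nh4cl"
  x[x %in% c("post", "post_nh4cl", "+nh4cl")] <- "post_nh4cl"
  bad <- setdiff(unique(x), PHASES)
  if (length(bad) > 0) {
    abort(paste0("unknown phase value(s): ", paste(bad, collapse = ", ")),
          class = "lc3_validation_error")
  }
  x
}
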