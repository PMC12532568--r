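#' Convert per-larva measurements to a long results table
#'
#' The long ("tidy") results format carries one row per
#' `(plate, well, larva, phase, metric)` with the value and its unit.
#' Excluded larvae (e.g. displaced during acquisition) keep their rows with
#' `excluded = TRUE` and an explicit `exclusion_reason`; they are never
#' silently dropped, so group n's remain auditable.
#'
#' @param wide Tibble with key columns `plate, well, larva, phase`, optional
#'   `excluded`/`exclusion_reason`, and one column per metric.
#' @return Long tibble with columns
#'   `plate, well, larva, phase, metric, value, unit, excluded,
#'   exclusion_reason`.
#' @export
as_results_table <- function(wide) {
  stopifnot(all(c("plate", "well", "larva", "phase") %in% names(wide)))
  wide <- as_tibble(wide)
  if (!"excluded" %in% names(wide)) wide$excluded <- FALSE
  if (!"exclusion_reason" %in% names(wide)) {
    wide$exclusion_reason <- NA_character_
  }
  keys <- c("plate", "well", "larva", "phase", "excluded", "exclusion_reason")
  metrics <- setdiff(names(wide), keys)
  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long$unit <- metric_unit(long$metric)
  long <- long[, c("plate", "well", "larva", "phase", "metric", "value",
                   "unit", "excluded", "exclusion_reason")]
  validate_results(long)
}

metric_unit <- function(metric) {
  dplyr::case_when(
    grepl("_px2$", metric) ~ "px^2",
    grepl("_um2$", metric) ~ "um^2",
    grepl("count$", metric) ~ "count",
    TRUE ~ "dimensionless"
  )
}

validate_results <- function(long) {
  key <- paste(long$plate, long$well, long$larva, long$phase, long$metric,
               sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate (plate, well, larva, phase, metric) rows",
          class = "lc3_validation_error")
  }
  if (any(long$excluded & is.na(long$exclusion_reason))) {
    abort("excluded rows must carry an exclusion reason",
          class = "lc3_validation_error")
  }
  long
}

#' Write a results table to CSV
#'
#' Columns are written in a stable order and numeric values with full
#' precision, so [read_results()] returns a table identical to the one
#' written (round trip is the identity on valid tables).
#'
#' @param table Long results tibble (see [as_results_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  table <- validate_results(table)
  out <- table
  out$value <- ifelse(is.na(out$value), "",
                      formatC(out$value, digits = 17, format = "g"))
  ok <- tryCatch(readr::write_csv(out, path),
                 error = function(e) {
                   abort(paste0("cannot write results: ", path),
                         class = "lc3_io_error")
                 })
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return Long results tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("results file not found: ", path), class = "lc3_io_error")
  }
  long <- readr::read_csv(
    path,
    col_types = readr::cols(
      plate = readr::col_character(), well = readr::col_character(),
      larva = readr::col_integer(), phase = readr::col_character(),
      metric = readr::col_character(), value = readr::col_double(),
      unit = readr::col_character(), excluded = readr::col_logical(),
      exclusion_reason = readr::col_character()
    )
  )
  validate_results(long)
}

#' Widen a long results table to one row per larva and phase
#'
#' @param long Long results tibble.
#' @return Wide tibble with one column per metric.
#' @export
results_wide <- function(long) {
  tidyr::pivot_wider(long,
                     id_cols = c("plate", "well", "larva", "phase",
                                 "excluded", "exclusion_reason"),
                     names_from = "metric", values_from = "value")
}
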