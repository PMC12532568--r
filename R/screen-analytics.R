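#' Normalize per-larva puncta readouts to the vehicle control
#'
#' Each larva's relative puncta area is divided by the mean (or median)
#' vehicle value of the same plate and phase, giving a per-larva fold
#' change; group fold changes (`fc`) are summaries of those per-larva
#' values per `(compound, dose, phase)`. Displaced / excluded larvae are
#' omitted from all means but their exclusion stays on record upstream.
#' The vehicle group's own fold change is 1 by construction.
#'
#' @param records Per-larva measurements: either the wide tibble from
#'   [process_well()] / [make_screen()] or a long results table (it is
#'   widened automatically). Must carry `relative_puncta_area`.
#' @param platemap An `lc3_platemap` (or data frame accepted by
#'   [as_platemap()]).
#' @param summary `"mean"` (default, matching fold-change heatmap
#'   semantics) or `"median"`.
#' @param normalization `"per_phase"` (each phase normalized to its own
#'   vehicle, default) or `"pre_vehicle"` (both phases normalized to the
#'   pre-NH4Cl vehicle).
#' @return Tibble of class `lc3_normalized` with columns
#'   `compound, dose_um, phase, fc, n, reason`; per-larva normalized values
#'   are kept in the `per_larva` attribute.
#' @export
normalize_to_vehicle <- function(records, platemap, summary = c("mean",
                                                                "median"),
                                 normalization = c("per_phase",
                                                   "pre_vehicle")) {
  summary <- match.arg(summary)
  normalization <- match.arg(normalization)
  est <- if (summary == "mean") mean else stats::median
  if ("metric" %in% names(records)) records <- results_wide(records)
  if (!inherits(platemap, "lc3_platemap")) platemap <- as_platemap(platemap)

  df <- records %>%
    filter(!.data$excluded, !is.na(.data$relative_puncta_area)) %>%
    left_join(platemap %>%
                select("plate", "well", "phase", "compound", "dose_um",
                       "role"),
              by = c("plate", "well", "phase"))
  if (anyNA(df$compound)) {
    miss <- df %>% filter(is.na(.data$compound)) %>%
      distinct(.data$plate, .data$well, .data$phase)
    abort(paste0("plate-map row missing for: ",
                 paste(paste(miss$plate, miss$well, miss$phase, sep = "/"),
                       collapse = "; ")),
          class = "lc3_validation_error")
  }

  veh <- df %>%
    filter(.data$role == "vehicle") %>%
    group_by(.data$plate, .data$phase) %>%
    summarise(vehicle_mean = est(.data$relative_puncta_area), .groups = "drop")
  strata <- df %>% distinct(.data$plate, .data$phase)
  no_veh <- dplyr::anti_join(strata, veh, by = c("plate", "phase"))
  if (nrow(no_veh) > 0) {
    abort(paste0("no vehicle larvae in stratum: ",
                 paste(paste(no_veh$plate, no_veh$phase, sep = "/"),
                       collapse = "; ")),
          class = "lc3_validation_error")
  }
  if (normalization == "pre_vehicle") {
    veh <- veh %>% filter(.data$phase == "pre_nh4cl") %>% select(-"phase")
    df <- df %>% left_join(veh, by = "plate")
  } else {
    df <- df %>% left_join(veh, by = c("plate", "phase"))
  }

  per_larva <- df %>%
    mutate(fc = ifelse(.data$vehicle_mean > 0,
                       .data$relative_puncta_area / .data$vehicle_mean,
                       NA_real_))
  out <- per_larva %>%
    group_by(.data$compound, .data$dose_um, .data$phase) %>%
    summarise(fc = est(.data$fc), n = dplyr::n(),
              bad_vehicle = any(.data$vehicle_mean <= 0),
              .groups = "drop") %>%
    mutate(reason = ifelse(.data$bad_vehicle, "vehicle mean is 0",
                           NA_character_),
           fc = ifelse(.data$bad_vehicle, NA_real_, .data$fc)) %>%
    select(-"bad_vehicle") %>%
    arrange(.data$compound, .data$dose_um, .data$phase)
  attr(out, "per_larva") <- per_larva %>%
    select("plate", "well", "larva", "phase", "compound", "dose_um",
           "role", "relative_puncta_area", "fc")
  class(out) <- c("lc3_normalized", class(out))
  out
}

#' Autophagic-flux summary from paired pre/post NH4Cl responses
#'
#' Autophagic flux is read out by comparing autophagosome abundance with
#' and without lysosomal blockade: for each `(compound, dose)` group the
#' flux ratio is the group fold change in the presence of NH4Cl divided by
#' the fold change in its absence. When the same larvae were measured in
#' both phases, per-larva paired ratios (post/pre, normalized to the
#' vehicle's paired ratio) are also reported.
#'
#' @param normalized An `lc3_normalized` table containing both phases.
#' @return Tibble with `compound, dose_um, fc_pre, fc_post, flux_ratio,
#'   n_pre, n_post, paired_flux, n_paired, reason` (`reason` set and ratio
#'   absent when a group lacks one phase).
#' @export
compute_flux <- function(normalized) {
  wide <- normalized %>%
    select("compound", "dose_um", "phase", "fc", "n") %>%
    tidyr::pivot_wider(names_from = "phase", values_from = c("fc", "n"))
  for (col in c("fc_pre_nh4cl", "fc_post_nh4cl", "n_pre_nh4cl",
                "n_post_nh4cl")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  out <- wide %>%
    mutate(
      flux_ratio = .data$fc_post_nh4cl / .data$fc_pre_nh4cl,
      reason = case_when(
        is.na(.data$fc_pre_nh4cl) ~ "group missing pre_nh4cl phase",
        is.na(.data$fc_post_nh4cl) ~ "group missing post_nh4cl phase",
        TRUE ~ NA_character_
      )
    ) %>%
    rename(fc_pre = "fc_pre_nh4cl", fc_post = "fc_post_nh4cl",
           n_pre = "n_pre_nh4cl", n_post = "n_post_nh4cl")

  per_larva <- attr(normalized, "per_larva")
  if (!is.null(per_larva) && "larva" %in% names(per_larva)) {
    paired <- per_larva %>%
      select("plate", "well", "larva", "phase", "compound", "dose_um",
             "role", "relative_puncta_area") %>%
      tidyr::pivot_wider(names_from = "phase",
                         values_from = "relative_puncta_area") %>%
      filter(!is.na(.data$pre_nh4cl), !is.na(.data$post_nh4cl),
             .data$pre_nh4cl > 0) %>%
      mutate(ratio = .data$post_nh4cl / .data$pre_nh4cl)
    if (nrow(paired) > 0) {
      veh_ratio <- paired %>%
        filter(.data$role == "vehicle") %>%
        group_by(.data$plate) %>%
        summarise(vr = mean(.data$ratio), .groups = "drop")
      pf <- paired %>%
        left_join(veh_ratio, by = "plate") %>%
        group_by(.data$compound, .data$dose_um) %>%
        summarise(paired_flux = mean(.data$ratio / .data$vr),
                  n_paired = dplyr::n(), .groups = "drop")
      out <- out %>% left_join(pf, by = c("compound", "dose_um"))
    }
  }
  if (!"paired_flux" %in% names(out)) {
    out$paired_flux <- NA_real_
    out$n_paired <- NA_integer_
  }
  out %>% arrange(.data$compound, .data$dose_um)
}

#' Assemble per-compound dose-response profiles with toxicity masking
#'
#' Doses are ordered ascending; fold changes in both phases are carried per
#' dose together with the toxicity flag from the plate map (a
#' compound/dose cell is toxic when any of its wells is flagged). E_max --
#' the maximum fold change in the presence of NH4Cl -- is computed over
#' non-toxic doses only; compounds whose every dose is toxic are reported
#' as excluded, with no E_max.
#'
#' @param normalized An `lc3_normalized` table.
#' @param platemap Plate map supplying the toxicity flags.
#' @return Tibble of class `lc3_profiles`: one row per compound with
#'   `e_max`, `e_max_dose`, `excluded`, and a `doses` list-column holding
#'   the per-dose table (`dose_um, fc_pre, fc_post, toxic`).
#' @export
build_dose_response <- function(normalized, platemap) {
  if (!inherits(platemap, "lc3_platemap")) platemap <- as_platemap(platemap)
  tox <- platemap %>%
    group_by(.data$compound, .data$dose_um) %>%
    summarise(toxic = any(.data$toxic), .groups = "drop")
  wide <- normalized %>%
    filter(.data$dose_um > 0) %>%
    select("compound", "dose_um", "phase", "fc") %>%
    tidyr::pivot_wider(names_from = "phase", values_from = "fc") %>%
    left_join(tox, by = c("compound", "dose_um")) %>%
    mutate(toxic = ifelse(is.na(.data$toxic), FALSE, .data$toxic))
  if (!"pre_nh4cl" %in% names(wide)) wide$pre_nh4cl <- NA_real_
  if (!"post_nh4cl" %in% names(wide)) wide$post_nh4cl <- NA_real_
  profiles <- wide %>%
    rename(fc_pre = "pre_nh4cl", fc_post = "post_nh4cl") %>%
    arrange(.data$compound, .data$dose_um) %>%
    group_by(.data$compound) %>%
    tidyr::nest(doses = c("dose_um", "fc_pre", "fc_post", "toxic")) %>%
    ungroup() %>%
    mutate(
      e_max = map_dbl(.data$doses, function(d) {
        ok <- !d$toxic & !is.na(d$fc_post)
        if (!any(ok)) NA_real_ else max(d$fc_post[ok])
      }),
      e_max_dose = map_dbl(.data$doses, function(d) {
        ok <- !d$toxic & !is.na(d$fc_post)
        if (!any(ok)) NA_real_ else {
          min(d$dose_um[ok & d$fc_post == max(d$fc_post[ok])])
        }
      }),
      excluded = map_lgl(.data$doses, function(d) all(d$toxic))
    )
  class(profiles) <- c("lc3_profiles", class(profiles))
  profiles
}

#' Rank compounds by maximum efficacy
#'
#' Descending sort by E_max (the maximum vehicle-normalized fold change in
#' the presence of NH4Cl over non-toxic doses). Ties are broken in favour
#' of the compound achieving its E_max at the lowest dose, then by compound
#' name. The hit flag is threshold-dependent: `e_max >= hit_fc_threshold`.
#' Excluded (all-toxic) compounds sort last with no rank.
#'
#' @param profiles An `lc3_profiles` table from [build_dose_response()].
#' @param hit_fc_threshold Fold-change threshold for hit calling
#'   (default 1.5).
#' @return Tibble with `rank, compound, e_max, e_max_dose, hit, excluded`.
#' @export
rank_hits <- function(profiles, hit_fc_threshold = 1.5) {
  ranked <- profiles %>%
    select("compound", "e_max", "e_max_dose", "excluded") %>%
    arrange(.data$excluded, desc(.data$e_max), .data$e_max_dose,
            .data$compound) %>%
    mutate(
      rank = ifelse(.data$excluded, NA_integer_,
                    cumsum(!.data$excluded)),
      hit = ifelse(.data$excluded, NA,
                   .data$e_max >= hit_fc_threshold)
    ) %>%
    select("rank", "compound", "e_max", "e_max_dose", "hit", "excluded")
  ranked
}

#' Compound-by-dose heatmap matrix
#'
#' The screen's summary view: a compounds x doses matrix of fold changes in
#' the presence of NH4Cl, rows ordered as in [rank_hits()]. Toxic cells are
#' masked (`NA` in the numeric matrix, `TRUE` in the `toxic` attribute, the
#' sentinel string `"TOXIC"` in the CSV) -- distinct from cells that were
#' simply not measured, which are `NA` in both.
#'
#' @param profiles An `lc3_profiles` table.
#' @param path Optional CSV output path.
#' @return Numeric matrix (compounds x doses) with attribute `toxic`
#'   (logical matrix of the same shape).
#' @export
export_heatmap_matrix <- function(profiles, path = NULL) {
  if (nrow(profiles) == 0) {
    m <- matrix(numeric(), 0, 0)
    attr(m, "toxic") <- matrix(logical(), 0, 0)
    return(m)
  }
  order_cmp <- rank_hits(profiles)$compound
  long <- profiles %>%
    select("compound", "doses") %>%
    tidyr::unnest("doses")
  doses <- sort(unique(long$dose_um))
  m <- matrix(NA_real_, length(order_cmp), length(doses),
              dimnames = list(order_cmp, paste0(doses, "uM")))
  tox <- matrix(FALSE, length(order_cmp), length(doses),
                dimnames = dimnames(m))
  for (i in seq_len(nrow(long))) {
    r <- match(long$compound[i], order_cmp)
    c <- match(long$dose_um[i], doses)
    tox[r, c] <- long$toxic[i]
    m[r, c] <- if (long$toxic[i]) NA_real_ else long$fc_post[i]
  }
  attr(m, "toxic") <- tox
  if (!is.null(path)) {
    out <- m
    chr <- matrix(ifelse(tox, "TOXIC",
                         ifelse(is.na(out), "",
                                formatC(out, digits = 17, format = "g"))),
                  nrow(out), ncol(out), dimnames = dimnames(out))
    df <- as_tibble(chr, rownames = "compound")
    readr::write_csv(df, path)
  }
  m
}
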