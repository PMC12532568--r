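#' Mitophagy index and mitolysosome foci from a mito-QC field
#'
#' In mito-QC reporters mitochondria carry a tandem mCherry-GFP tag; inside
#' acidic lysosomes GFP is quenched, so mitolysosomes appear mCherry-only.
#' The mitochondrial mask is a global threshold on the mCherry channel; a
#' per-pixel ratio image `A / (B + epsilon)` identifies mCherry-only
#' pixels (`ratio > ratio_threshold`) within that mask; components at least
#' `min_focus_area` px^2 are the mitolysosome foci. The index is either the
#' mitolysosome area fraction of the mitochondrial area (`mode = "area"`,
#' the default, bounded in `[0, 1]`) or the foci count divided by the
#' mitochondrial object count (`mode = "count"`). The foci count is always
#' reported.
#'
#' @param field An [two_channel_field()] with A = mCherry, B = GFP.
#' @param ratio_threshold Numeric ratio cut (default 2: a pixel is
#'   mCherry-only when mCherry exceeds twice the GFP signal), or `"otsu"`
#'   for a data-driven cut on the log-ratio within the mitochondrial mask.
#' @param min_focus_area Minimum focus area, px^2.
#' @param mode `"area"` or `"count"`.
#' @param mito_threshold Threshold for the mitochondrial mask: `"otsu"` or
#'   a fixed intensity.
#' @param epsilon Intensity unit added to the denominator to avoid division
#'   blow-ups (default 1).
#' @return One-row tibble: `mitophagy_index, foci_count, mito_area_px2,
#'   mitolysosome_area_px2, mode, reason` (index `NA` with a reason when the
#'   mitochondrial mask is empty).
#' @export
mitophagy_index <- function(field, ratio_threshold = 2, min_focus_area = 4,
                            mode = c("area", "count"),
                            mito_threshold = "otsu", epsilon = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "lc3_field"))
  a <- field$a; b <- field$b
  if (!is.null(field$roi)) {
    a <- a * field$roi; b <- b * field$roi
  }
  thr <- if (is.numeric(mito_threshold)) mito_threshold else otsu_threshold(a)
  mito <- a > thr
  if (!any(mito)) {
    return(tibble(mitophagy_index = NA_real_, foci_count = NA_real_,
                  mito_area_px2 = 0, mitolysosome_area_px2 = NA_real_,
                  mode = mode, reason = "empty mitochondrial mask"))
  }
  ratio <- a / (b + epsilon)
  rt <- if (identical(ratio_threshold, "otsu")) {
    lr <- log(ratio[mito])
    exp(otsu_threshold(matrix(lr - min(lr), ncol = 1)) + min(lr))
  } else {
    ratio_threshold
  }
  lyso_pre <- mito & ratio > rt
  lab <- label_mask(lyso_pre)
  foci <- 0L
  lyso_area <- 0
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], max(lab))
    keep <- which(areas >= min_focus_area)
    foci <- length(keep)
    lyso_area <- sum(areas[keep])
  }
  idx <- if (mode == "area") {
    lyso_area / sum(mito)
  } else {
    n_mito <- max(label_mask(mito))
    if (n_mito == 0) NA_real_ else foci / n_mito
  }
  tibble(mitophagy_index = idx, foci_count = as.numeric(foci),
         mito_area_px2 = as.numeric(sum(mito)),
         mitolysosome_area_px2 = as.numeric(lyso_area),
         mode = mode, reason = NA_character_)
}

#' mtRosella DsRed/GFP mitophagy ratio
#'
#' The mtRosella biosensor pairs pH-insensitive DsRed with pH-sensitive
#' GFP; delivery of mitochondria to acidic compartments quenches GFP, so a
#' higher DsRed/GFP mean-intensity ratio over the region of interest means
#' more mitophagy.
#'
#' @param field An [two_channel_field()] with A = DsRed, B = GFP.
#' @param roi Optional logical mask; defaults to the field's ROI or the
#'   whole field.
#' @return Ratio of mean DsRed to mean GFP intensity over the ROI
#'   (`NA` with a warning when the GFP mean is 0).
#' @export
rosella_ratio <- function(field, roi = NULL) {
  stopifnot(inherits(field, "lc3_field"))
  roi <- roi %||% field$roi %||% (field$a >= 0)
  if (!any(roi)) abort("empty ROI", class = "lc3_usage_error")
  gfp <- mean(field$b[roi])
  if (gfp <= 0) {
    warn("GFP mean intensity is 0; ratio undefined")
    return(NA_real_)
  }
  mean(field$a[roi]) / gfp
}

#' TMRM/MitoTracker membrane-potential area ratio
#'
#' MitoTracker marks all mitochondria regardless of potential; TMRM
#' partitions only into polarized mitochondria. Both channels are
#' segmented and the ratio of TMRM-positive area to MitoTracker-positive
#' area quantifies the fraction of the network holding a membrane
#' potential (1 = fully polarized, 0 = fully depolarized).
#'
#' By default one shared threshold -- Otsu on the MitoTracker (structural)
#' channel -- is applied to both channels, so an empty TMRM channel yields
#' an empty TMRM mask rather than a spurious split of its noise floor.
#'
#' @param field An [two_channel_field()] with A = TMRM, B = MitoTracker.
#' @param thresholds Either `"shared_otsu"` (default) or a named list
#'   `list(tmrm = , mito = )` of fixed intensity thresholds.
#' @return TMRM-positive area / MitoTracker-positive area (`NA` with a
#'   warning when the MitoTracker mask is empty).
#' @export
membrane_potential_ratio <- function(field, thresholds = "shared_otsu") {
  stopifnot(inherits(field, "lc3_field"))
  a <- field$a; b <- field$b
  if (!is.null(field$roi)) {
    a <- a * field$roi; b <- b * field$roi
  }
  if (identical(thresholds, "shared_otsu")) {
    thr <- otsu_threshold(b)
    thr_a <- thr; thr_b <- thr
  } else {
    thr_a <- thresholds$tmrm; thr_b <- thresholds$mito
  }
  mito_area <- sum(b > thr_b)
  if (mito_area == 0) {
    warn("empty MitoTracker mask; ratio undefined")
    return(NA_real_)
  }
  sum(a > thr_a) / mito_area
}

#' JC-10 monomer/aggregate ratio
#'
#' JC-10 aggregates in polarized mitochondria; depolarization shifts the
#' dye toward its monomeric form, so the monomer/aggregate ratio rises
#' with depolarization. Scalars or vectors are treated as per-event flow
#' signals (element-wise ratio); matrices as per-cell images (ratio of
#' mean intensities). Channel-to-role assignment is the caller's explicit
#' responsibility -- it is never inferred from emission wavelengths.
#'
#' @param monomer_signal,aggregate_signal Non-negative scalars, vectors of
#'   equal length, or matrices of equal shape.
#' @return Numeric ratio(s); `NA` where the aggregate signal is 0.
#' @export
jc10_ratio <- function(monomer_signal, aggregate_signal) {
  if (is.matrix(monomer_signal)) {
    stopifnot(is.matrix(aggregate_signal),
              all(dim(monomer_signal) == dim(aggregate_signal)))
    agg <- mean(aggregate_signal)
    if (agg <= 0) {
      warn("aggregate signal is 0; ratio undefined")
      return(NA_real_)
    }
    return(mean(monomer_signal) / agg)
  }
  stopifnot(length(monomer_signal) == length(aggregate_signal),
            all(monomer_signal >= 0, na.rm = TRUE),
            all(aggregate_signal >= 0, na.rm = TRUE))
  out <- ifelse(aggregate_signal > 0,
                monomer_signal / aggregate_signal, NA_real_)
  if (anyNA(out)) warn("aggregate signal 0 for some events; ratio NA there")
  out
}

#' Flow-cytometry autophagic-flux formula
#'
#' Flux from LC3-II mean fluorescence intensities with and without a
#' lysosomal inhibitor: `((+inhibitor) - (-inhibitor)) / (-inhibitor)`.
#' Negative flux (signal lower with the inhibitor) is reported as-is with
#' a warning, since it usually flags a technical problem.
#'
#' @param mfi_plus_inhibitor,mfi_minus_inhibitor MFI values (vectorized).
#' @return Flux value(s); `NA` with a warning where the minus-inhibitor MFI
#'   is not positive.
#' @export
#' @examples
#' flow_flux(450, 300) # 0.5
flow_flux <- function(mfi_plus_inhibitor, mfi_minus_inhibitor) {
  n <- max(length(mfi_plus_inhibitor), length(mfi_minus_inhibitor))
  plus <- rep_len(mfi_plus_inhibitor, n)
  minus <- rep_len(mfi_minus_inhibitor, n)
  out <- (plus - minus) / minus
  out[minus <= 0] <- NA_real_
  if (anyNA(out)) warn("non-positive minus-inhibitor MFI; flux undefined")
  if (any(out < 0, na.rm = TRUE)) warn("negative flux value(s) reported")
  out
}
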