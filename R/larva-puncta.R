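#' Maximal projection of a Z-stack
#'
#' Per-pixel maximum over the Z axis; a single-plane stack projects to
#' itself. Multi-channel stacks must have a channel selected first.
#'
#' @param stack An `lc3_stack` (or a `[y, x, z]` array / matrix).
#' @return Numeric matrix `[y, x]`.
#' @export
#' @examples
#' s <- image_stack(array(runif(10 * 10 * 4), c(10, 10, 4)))
#' p <- max_project(s)
max_project <- function(stack) {
  if (inherits(stack, "lc3_stack")) {
    if (stack$planes == "c") {
      abort("multi-channel stack: select a channel before projecting",
            class = "lc3_usage_error")
    }
    px <- stack$pixels
  } else if (is.matrix(stack)) {
    return(stack)
  } else {
    px <- stack
  }
  if (dim(px)[3] == 1L) return(px[, , 1])
  apply(px, c(1, 2), max)
}

#' Compute the larva body mask from a projection
#'
#' The projection is smoothed (median then Gaussian, see [smooth_image()]),
#' the smoothed image is binarized by a global threshold (Otsu by default)
#' into a pre-body mask, the mask is cleaned by area filtering (components
#' below `min_body_area` dropped, then the largest kept) and finally shrunk
#' by a disc erosion so the mask sits safely inside the true body outline.
#'
#' @param projection Numeric matrix (maximal projection).
#' @param median_size,smooth_sigma Smoothing parameters, px.
#' @param body_threshold `"otsu"` or a fixed intensity threshold.
#' @param min_body_area Minimum component area kept, px^2.
#' @param shrink_radius Erosion disc radius, px.
#' @param well Optional well identity, carried into the "no larva detected"
#'   condition so displaced exclusions stay auditable.
#' @return List with `smoothed` (matrix), `mask` (logical matrix, a single
#'   connected component), and `threshold` used.
#' @export
compute_body_mask <- function(projection, median_size = 3, smooth_sigma = 10,
                              body_threshold = "otsu", min_body_area = 5000,
                              shrink_radius = 5, well = NULL) {
  projection <- as_matrix(projection)
  smoothed <- smooth_image(projection, median_size, smooth_sigma)
  thr <- if (is.numeric(body_threshold)) body_threshold else {
    otsu_threshold(smoothed)
  }
  if (!is.numeric(body_threshold) && !has_contrast(smoothed, thr)) {
    signal_no_larva(well)
  }
  pre <- smoothed > thr
  lab <- label_mask(pre)
  areas <- if (max(lab) > 0) tabulate(lab[lab > 0], max(lab)) else integer()
  big <- which(areas >= min_body_area)
  if (length(big) == 0) signal_no_larva(well)
  largest <- big[which.max(areas[big])]
  mask <- lab == largest
  mask <- erode_mask(mask, shrink_radius)
  if (!any(mask)) signal_no_larva(well)
  # erosion can split a thin body; keep the largest piece so the body mask
  # stays a single connected component
  lab2 <- label_mask(mask)
  if (max(lab2) > 1) {
    areas2 <- tabulate(lab2[lab2 > 0], max(lab2))
    mask <- lab2 == which.max(areas2)
  }
  list(smoothed = smoothed, mask = mask, threshold = thr)
}

signal_no_larva <- function(well) {
  abort(paste0("no larva detected",
               if (!is.null(well)) paste0(" in well ", well) else ""),
        class = "lc3_no_larva", well = well)
}

#' Segment LC3 puncta inside the body mask
#'
#' The smoothed background estimate is subtracted from the projection
#' (clipped at zero); the subtracted image is binarized at
#' `threshold_factor` times the mean smoothed intensity over the body mask;
#' connected components smaller than `min_punctum_area` are dropped; and
#' only objects satisfying the containment rule with respect to the body
#' mask are kept (by default every object pixel must lie inside the body).
#'
#' @param projection,smoothed Matrices from the projection/smoothing steps.
#' @param body_mask Logical matrix, non-empty.
#' @param threshold_factor Scale factor `k` on the body-covered smoothed
#'   mean (default 1).
#' @param min_punctum_area Minimum punctum area, px^2.
#' @param containment `"fully_inside"` (every pixel inside the body mask) or
#'   `"centroid_inside"`.
#' @return Object of class `lc3_segmentation`: projection, smoothed,
#'   subtracted image, body mask, labeled puncta (`puncta_labels`), binary
#'   `puncta_mask`, the threshold used, and an `objects` tibble (label,
#'   area, centroid, mean intensity).
#' @export
segment_puncta <- function(projection, smoothed, body_mask,
                           threshold_factor = 1, min_punctum_area = 4,
                           containment = c("fully_inside",
                                           "centroid_inside")) {
  containment <- match.arg(containment)
  projection <- as_matrix(projection)
  if (!all(dim(projection) == dim(smoothed)) ||
      !all(dim(projection) == dim(body_mask))) {
    abort("projection, smoothed and body mask must share shape",
          class = "lc3_usage_error")
  }
  if (!any(body_mask)) {
    abort("empty body mask", class = "lc3_usage_error")
  }
  subtracted <- pmax(projection - smoothed, 0)
  thr <- threshold_factor * mean(smoothed[body_mask])
  lab <- label_mask(subtracted > thr)
  keep <- integer()
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], max(lab))
    keep <- which(areas >= min_punctum_area)
    if (length(keep) > 0) {
      if (containment == "fully_inside") {
        outside <- lab[!body_mask]
        outside_counts <- tabulate(outside[outside > 0], max(lab))
        keep <- keep[outside_counts[keep] == 0]
      } else {
        st <- label_stats(lab)
        st <- st[st$label %in% keep, ]
        cy <- pmin(pmax(round(st$centroid_y), 1), nrow(body_mask))
        cx <- pmin(pmax(round(st$centroid_x), 1), ncol(body_mask))
        inside <- body_mask[cbind(cy, cx)]
        keep <- st$label[inside]
      }
    }
  }
  # relabel retained objects 1..n in original label order
  relabel <- integer(max(lab, 1))
  relabel[keep] <- seq_along(keep)
  puncta_labels <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  puncta_labels[nz] <- relabel[lab[nz]]
  objects <- label_stats(puncta_labels, projection)
  structure(
    list(projection = projection, smoothed = smoothed,
         subtracted = subtracted, body_mask = body_mask,
         puncta_mask = puncta_labels > 0, puncta_labels = puncta_labels,
         threshold = thr, objects = objects),
    class = "lc3_segmentation"
  )
}

#' @export
print.lc3_segmentation <- function(x, ...) {
  cat(sprintf("<lc3_segmentation> body %d px^2, %d puncta (%.0f px^2), T = %.2f\n",
              sum(x$body_mask), nrow(x$objects), sum(x$objects$area_px2),
              x$threshold))
  invisible(x)
}

#' Per-larva puncta measurement
#'
#' Summarizes a segmentation into the screen's readout: body area, puncta
#' count, puncta total area, and the relative puncta area (puncta total
#' area divided by body area) -- the dimensionless quantity every
#' downstream normalization consumes. Areas are reported in both px^2 and
#' um^2 (`px^2 * pixel_size_um^2`).
#'
#' @param seg An `lc3_segmentation`.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return One-row tibble with `body_area_px2`, `body_area_um2`,
#'   `puncta_count`, `puncta_total_area_px2`, `puncta_total_area_um2`,
#'   `relative_puncta_area`.
#' @export
measure_puncta <- function(seg, pixel_size_um = 1) {
  stopifnot(inherits(seg, "lc3_segmentation"))
  body <- sum(seg$body_mask)
  total <- sum(seg$objects$area_px2)
  k2 <- pixel_size_um^2
  tibble(
    body_area_px2 = as.numeric(body),
    body_area_um2 = body * k2,
    puncta_count = as.numeric(nrow(seg$objects)),
    puncta_total_area_px2 = total,
    puncta_total_area_um2 = total * k2,
    relative_puncta_area = total / body
  )
}

#' Locate larvae in a low-magnification well image
#'
#' Detects up to `max_larvae` larva silhouettes (smoothing, global
#' threshold, area filtering), finds each silhouette's long axis by
#' principal components of its pixel coordinates, and anchors the analysis
#' area `head_tail_offset` px inward from both the head-side and tail-side
#' extremes. Larvae whose silhouette touches the image border, or is too
#' short for the offset window, are flagged (see the `flagged` attribute)
#' and not returned. An empty well returns an empty tibble.
#'
#' @param lowmag Single-channel 2D image (matrix or one-plane `lc3_stack`).
#' @param max_larvae Maximum ROIs returned (largest silhouettes win).
#' @param head_tail_offset Inward offset from head/tail extremes, px.
#' @param min_larva_area Minimum silhouette area, px^2.
#' @param median_size,smooth_sigma Detection smoothing parameters.
#' @return Tibble with one ROI per larva: `larva`, 1-based inclusive bounds
#'   `y0, y1, x0, x1`, `anchor_y, anchor_x` (analysis-area centre) and
#'   `area_px2`, sorted by position for stable indexing. Attribute
#'   `flagged`: tibble of skipped silhouettes with reasons.
#' @export
locate_larvae <- function(lowmag, max_larvae = 3, head_tail_offset = 40,
                          min_larva_area = 400, median_size = 3,
                          smooth_sigma = 5) {
  img <- as_matrix(lowmag)
  smoothed <- smooth_image(img, median_size, smooth_sigma)
  thr <- otsu_threshold(smoothed)
  empty <- tibble(larva = integer(), y0 = integer(), y1 = integer(),
                  x0 = integer(), x1 = integer(), anchor_y = numeric(),
                  anchor_x = numeric(), area_px2 = numeric())
  flagged <- tibble(anchor_y = numeric(), anchor_x = numeric(),
                    reason = character())
  if (!has_contrast(smoothed, thr)) return(structure(empty, flagged = flagged))
  lab <- label_mask(smoothed > thr)
  if (max(lab) == 0) return(structure(empty, flagged = flagged))
  areas <- tabulate(lab[lab > 0], max(lab))
  cand <- which(areas >= min_larva_area)
  if (length(cand) == 0) return(structure(empty, flagged = flagged))
  # keep the largest silhouettes if more than max_larvae candidates
  cand <- cand[order(areas[cand], decreasing = TRUE)]
  rois <- list()
  for (lb in cand) {
    idx <- which(lab == lb)
    yy <- (idx - 1) %% nrow(lab) + 1
    xx <- (idx - 1) %/% nrow(lab) + 1
    touches_border <- any(yy == 1 | yy == nrow(lab) |
                          xx == 1 | xx == ncol(lab))
    # long axis by PCA of pixel coordinates
    pts <- cbind(yy, xx)
    ctr <- colMeans(pts)
    ev <- eigen(stats::cov(pts), symmetric = TRUE)$vectors[, 1]
    t_coord <- (pts[, 1] - ctr[1]) * ev[1] + (pts[, 2] - ctr[2]) * ev[2]
    span <- max(t_coord) - min(t_coord)
    if (touches_border || span <= 2 * head_tail_offset) {
      reason <- if (touches_border) "touches image border" else {
        "offset window does not fit"
      }
      flagged <- bind_rows(flagged, tibble(anchor_y = ctr[1],
                                           anchor_x = ctr[2],
                                           reason = reason))
      next
    }
    keep <- t_coord >= min(t_coord) + head_tail_offset &
      t_coord <= max(t_coord) - head_tail_offset
    sub <- pts[keep, , drop = FALSE]
    rois[[length(rois) + 1]] <- tibble(
      y0 = min(sub[, 1]), y1 = max(sub[, 1]),
      x0 = min(sub[, 2]), x1 = max(sub[, 2]),
      anchor_y = mean(sub[, 1]), anchor_x = mean(sub[, 2]),
      area_px2 = as.numeric(areas[lb])
    )
    if (length(rois) == max_larvae) break
  }
  if (length(rois) == 0) return(structure(empty, flagged = flagged))
  out <- list_rbind(rois) %>%
    arrange(.data$anchor_x, .data$anchor_y) %>%
    mutate(larva = row_number(), .before = 1)
  structure(out, flagged = flagged)
}

#' Run the full puncta chain for one well, pre and post NH4Cl
#'
#' For each acquisition phase the stack is maximally projected, larvae are
#' located on the projection, each larva is cropped (with a margin) and run
#' through body masking, puncta segmentation and measurement. Larvae are
#' paired across phases by nearest anchor distance (ties broken by smallest
#' distance then lowest larva index); a larva detectable in only one phase
#' is emitted as a displaced-excluded record for the missing phase, never
#' silently dropped.
#'
#' @param pre_stack `lc3_stack` acquired before NH4Cl.
#' @param post_stack `lc3_stack` acquired after NH4Cl, or `NULL` for a
#'   baseline-only design.
#' @param platemap_row One-row data frame with at least `plate` and `well`.
#' @param config Configuration list, see [lc3_config()].
#' @return Wide per-larva tibble (one row per larva and phase) with the
#'   [measure_puncta()] metrics plus `excluded` / `exclusion_reason`;
#'   convert with [as_results_table()] for serialization.
#' @export
process_well <- function(pre_stack, post_stack = NULL, platemap_row,
                         config = lc3_config()) {
  if (is.null(platemap_row) || !all(c("plate", "well") %in%
                                    names(platemap_row))) {
    abort("plate-map row with `plate` and `well` required",
          class = "lc3_validation_error")
  }
  pc <- config$puncta
  phases <- list(pre_nh4cl = pre_stack)
  if (!is.null(post_stack)) phases$post_nh4cl <- post_stack

  per_phase <- imap(phases, function(stack, phase) {
    proj <- max_project(stack)
    rois <- locate_larvae(proj, max_larvae = pc$max_larvae,
                          head_tail_offset = pc$head_tail_offset,
                          min_larva_area = pc$min_body_area,
                          median_size = pc$median_size,
                          smooth_sigma = pc$smooth_sigma)
    meas <- map(seq_len(nrow(rois)), function(i) {
      r <- rois[i, ]
      m <- pc$roi_margin
      y0 <- max(1, r$y0 - m); y1 <- min(nrow(proj), r$y1 + m)
      x0 <- max(1, r$x0 - m); x1 <- min(ncol(proj), r$x1 + m)
      crop <- proj[y0:y1, x0:x1]
      tryCatch({
        bm <- compute_body_mask(crop, pc$median_size, pc$smooth_sigma,
                                pc$body_threshold, pc$min_body_area,
                                pc$shrink_radius,
                                well = platemap_row$well)
        seg <- segment_puncta(crop, bm$smoothed, bm$mask,
                              pc$threshold_factor, pc$min_punctum_area,
                              pc$containment)
        measure_puncta(seg, stack$pixel_size_um)
      }, lc3_no_larva = function(e) NULL)
    })
    ok <- !map_lgl(meas, is.null)
    list(rois = rois[ok, , drop = FALSE], meas = meas[ok])
  })

  pair_and_emit(per_phase, platemap_row)
}

# Pair larvae across phases by nearest anchors and emit wide records,
# including displaced-excluded rows for unmatched larvae.
pair_and_emit <- function(per_phase, platemap_row) {
  na_metrics <- tibble(body_area_px2 = NA_real_, body_area_um2 = NA_real_,
                       puncta_count = NA_real_,
                       puncta_total_area_px2 = NA_real_,
                       puncta_total_area_um2 = NA_real_,
                       relative_puncta_area = NA_real_)
  emit <- function(larva, phase, metrics, excluded = FALSE, reason = NA) {
    dplyr::bind_cols(
      tibble(plate = platemap_row$plate, well = platemap_row$well,
             larva = larva, phase = phase),
      metrics,
      tibble(excluded = excluded, exclusion_reason = as.character(reason))
    )
  }
  pre <- per_phase$pre_nh4cl
  rows <- list()
  if (length(per_phase) == 1L) {
    for (i in seq_len(nrow(pre$rois))) {
      rows[[length(rows) + 1]] <- emit(i, "pre_nh4cl", pre$meas[[i]])
    }
    return(if (length(rows)) list_rbind(rows) else
      emit(integer(), character(), na_metrics[0, ]))
  }
  post <- per_phase$post_nh4cl
  n1 <- nrow(pre$rois); n2 <- nrow(post$rois)
  matched_pre <- integer(); matched_post <- integer()
  if (n1 > 0 && n2 > 0) {
    d <- outer(seq_len(n1), seq_len(n2), function(i, j) {
      sqrt((pre$rois$anchor_y[i] - post$rois$anchor_y[j])^2 +
           (pre$rois$anchor_x[i] - post$rois$anchor_x[j])^2)
    })
    while (length(matched_pre) < min(n1, n2)) {
      free_i <- setdiff(seq_len(n1), matched_pre)
      free_j <- setdiff(seq_len(n2), matched_post)
      sub <- d[free_i, free_j, drop = FALSE]
      best <- which(sub == min(sub), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      matched_pre <- c(matched_pre, free_i[best[1]])
      matched_post <- c(matched_post, free_j[best[2]])
    }
  }
  larva_idx <- 0L
  ord <- order(matched_pre)
  for (k in ord) {
    larva_idx <- larva_idx + 1L
    rows[[length(rows) + 1]] <-
      emit(larva_idx, "pre_nh4cl", pre$meas[[matched_pre[k]]])
    rows[[length(rows) + 1]] <-
      emit(larva_idx, "post_nh4cl", post$meas[[matched_post[k]]])
  }
  for (i in setdiff(seq_len(n1), matched_pre)) {
    larva_idx <- larva_idx + 1L
    rows[[length(rows) + 1]] <- emit(larva_idx, "pre_nh4cl", pre$meas[[i]])
    rows[[length(rows) + 1]] <-
      emit(larva_idx, "post_nh4cl", na_metrics, TRUE,
           "displaced: not detected in post_nh4cl acquisition")
  }
  for (j in setdiff(seq_len(n2), matched_post)) {
    larva_idx <- larva_idx + 1L
    rows[[length(rows) + 1]] <-
      emit(larva_idx, "pre_nh4cl", na_metrics, TRUE,
           "displaced: not detected in pre_nh4cl acquisition")
    rows[[length(rows) + 1]] <- emit(larva_idx, "post_nh4cl", post$meas[[j]])
  }
  if (length(rows) == 0) {
    return(emit(integer(), character(), na_metrics[0, ]))
  }
  list_rbind(rows)
}
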