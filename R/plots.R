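#' Plot the screen heatmap (compounds x doses, E_max-ordered)
#'
#' Fold change in the presence of NH4Cl, rows ordered by E_max rank; toxic
#' cells are drawn crossed out.
#'
#' @param profiles An `lc3_profiles` table from [build_dose_response()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(profiles) {
  m <- export_heatmap_matrix(profiles)
  tox <- attr(m, "toxic")
  df <- as_tibble(m, rownames = "compound") %>%
    tidyr::pivot_longer(-"compound", names_to = "dose", values_to = "fc")
  df$toxic <- as.vector(t(tox))
  df$compound <- factor(df$compound, levels = rev(rownames(m)))
  df$dose <- factor(df$dose, levels = colnames(m))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$compound,
                                        fill = .data$fc)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
                                  mid = "white", high = "firebrick",
                                  na.value = "white",
                                  name = "FC (+NH4Cl)") +
    ggplot2::geom_point(data = df[df$toxic, ], shape = 4, size = 3,
                        colour = "grey40") +
    ggplot2::labs(x = "dose", y = NULL) +
    ggplot2::theme_minimal()
  p
}

#' Plot an OCR trace with its injections and summary levels
#'
#' @param trace An `lc3_ocr_trace`.
#' @param summary Optional [ocr_summary()] row; basal / maximal /
#'   nonmitochondrial levels are drawn as dashed lines when given.
#' @return A ggplot object.
#' @export
plot_ocr_trace <- function(trace, summary = NULL) {
  inj <- attr(trace, "injections")
  p <- ggplot2::ggplot(as_tibble(trace),
                       ggplot2::aes(x = .data$time_min, y = .data$ocr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "OCR (pmol O2/min)") +
    ggplot2::theme_minimal()
  if (nrow(inj) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = inj$time_min,
                                 linetype = "dotted") +
      ggplot2::annotate("text", x = inj$time_min, y = max(trace$ocr),
                        label = inj$label, hjust = -0.1, size = 3)
  }
  if (!is.null(summary)) {
    lv <- c(basal = summary$basal, maximal = summary$maximal,
            nonmitochondrial = summary$nonmitochondrial)
    lv <- lv[is.finite(lv)]
    p <- p + ggplot2::geom_hline(yintercept = unname(lv),
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot a segmentation QC overlay
#'
#' Projection image with the body-mask outline and puncta filled in, the
#' standard per-larva quality-control view.
#'
#' @param seg An `lc3_segmentation`.
#' @return A ggplot object.
#' @export
plot_segmentation <- function(seg) {
  img <- seg$projection
  df <- tibble(
    y = rep(seq_len(nrow(img)), ncol(img)),
    x = rep(seq_len(ncol(img)), each = nrow(img)),
    intensity = as.vector(img),
    body = as.vector(seg$body_mask),
    punctum = as.vector(seg$puncta_mask)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_raster(data = df[df$punctum, ], fill = "red",
                         alpha = 0.8) +
    ggplot2::geom_contour(ggplot2::aes(z = as.numeric(.data$body)),
                          breaks = 0.5, colour = "cyan",
                          linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
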