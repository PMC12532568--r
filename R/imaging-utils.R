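# Thin wrappers around EBImage primitives, all operating on plain [y, x]
# matrices so the rest of the package never touches Image objects directly.

as_matrix <- function(x) {
  if (inherits(x, "lc3_stack")) {
    if (dim(x$pixels)[3] != 1L) {
      abort("expected a single-plane image; project or select a channel first",
            class = "lc3_usage_error")
    }
    return(x$pixels[, , 1])
  }
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 1L) return(x[, , 1])
  if (!is.matrix(x)) abort("expected a matrix image", class = "lc3_usage_error")
  x
}

#' Smooth an image by a median filter followed by a Gaussian blur
#'
#' The "serial operations" smoothing of the puncta pipeline: a small median
#' filter knocks out hot pixels, then a heavy Gaussian blur (sigma on the
#' order of the larva half-width) turns the image into a body-background
#' estimate that preserves no puncta.
#'
#' @param img Numeric matrix.
#' @param median_size Median window edge in px (odd; 1 disables).
#' @param sigma Gaussian blur sigma in px.
#' @return Smoothed matrix, same shape.
#' @export
smooth_image <- function(img, median_size = 3, sigma = 10) {
  img <- as_matrix(img)
  m <- max(img)
  if (m <= 0) m <- 1
  out <- img / m
  r <- floor(median_size / 2)
  if (r >= 1) {
    out <- EBImage::imageData(EBImage::medianFilter(out, r))
  }
  if (sigma > 0) {
    out <- EBImage::imageData(EBImage::gblur(out, sigma = sigma))
  }
  out * m
}

# Otsu threshold on an arbitrary-range image; scale-invariant because the
# image is normalized to [0, 1] before binning.
otsu_threshold <- function(img) {
  m <- max(img)
  if (m <= 0) return(Inf)
  EBImage::otsu(EBImage::Image(img / m), range = c(0, 1)) * m
}

# Connected-component labeling of a logical mask.
label_mask <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  storage.mode(lab) <- "integer"
  EBImage::imageData(lab)
}

# Binary erosion by a disc of the given radius.
erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1), brush)) > 0
}

# A global threshold on a blank (noise-only) image splits a unimodal
# distribution and invents foreground. Real bodies are several-fold
# brighter than background, so require the above/below-threshold mean
# ratio to clear a contrast floor before trusting the binarization.
has_contrast <- function(smoothed, thr, min_ratio = 1.5) {
  above <- smoothed > thr
  if (!any(above) || all(above)) return(FALSE)
  mean(smoothed[above]) >= min_ratio * max(mean(smoothed[!above]), 1e-9)
}

# Per-label pixel statistics of a label matrix: area, centroid, mean
# intensity over `img`.
label_stats <- function(labels, img = NULL) {
  n <- max(labels)
  if (n == 0) {
    return(tibble(label = integer(), area_px2 = numeric(),
                  centroid_y = numeric(), centroid_x = numeric(),
                  mean_intensity = numeric()))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  yy <- (idx - 1) %% nrow(labels) + 1
  xx <- (idx - 1) %/% nrow(labels) + 1
  area <- tabulate(lab, n)
  cy <- rowsum(as.numeric(yy), lab)[, 1] / area[sort(unique(lab))]
  cx <- rowsum(as.numeric(xx), lab)[, 1] / area[sort(unique(lab))]
  keep <- sort(unique(lab))
  mi <- if (is.null(img)) rep(NA_real_, length(keep)) else {
    rowsum(img[idx], lab)[, 1] / area[keep]
  }
  tibble(label = keep, area_px2 = as.numeric(area[keep]),
         centroid_y = as.numeric(cy), centroid_x = as.numeric(cx),
         mean_intensity = as.numeric(mi))
}
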