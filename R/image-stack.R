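#' Construct an image stack
#'
#' The raw acquisition unit: a single plane or a stack of planes, stored as
#' a `[y, x]` matrix or `[y, x, plane]` array. The third axis is either Z
#' (`planes = "z"`, a confocal stack, the screen acquires 26 Z planes per
#' area) or channel (`planes = "c"`, e.g. an RGB or two-fluorophore field).
#' Pixel coordinates are 1-based `(row, col) = (y, x)`.
#'
#' @param pixels Numeric matrix `[y, x]` or array `[y, x, plane]`, finite and
#'   non-negative.
#' @param planes `"z"` for a Z-stack (default) or `"c"` for channels.
#' @param channels Optional character vector of channel labels; length must
#'   match the plane count when `planes = "c"`.
#' @param pixel_size_um Physical edge length of one pixel in micrometres
#'   (> 0).
#' @param meta Named list of acquisition annotations (well id, magnification,
#'   phase, ...).
#' @return An object of class `lc3_stack`.
#' @export
#' @examples
#' s <- image_stack(array(runif(20 * 30 * 4), c(20, 30, 4)), pixel_size_um = 0.7)
#' dim(s$pixels)
image_stack <- function(pixels, planes = c("z", "c"), channels = NULL,
                        pixel_size_um = 1, meta = list()) {
  planes <- match.arg(planes)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (length(dim(pixels)) != 3L) {
    abort("`pixels` must be a [y, x] matrix or [y, x, plane] array",
          class = "lc3_validation_error")
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("pixel intensities must be finite and >= 0",
          class = "lc3_validation_error")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number",
          class = "lc3_validation_error")
  }
  if (planes == "c") {
    if (is.null(channels)) channels <- paste0("ch", seq_len(dim(pixels)[3]))
    if (length(channels) != dim(pixels)[3]) {
      abort("channel labels must match the plane count",
            class = "lc3_validation_error")
    }
  }
  structure(
    list(pixels = pixels, planes = planes, channels = channels,
         pixel_size_um = pixel_size_um, meta = meta),
    class = "lc3_stack"
  )
}

#' @export
print.lc3_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<lc3_stack> %d x %d px, %d %s plane(s), %.3g um/px\n",
              d[1], d[2], d[3], if (x$planes == "z") "Z" else "channel",
              x$pixel_size_um))
  invisible(x)
}

#' Number of planes in a stack
#' @param stack An `lc3_stack`.
#' @return Integer plane count.
#' @export
n_planes <- function(stack) dim(stack$pixels)[3]

#' Read a TIFF / OME-TIFF stack
#'
#' Multi-page TIFFs become Z-stacks; a single page with an interleaved
#' sample axis (e.g. RGB) becomes a channel stack. Integer data are read
#' losslessly (bit-exact values). Pixel size is taken from the TIFF
#' resolution tag when present (assumed pixels per micrometre or per cm as
#' tagged), otherwise from `pixel_size_um`; with neither, a configuration
#' error is raised.
#'
#' @param path TIFF file path.
#' @param pixel_size_um Fallback pixel size (um) when the file carries no
#'   resolution metadata.
#' @param channels Optional channel labels for interleaved-channel files.
#' @param meta Extra annotations stored on the stack.
#' @return An `lc3_stack`.
#' @export
read_stack <- function(path, pixel_size_um = NULL, channels = NULL,
                       meta = list()) {
  if (!file.exists(path)) {
    abort(paste0("cannot read TIFF: ", path), class = "lc3_io_error")
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) abort(paste0("unreadable TIFF: ", path, " (",
                                     conditionMessage(e), ")"),
                              class = "lc3_io_error")
  )
  px_um <- pixel_size_um
  info <- attributes(pages[[1]])
  if (is.null(px_um) && !is.null(info$x.resolution) && info$x.resolution > 0) {
    # resolution tag stored as pixels per unit; unit "cm" per baseline TIFF
    unit_um <- if (identical(info$resolution.unit, "inch")) 25400 else 10000
    px_um <- unit_um / info$x.resolution
  }
  if (is.null(px_um)) {
    abort(paste0("no pixel size in TIFF metadata and no fallback given: ",
                 path),
          class = "lc3_config_error")
  }
  first <- pages[[1]]
  if (length(dim(first)) == 3L) {
    # interleaved channels in a single page
    return(image_stack(first, planes = "c", channels = channels,
                       pixel_size_um = px_um, meta = meta))
  }
  arr <- array(0, c(dim(first), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  image_stack(arr, planes = "z", pixel_size_um = px_um, meta = meta)
}

#' Write an image stack to a multi-page 16-bit TIFF
#'
#' Integer intensities up to 65535 survive a write/read round trip
#' bit-exactly.
#'
#' @param stack An `lc3_stack` with intensities in `[0, 65535]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  px <- stack$pixels
  if (max(px) > 65535) {
    abort("intensities exceed 16-bit range", class = "lc3_validation_error")
  }
  planes <- lapply(seq_len(dim(px)[3]), function(i) px[, , i] / 65535)
  ok <- tryCatch(tiff::writeTIFF(planes, path, bits.per.sample = 16L),
                 error = function(e) abort(paste0("cannot write TIFF: ", path),
                                           class = "lc3_io_error"))
  invisible(path)
}

#' Construct a two-channel field
#'
#' Container for ratiometric quantifications: channel A is the
#' acid-resistant / potential-sensitive signal (mCherry, DsRed, TMRM, JC-10
#' monomer), channel B the reference (GFP, MitoTracker, JC-10 aggregate).
#'
#' @param a,b Numeric matrices of identical shape, finite and non-negative.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param roi Optional logical matrix (same shape) restricting analysis to a
#'   cell or region.
#' @param channels Length-2 character vector naming A and B.
#' @return An object of class `lc3_field`.
#' @export
two_channel_field <- function(a, b, pixel_size_um = 1, roi = NULL,
                              channels = c("mCherry", "GFP")) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b))) {
    abort("channels must be matrices of identical shape",
          class = "lc3_validation_error")
  }
  for (ch in list(a, b)) {
    if (anyNA(ch) || any(!is.finite(ch)) || any(ch < 0)) {
      abort("intensities must be finite and >= 0",
            class = "lc3_validation_error")
    }
  }
  if (!is.null(roi)) {
    stopifnot(is.logical(roi), all(dim(roi) == dim(a)))
  }
  structure(
    list(a = a, b = b, pixel_size_um = pixel_size_um, roi = roi,
         channels = channels),
    class = "lc3_field"
  )
}

#' @export
print.lc3_field <- function(x, ...) {
  cat(sprintf("<lc3_field> %d x %d px, channels %s/%s\n",
              nrow(x$a), ncol(x$a), x$channels[1], x$channels[2]))
  invisible(x)
}
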