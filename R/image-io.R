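#' Construct a fluorescence image
#'
#' Wraps a numeric matrix of fluorescence radiance values (rows = y, columns
#' = x) together with the bit depth of the source capture. Intensities are
#' kept on their native integer scale (0..2^bit_depth - 1): every downstream
#' quantity is a ratio or a difference of intensities, so the absolute scale
#' cancels in percent loss and rescaling would only lose precision.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities; at
#'   least 3 x 3.
#' @param bit_depth Integer, 8 or 16; bit depth of the source image.
#' @return An object of class `qlf_image` with fields `pixels`, `height`,
#'   `width` and `source_bit_depth`.
#' @export
fluorescence_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("image must be at least 3 x 3 pixels", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("all intensities must be finite", call. = FALSE)
  if (any(pixels < 0))
    stop("all intensities must be >= 0", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  structure(
    list(
      pixels = pixels,
      height = nrow(pixels),
      width = ncol(pixels),
      source_bit_depth = as.integer(bit_depth)
    ),
    class = "qlf_image"
  )
}

#' @export
print.qlf_image <- function(x, ...) {
  cat(sprintf(
    "<qlf_image> %d x %d px, %d-bit source, intensity range [%g, %g]\n",
    x$width, x$height, x$source_bit_depth,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Load a grayscale fluorescence image
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF and returns the stored
#' integer pixel values as real numbers on their native scale. Color
#' (multi-channel) images are rejected rather than silently converted:
#' any channel-mixing rule would alter fluorescence-loss values invisibly.
#'
#' @param path Path to a grayscale PNG or TIFF file.
#' @return A [fluorescence_image()] object.
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: file '%s' does not exist", path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    depth <- as.integer(info$bit.depth)
    if (length(dim(arr)) == 3L)
      stop(sprintf(
        "'%s' has %d channels; convert to single-channel grayscale first",
        path, dim(arr)[3L]), call. = FALSE)
    # readPNG scales to [0,1] by 2^depth - 1
    px <- round(unclass(arr) * (2^depth - 1))
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    depth <- as.integer(attr(arr, "bits.per.sample"))
    if (length(dim(arr)) == 3L)
      stop(sprintf(
        "'%s' has %d channels; convert to single-channel grayscale first",
        path, dim(arr)[3L]), call. = FALSE)
    px <- unclass(arr) + 0.0
  } else {
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  }
  if (!depth %in% c(8L, 16L))
    stop(sprintf("'%s' is %d-bit; only 8- and 16-bit images are supported",
                 path, depth), call. = FALSE)
  attributes(px) <- list(dim = dim(px))
  fluorescence_image(px, bit_depth = depth)
}

#' Write a fluorescence image to disk
#'
#' Writes the integer intensities losslessly at the source bit depth.
#' 16-bit images must go to TIFF (PNG output here is 8-bit only).
#'
#' @param image A [fluorescence_image()] object.
#' @param path Output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "qlf_image"))
  ext <- tolower(tools::file_ext(path))
  maxval <- 2^image$source_bit_depth - 1
  px <- pmin(pmax(round(image$pixels), 0), maxval)
  if (ext == "png") {
    if (image$source_bit_depth != 8L)
      stop("PNG output is 8-bit; write 16-bit images as TIFF", call. = FALSE)
    png::writePNG(px / maxval, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px / maxval, path,
                    bits.per.sample = image$source_bit_depth)
  } else {
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' The Fire look-up table
#'
#' The 256-entry "Fire" pseudocolor table (black through red and yellow to
#' white) as popularized by ImageJ, generated by linear interpolation of its
#' 32 published control points.
#'
#' @return A 256 x 3 integer matrix of RGB values in 0..255; row 1 is black,
#'   row 256 is white.
#' @export
fire_lut <- function() {
  r <- c(0, 0, 1, 25, 49, 73, 98, 122, 146, 162, 173, 184, 195, 207, 217,
         229, 240, 252, 255, 255, 255, 255, 255, 255, 255, 255, 255, 255,
         255, 255, 255, 255)
  g <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 14, 35, 57, 79, 101, 117,
         133, 147, 161, 175, 190, 205, 219, 234, 248, 255, 255, 255, 255)
  b <- c(0, 61, 96, 130, 165, 192, 220, 227, 210, 181, 151, 122, 93, 64,
         35, 5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 35, 98, 160, 223, 255, 255, 255)
  pos <- (0:255) * length(r) / 256
  i1 <- pmin(floor(pos), length(r) - 1)
  i2 <- pmin(i1 + 1, length(r) - 1)
  frac <- pos - i1
  interp <- function(v) as.integer(round(v[i1 + 1] + frac * (v[i2 + 1] - v[i1 + 1])))
  cbind(red = interp(r), green = interp(g), blue = interp(b))
}

#' Render a percent-loss map through the Fire LUT
#'
#' Clips percent-loss values to `[0, max_percent]`, maps them linearly to
#' LUT indices 0..255 and colors them with [fire_lut()]. Pixels outside the
#' ROI interior are rendered black. A vertical color-scale bar spanning the
#' full LUT is appended on the right.
#'
#' @param percent Numeric matrix of percent-loss values (finite where
#'   `mask` is `TRUE`).
#' @param max_percent Positive scale ceiling in percent.
#' @param mask Optional logical matrix; `FALSE` pixels render black.
#'   Defaults to all `TRUE`.
#' @param scale_bar Append the vertical color-scale bar? Default `TRUE`.
#' @return An `height x width x 3` numeric array with values in `[0, 1]`,
#'   suitable for [png::writePNG()]. The LUT index of each in-mask pixel is
#'   attached as attribute `"lut_index"`.
#' @export
render_fire_lut <- function(percent, max_percent, mask = NULL,
                            scale_bar = TRUE) {
  if (!is.numeric(max_percent) || length(max_percent) != 1L ||
      max_percent <= 0)
    stop("`max_percent` must be a single positive number", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(percent), ncol(percent))
  stopifnot(all(dim(mask) == dim(percent)))
  if (any(!is.finite(percent[mask])))
    stop("percent values inside the mask must be finite", call. = FALSE)

  lut <- fire_lut()
  clipped <- pmin(pmax(percent, 0), max_percent)
  idx <- matrix(as.integer(round(clipped / max_percent * 255)),
                nrow(percent), ncol(percent))
  idx[!mask] <- 0L

  h <- nrow(percent)
  rgb <- array(0, dim = c(h, ncol(percent), 3L))
  for (ch in 1:3) {
    plane <- matrix(lut[idx + 1L, ch] / 255, h, ncol(percent))
    plane[!mask] <- 0
    rgb[, , ch] <- plane
  }

  if (scale_bar) {
    # bar runs from LUT 255 (top) to 0 (bottom), one gap column + 8 bar cols
    bar_idx <- as.integer(round(seq(255, 0, length.out = h)))
    bar <- array(0, dim = c(h, 9L, 3L))
    for (ch in 1:3)
      bar[, 2:9, ch] <- matrix(lut[bar_idx + 1L, ch] / 255, h, 8L)
    out <- array(0, dim = c(h, ncol(percent) + 9L, 3L))
    out[, seq_len(ncol(percent)), ] <- rgb
    out[, ncol(percent) + 1:9, ] <- bar
    rgb <- out
  }
  attr(rgb, "lut_index") <- idx
  rgb
}
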