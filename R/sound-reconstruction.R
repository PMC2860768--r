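# Sound-enamel reconstruction by two-step two-dimensional linear
# interpolation. For an interior pixel M the scheme is:
#
#   step 1 (horizontal): L_m(x) = L_g + (L_h - L_g) * (X_m - X_g)/(X_h - X_g)
#     with g, h the border anchors left and right of M on its row;
#   step 2 (vertical residual correction): at the column anchors e (above)
#     and f (below), the same horizontal rule gives interpolated values
#     L_e(i), L_f(i); the residuals dL_e = L_e - L_e(i), dL_f = L_f - L_f(i)
#     are interpolated vertically,
#       L_m(y) = dL_e + (dL_f - dL_e) * (Y_m - Y_e)/(Y_f - Y_e),
#     and the reconstructed sound value is L_m(i) = L_m(x) + L_m(y).
#
# The scheme reproduces any field affine in (x, y) exactly: step 1 is exact
# along rows, and on an affine field both residuals vanish so step 2 adds
# nothing. Fluorescence loss at M is dL_m = L_m(i) - L_m (observed), and
# percent loss is 100 * dL_m / L_m(i).

.new_lossmap <- function(observed, sound, interior_mask, bit_depth = 8L) {
  delta <- sound - observed
  delta[!interior_mask] <- NA_real_
  sound[!interior_mask] <- NA_real_
  valid <- interior_mask & !is.na(sound) & sound > 0
  percent <- matrix(NA_real_, nrow(sound), ncol(sound))
  percent[valid] <- 100 * delta[valid] / sound[valid]
  structure(
    list(
      sound = sound, delta = delta, percent = percent,
      valid_mask = valid, interior_mask = interior_mask,
      observed = observed, bit_depth = as.integer(bit_depth)
    ),
    class = "qlf_lossmap"
  )
}

#' @export
print.qlf_lossmap <- function(x, ...) {
  p <- x$percent[x$valid_mask]
  cat(sprintf(
    "<qlf_lossmap> %d interior px (%d valid); percent loss range [%.2f, %.2f]\n",
    sum(x$interior_mask), sum(x$valid_mask),
    if (length(p)) min(p) else NA, if (length(p)) max(p) else NA))
  invisible(x)
}

#' Reconstruct sound fluorescence inside an axis-aligned rectangle
#'
#' The reference form of the two-step two-dimensional linear interpolation:
#' the analysis region is the rectangle with corners `(x0, y0)` and
#' `(x1, y1)`, whose four edges are assumed to lie on sound tissue. Row
#' anchors are the raw (unsmoothed) intensities on the left and right
#' edges; the step-2 horizontal interpolations along the top and bottom
#' edges run between the rectangle's corners. This form uses raw edge
#' intensities throughout and serves as the faithful reference of the
#' original algorithm; [interpolate_polygon()] is the noise-hardened
#' generalization.
#'
#' @param image A [fluorescence_image()] object.
#' @param x0,y0,x1,y1 Integer pixel coordinates (0-based) of two opposite
#'   rectangle corners; each side must span at least 3 pixels.
#' @return A `qlf_lossmap` with matrices `sound` (reconstructed intensity),
#'   `delta` (`sound - observed`) and `percent` (`100 * delta / sound`),
#'   defined on the rectangle's interior and `NA` elsewhere; `valid_mask`
#'   flags interior pixels with a positive reconstruction.
#' @export
interpolate_rectangle <- function(image, x0, y0, x1, y1) {
  stopifnot(inherits(image, "qlf_image"))
  if (x0 > x1) { tmp <- x0; x0 <- x1; x1 <- tmp }
  if (y0 > y1) { tmp <- y0; y0 <- y1; y1 <- tmp }
  if (x1 - x0 < 2 || y1 - y0 < 2)
    stop("degenerate rectangle: each side must span at least 3 pixels",
         call. = FALSE)
  if (x0 < 0 || y0 < 0 || x1 > image$width - 1 || y1 > image$height - 1)
    stop("rectangle exceeds image bounds", call. = FALSE)

  px <- image$pixels
  xs <- (x0 + 1L):(x1 - 1L)              # interior columns, 0-based
  ys <- (y0 + 1L):(y1 - 1L)              # interior rows
  fx <- (xs - x0) / (x1 - x0)
  fy <- (ys - y0) / (y1 - y0)

  # step 1: horizontal interpolation between the left and right edges
  l_g <- px[ys + 1L, x0 + 1L]            # left edge, per interior row
  l_h <- px[ys + 1L, x1 + 1L]            # right edge
  l_mx <- outer(l_g, rep(1, length(xs))) +
    outer(l_h - l_g, fx)

  # step 2: residuals at the top and bottom edges, interpolated between
  # the rectangle corners, then blended vertically
  top_lo <- px[y0 + 1L, x0 + 1L]; top_hi <- px[y0 + 1L, x1 + 1L]
  bot_lo <- px[y1 + 1L, x0 + 1L]; bot_hi <- px[y1 + 1L, x1 + 1L]
  d_e <- px[y0 + 1L, xs + 1L] - (top_lo + (top_hi - top_lo) * fx)
  d_f <- px[y1 + 1L, xs + 1L] - (bot_lo + (bot_hi - bot_lo) * fx)
  l_my <- outer(1 - fy, d_e) + outer(fy, d_f)

  sound <- matrix(NA_real_, image$height, image$width)
  sound[ys + 1L, xs + 1L] <- l_mx + l_my
  interior <- matrix(FALSE, image$height, image$width)
  interior[ys + 1L, xs + 1L] <- TRUE
  .new_lossmap(px, sound, interior, image$source_bit_depth)
}

#' Reconstruct sound fluorescence inside a polygon ROI
#'
#' The polygon generalization of [interpolate_rectangle()], hardened
#' against border noise: anchors carry 3 x 3-smoothed border intensities
#' (see [smoothed_border_values()]), each interior pixel uses the nearest
#' border pixels bounding its own row and column spans, and the step-2
#' horizontal interpolations at the column anchors e and f run between the
#' endpoints of the contiguous border run containing each anchor on its
#' row. For an axis-aligned rectangular polygon those run endpoints are
#' the rectangle's corners, so the scheme degenerates exactly to the
#' reference rectangle algorithm (up to border smoothing).
#'
#' @param image A [fluorescence_image()] object.
#' @param raster A [rasterize()]d ROI of the same shape.
#' @param border_values Optional matrix of smoothed border intensities as
#'   returned by [smoothed_border_values()]; computed from `image` when
#'   omitted.
#' @return A `qlf_lossmap`; see [interpolate_rectangle()].
#' @export
interpolate_polygon <- function(image, raster, border_values = NULL) {
  stopifnot(inherits(image, "qlf_image"), inherits(raster, "qlf_raster"))
  if (image$height != raster$height || image$width != raster$width)
    stop("image and rasterized ROI have different shapes", call. = FALSE)
  if (is.null(border_values))
    border_values <- smoothed_border_values(image, raster)
  stopifnot(all(dim(border_values) == dim(image$pixels)))

  bv <- border_values
  idx <- which(raster$interior_mask)               # column-major linear
  yy <- ((idx - 1L) %% raster$height)              # 0-based row (y)
  xx <- ((idx - 1L) %/% raster$height)             # 0-based column (x)

  gx <- raster$anchor_left[idx]
  hx <- raster$anchor_right[idx]
  ey <- raster$anchor_top[idx]
  fy <- raster$anchor_bottom[idx]
  if (anyNA(gx) || anyNA(hx) || anyNA(ey) || anyNA(fy))
    stop("rasterized ROI is inconsistent: interior pixel without four anchors",
         call. = FALSE)

  at <- function(y, x) bv[cbind(y + 1L, x + 1L)]

  # step 1 on the pixel's own row
  l_g <- at(yy, gx); l_h <- at(yy, hx)
  l_mx <- l_g + (l_h - l_g) * (xx - gx) / (hx - gx)

  # horizontal interpolation along a border row between the endpoints of
  # the contiguous border run containing column x
  run_interp <- function(y, x) {
    rl <- raster$run_left[cbind(y + 1L, x + 1L)]
    rr <- raster$run_right[cbind(y + 1L, x + 1L)]
    v_l <- at(y, rl); v_r <- at(y, rr)
    out <- v_l
    wide <- rr > rl
    out[wide] <- v_l[wide] +
      (v_r[wide] - v_l[wide]) * (x[wide] - rl[wide]) / (rr[wide] - rl[wide])
    out
  }

  d_e <- at(ey, xx) - run_interp(ey, xx)
  d_f <- at(fy, xx) - run_interp(fy, xx)
  l_my <- d_e + (d_f - d_e) * (yy - ey) / (fy - ey)

  sound <- matrix(NA_real_, image$height, image$width)
  sound[idx] <- l_mx + l_my
  .new_lossmap(image$pixels, sound, raster$interior_mask,
               image$source_bit_depth)
}

#' Export a loss map as a table of interior pixel records
#'
#' @param loss A `qlf_lossmap`.
#' @return A data frame with one row per interior pixel: `x`, `y` (0-based
#'   pixel coordinates), `observed`, `sound`, `delta` (intensity units) and
#'   `percent` (percent loss; `NA` where the reconstruction is not
#'   positive).
#' @export
lossmap_as_table <- function(loss) {
  stopifnot(inherits(loss, "qlf_lossmap"))
  idx <- which(loss$interior_mask)
  h <- nrow(loss$sound)
  data.frame(
    x = (idx - 1L) %/% h,
    y = (idx - 1L) %% h,
    observed = loss$observed[idx],
    sound = loss$sound[idx],
    delta = loss$delta[idx],
    percent = loss$percent[idx]
  )
}

#' Write a loss map as a 3-layer 32-bit float TIFF
#'
#' Layers are, in order, the reconstructed sound intensity, the absolute
#' loss and the percent loss. TIFF samples live in `[0, 1]`, so each layer
#' is stored under a fixed affine mapping (with `V = 2^bit_depth - 1` the
#' intensity ceiling): sound as `sound / V`, delta as
#' `(delta + V) / (2 V)`, percent as `(percent + 100) / 200`, clipped to
#' the representable range. [read_lossmap_tiff()] inverts the mapping.
#' Pixels outside the ROI interior are stored as `NA`-equivalent zeros in
#' the forward map. The CSV export ([lossmap_as_table()]) is the lossless
#' record.
#'
#' @param loss A `qlf_lossmap`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_lossmap_tiff <- function(loss, path) {
  stopifnot(inherits(loss, "qlf_lossmap"))
  v <- 2^loss$bit_depth - 1
  clip01 <- function(m) { m[is.na(m)] <- 0; pmin(pmax(m, 0), 1) }
  tiff::writeTIFF(
    list(clip01(loss$sound / v),
         clip01((loss$delta + v) / (2 * v)),
         clip01((loss$percent + 100) / 200)),
    path, bits.per.sample = 32, reduce = FALSE
  )
  invisible(path)
}

#' Read back a 3-layer loss-map TIFF
#'
#' Inverts the affine layer mapping documented in [write_lossmap_tiff()].
#'
#' @param path Path to a TIFF written by [write_lossmap_tiff()].
#' @param bit_depth Bit depth the map was written with (8 or 16).
#' @return A list with matrices `sound`, `delta` and `percent`.
#' @export
read_lossmap_tiff <- function(path, bit_depth = 8L) {
  v <- 2^bit_depth - 1
  layers <- tiff::readTIFF(path, all = TRUE)
  list(sound = layers[[1]] * v,
       delta = layers[[2]] * 2 * v - v,
       percent = layers[[3]] * 200 - 100)
}
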