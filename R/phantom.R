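# Synthetic QLF tooth phantoms: a smooth sound-fluorescence field with an
# embedded lesion of known percent-loss profile, optional Gaussian sensor
# noise and injected single-pixel hot/cold spots. The lesion is
# multiplicative — image = sound * (1 - loss/100) — so the ground-truth
# percent-loss grid is exact by construction even on curved fields.

#' Specify a synthetic QLF phantom
#'
#' @param height,width Image dimensions in pixels; default 80 x 80.
#' @param sound_field A list describing the sound-enamel fluorescence
#'   field:
#'   \describe{
#'     \item{`list(type = "constant", value)`}{flat field.}
#'     \item{`list(type = "affine", a, bx, by)`}{`a + bx*x + by*y` — a
#'       tilted plane, the regime in which the interpolation scheme is
#'       exact.}
#'     \item{`list(type = "curved", base, curvature)`}{a quadratic dome,
#'       `base * (1 - curvature * d2/d2max)` with `d2` the squared distance
#'       from the image center — the simplest stand-in for natural tooth
#'       surface curvature, which stresses the linear-interpolation bias.}
#'   }
#'   Default: an affine field `180 + 0.3*x + 0.2*y`, emulating the gentle
#'   illumination/curvature gradient of a bright 8-bit enamel capture.
#' @param lesion A list with `center` (`c(x, y)`, pixels), `radii`
#'   (`c(rx, ry)`, pixels) and `peak_percent` (peak percent loss, in
#'   (0, 100)). The radial profile is a cosine taper:
#'   `peak * 0.5 * (1 + cos(pi * rho))` for normalized elliptical radius
#'   `rho <= 1`, zero outside — smooth, compactly supported, with an
#'   unambiguous maximum. Default: centered, radii 16 x 13, peak 25%.
#' @param noise_sd Additive Gaussian sensor noise, standard deviation in
#'   intensity units; default 0.
#' @param spikes Optional data frame / matrix with columns `x`, `y`,
#'   `magnitude` (intensity units) and `sign` (+1 hot spot, -1 cold spot)
#'   of single-pixel defects.
#' @param bit_depth Bit depth of the emulated capture (8 or 16); intensities
#'   are clipped to the valid range and rounded to integers like a real
#'   sensor readout.
#' @param seed Optional random seed; generation is deterministic given the
#'   seed and leaves the caller's RNG stream untouched.
#' @return An object of class `qlf_phantom_spec`.
#' @export
phantom_spec <- function(height = 80L, width = 80L,
                         sound_field = list(type = "affine",
                                            a = 180, bx = 0.3, by = 0.2),
                         lesion = list(center = c(x = (width - 1) / 2,
                                                  y = (height - 1) / 2),
                                       radii = c(rx = 16, ry = 13),
                                       peak_percent = 25),
                         noise_sd = 0, spikes = NULL,
                         bit_depth = 8L, seed = NULL) {
  stopifnot(height >= 16L, width >= 16L)
  if (!sound_field$type %in% c("constant", "affine", "curved"))
    stop("unknown sound_field type '", sound_field$type, "'", call. = FALSE)
  pk <- lesion$peak_percent
  if (!is.numeric(pk) || pk <= 0 || pk >= 100)
    stop("lesion peak_percent must be in (0, 100)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  cx <- lesion$center[[1]]; cy <- lesion$center[[2]]
  rx <- lesion$radii[[1]]; ry <- lesion$radii[[2]]
  # lesion must sit strictly inside the image with a sound margin wide
  # enough to place a valid ROI (its border plus smoothing reach) on sound
  # tissue
  margin <- 3
  if (cx - rx < margin || cx + rx > width - 1 - margin ||
      cy - ry < margin || cy + ry > height - 1 - margin)
    stop("lesion does not fit inside the image with a ", margin,
         "-pixel sound margin", call. = FALSE)
  if (!is.null(spikes)) {
    spikes <- as.data.frame(spikes)
    stopifnot(all(c("x", "y", "magnitude", "sign") %in% names(spikes)))
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         sound_field = sound_field,
         lesion = list(center = c(x = cx, y = cy), radii = c(rx = rx, ry = ry),
                       peak_percent = pk),
         noise_sd = noise_sd, spikes = spikes,
         bit_depth = as.integer(bit_depth), seed = seed),
    class = "qlf_phantom_spec"
  )
}

.sound_field_grid <- function(sf, height, width) {
  x <- matrix(rep(0:(width - 1L), each = height), height, width)
  y <- matrix(rep(0:(height - 1L), times = width), height, width)
  switch(sf$type,
    constant = matrix(sf$value, height, width),
    affine = sf$a + sf$bx * x + sf$by * y,
    curved = {
      cx <- (width - 1) / 2; cy <- (height - 1) / 2
      d2 <- (x - cx)^2 + (y - cy)^2
      sf$base * (1 - sf$curvature * d2 / max(d2))
    }
  )
}

#' Generate a synthetic QLF phantom
#'
#' Builds the phantom image `sound * (1 - loss/100) + noise + spikes`,
#' clipped to the valid intensity range and rounded to integer sensor
#' counts, together with the exact ground-truth percent-loss grid and a
#' suggested octagonal ROI whose edges lie on sound tissue around the
#' lesion.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (a [fluorescence_image()]),
#'   `truth_percent` (matrix of true percent loss), `roi` (a suggested
#'   [polygon_roi()]), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "qlf_phantom_spec"))
  h <- spec$height; w <- spec$width
  sound <- .sound_field_grid(spec$sound_field, h, w)

  x <- matrix(rep(0:(w - 1L), each = h), h, w)
  y <- matrix(rep(0:(h - 1L), times = w), h, w)
  cx <- spec$lesion$center[["x"]]; cy <- spec$lesion$center[["y"]]
  rx <- spec$lesion$radii[["rx"]]; ry <- spec$lesion$radii[["ry"]]
  rho <- sqrt(((x - cx) / rx)^2 + ((y - cy) / ry)^2)
  truth <- ifelse(rho <= 1,
                  spec$lesion$peak_percent * 0.5 * (1 + cos(pi * rho)), 0)

  img <- sound * (1 - truth / 100)
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
  }
  if (!is.null(spec$spikes)) {
    sp <- spec$spikes
    for (i in seq_len(nrow(sp)))
      img[sp$y[i] + 1L, sp$x[i] + 1L] <-
        img[sp$y[i] + 1L, sp$x[i] + 1L] + sp$sign[i] * sp$magnitude[i]
  }
  maxval <- 2^spec$bit_depth - 1
  img <- pmin(pmax(round(img), 0), maxval)

  list(
    image = fluorescence_image(img, bit_depth = spec$bit_depth),
    truth_percent = truth,
    roi = suggest_octagon_roi(spec),
    spec = spec
  )
}

#' Suggested octagonal ROI enclosing a phantom's lesion
#'
#' A regular octagon centered on the lesion whose inradius clears the
#' lesion support by at least 2 pixels (so every edge lies on sound
#' tissue) and whose vertices stay at least 1 pixel inside the image (so
#' 3 x 3 border smoothing windows are complete).
#'
#' @param spec A [phantom_spec()].
#' @return A [polygon_roi()].
#' @export
suggest_octagon_roi <- function(spec) {
  stopifnot(inherits(spec, "qlf_phantom_spec"))
  cx <- spec$lesion$center[["x"]]; cy <- spec$lesion$center[["y"]]
  rmax <- max(spec$lesion$radii)
  # circumradius: inradius = R * cos(pi/8) must exceed rmax + 2
  r_need <- (rmax + 2) / cos(pi / 8)
  r_fit <- min(cx - 1, spec$width - 2 - cx, cy - 1, spec$height - 2 - cy)
  r <- min(r_need + 1.5, r_fit)
  if (r < r_need)
    stop("image too small to place an octagonal ROI on sound tissue",
         call. = FALSE)
  ang <- pi / 8 + (0:7) * pi / 4
  polygon_roi(cbind(x = round(cx + r * cos(ang), 2),
                    y = round(cy + r * sin(ang), 2)))
}
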