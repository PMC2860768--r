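#' Analyze a QLF image end to end
#'
#' Runs the full lesion-analysis pipeline: load the image, rasterize the
#' polygon ROI, smooth the border intensities, reconstruct the sound
#' fluorescence field by two-step two-dimensional linear interpolation,
#' extract the robust maximum percent loss, and convert it to an estimated
#' demineralization depth through the calibration line. Optionally writes
#' the result bundle (metrics JSON, Fire-LUT rendering, loss-map CSV and
#' TIFF) to an output directory.
#'
#' @param image A [fluorescence_image()] or a path to a grayscale PNG/TIFF.
#' @param roi A [polygon_roi()], a path to a ROI JSON sidecar, or an n x 2
#'   vertex matrix.
#' @param rel_tolerance Cold-spot rejection threshold; see
#'   [robust_max_loss()].
#' @param area_threshold Lesion-area percent cutoff; see
#'   [robust_max_loss()].
#' @param max_percent Scale ceiling for the Fire-LUT rendering (%);
#'   default 30.
#' @param calibration A `qlf_calibration`, a path to a calibration CSV
#'   (columns `depth_um`, `loss_percent`), or `NULL` for the packaged
#'   pairs.
#' @param level Confidence level for the depth interval.
#' @param out_dir Optional output directory for the artifact bundle.
#' @param image_id Identifier used in exported tables; defaults to the
#'   image file name or `"image"`.
#' @return A list of class `qlf_analysis`: `metrics` (see
#'   [robust_max_loss()]), `depth` (see [estimate_depth()]), `loss` (the
#'   `qlf_lossmap`), `raster`, `calibration` and `params`.
#' @export
analyze <- function(image, roi, rel_tolerance = 0.2, area_threshold = 5,
                    max_percent = 30, calibration = NULL, level = 0.95,
                    out_dir = NULL, image_id = NULL) {
  if (is.character(image)) {
    if (is.null(image_id))
      image_id <- tools::file_path_sans_ext(basename(image))
    image <- load_image(image)
  }
  if (is.null(image_id)) image_id <- "image"
  if (is.character(roi)) roi <- read_roi_json(roi)
  if (!inherits(roi, "qlf_roi")) roi <- polygon_roi(roi)
  if (is.null(calibration)) calibration <- fit_calibration(calibration_pairs())
  if (is.character(calibration))
    calibration <- fit_calibration(calibration_pairs(calibration))

  raster <- rasterize(roi, image$height, image$width)
  border_vals <- smoothed_border_values(image, raster)
  loss <- interpolate_polygon(image, raster, border_vals)
  metrics <- robust_max_loss(loss, rel_tolerance = rel_tolerance,
                             area_threshold = area_threshold)
  depth <- estimate_depth(calibration, max(metrics$max_percent_loss, 0),
                          level = level)

  result <- structure(
    list(
      metrics = metrics, depth = depth, loss = loss, raster = raster,
      calibration = calibration,
      params = list(image_id = image_id, rel_tolerance = rel_tolerance,
                    area_threshold = area_threshold,
                    max_percent = max_percent, level = level)
    ),
    class = "qlf_analysis"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(analysis_as_list(result),
                         file.path(out_dir, paste0(image_id, "_metrics.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rgb <- render_fire_lut(loss$percent, max_percent, mask = loss$valid_mask)
    png::writePNG(rgb, file.path(out_dir, paste0(image_id, "_fire.png")))
    utils::write.csv(lossmap_as_table(loss),
                     file.path(out_dir, paste0(image_id, "_lossmap.csv")),
                     row.names = FALSE)
    write_lossmap_tiff(loss, file.path(out_dir,
                                       paste0(image_id, "_lossmap.tif")))
  }
  result
}

#' Flatten an analysis result for JSON export
#'
#' Field names carry units (`percent`, `um`): the calibration mixes percent
#' loss and micrometers and silent unit confusion is the main user hazard.
#'
#' @param result A `qlf_analysis` from [analyze()].
#' @return A nested plain list.
#' @export
analysis_as_list <- function(result) {
  stopifnot(inherits(result, "qlf_analysis"))
  m <- result$metrics
  d <- result$depth
  cal <- result$calibration
  list(
    image_id = result$params$image_id,
    max_loss_percent = m$max_percent_loss,
    max_location = list(x = m$max_location[["x"]], y = m$max_location[["y"]]),
    raw_max_percent = m$raw_max_percent,
    cold_spots_rejected = m$cold_spots_rejected,
    lesion_area_px = m$lesion_area_px,
    mean_loss_percent = m$mean_percent_loss,
    estimated_depth_um = d$depth_um,
    depth_interval_um = list(lower = d$lower_um, upper = d$upper_um,
                             level = d$level),
    calibration = list(slope_percent_per_um = cal$slope,
                       intercept_percent = cal$intercept,
                       r = cal$r, n = cal$n),
    params = list(rel_tolerance = result$params$rel_tolerance,
                  area_threshold_percent = result$params$area_threshold,
                  lut_max_percent = result$params$max_percent)
  )
}

#' @export
print.qlf_analysis <- function(x, ...) {
  print(x$metrics)
  cat(sprintf(
    "  estimated depth : %.1f um (%.0f%% interval %.1f - %.1f um)\n",
    x$depth$depth_um, 100 * x$depth$level, x$depth$lower_um,
    x$depth$upper_um))
  invisible(x)
}
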