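#' Robust maximum fluorescence loss and lesion summary metrics
#'
#' A single-pixel maximum of the percent-loss map is fragile: one cold spot
#' (a spuriously dark pixel from sensor noise) can dominate it. This
#' estimator therefore ranks interior pixels by descending percent loss
#' (ties broken by smaller row-major pixel index) and walks down the list:
#' for each candidate it computes the mean percent loss over the 3 x 3
#' neighborhood (clipped to valid interior pixels). A candidate standing
#' more than `rel_tolerance` (as a fraction of its own value) above its
#' neighborhood mean is rejected as a cold spot and the next-ranked pixel
#' is examined; a rejected pixel is also excluded from all subsequent
#' neighborhood means, so one bad sensor count cannot leak into the value
#' reported for its neighbors. The first candidate consistent with its
#' neighborhood is accepted, and its neighborhood mean is reported as the
#' maximum loss. If
#' every candidate is rejected the last one's neighborhood mean is used
#' with a warning. A genuine smooth lesion maximum sits only a few percent
#' above its neighborhood mean, so it always passes at the default
#' tolerance.
#'
#' @param loss A `qlf_lossmap` from [interpolate_polygon()] or
#'   [interpolate_rectangle()].
#' @param rel_tolerance Cold-spot rejection threshold as a fraction of the
#'   candidate value, in (0, 1); default 0.20.
#' @param area_threshold Percent-loss cutoff defining lesion pixels;
#'   default 5 (%).
#' @return An object of class `qlf_metrics`:
#'   \describe{
#'     \item{max_percent_loss}{the robust maximum percent loss (a 3 x 3
#'       neighborhood mean, hence never above `raw_max_percent`).}
#'     \item{max_location}{`c(x, y)` of the accepted candidate (0-based).}
#'     \item{raw_max_percent}{single-pixel maximum before the robustness
#'       correction.}
#'     \item{cold_spots_rejected}{number of candidates discarded.}
#'     \item{lesion_area_px}{count of valid pixels at or above
#'       `area_threshold`.}
#'     \item{mean_percent_loss}{mean percent loss over those lesion
#'       pixels (`NA` if none).}
#'   }
#' @export
robust_max_loss <- function(loss, rel_tolerance = 0.2, area_threshold = 5) {
  stopifnot(inherits(loss, "qlf_lossmap"))
  if (!is.numeric(rel_tolerance) || length(rel_tolerance) != 1L ||
      rel_tolerance <= 0 || rel_tolerance >= 1)
    stop("`rel_tolerance` must be a single number in (0, 1)", call. = FALSE)
  if (!any(loss$valid_mask))
    stop("loss map has no valid interior pixels; nothing to measure",
         call. = FALSE)

  h <- nrow(loss$percent); w <- ncol(loss$percent)
  mask <- loss$valid_mask
  nb_mean <- box_mean3(loss$percent, mask = mask)

  idx <- which(loss$valid_mask)                 # column-major linear indices
  xx <- (idx - 1L) %/% h                        # 0-based x
  yy <- (idx - 1L) %% h                         # 0-based y
  p <- loss$percent[idx]
  row_major <- yy * w + xx
  ord <- order(-p, row_major)

  accepted <- NA_integer_
  rejected <- 0L
  exhausted <- FALSE
  for (k in ord) {
    cand <- p[k]
    nb <- nb_mean[idx[k]]
    # a non-positive candidate cannot be a cold spot above its surroundings
    if (cand <= 0 || (cand - nb) / cand <= rel_tolerance) {
      accepted <- k
      break
    }
    rejected <- rejected + 1L
    # drop the cold spot from later neighborhood means
    mask[idx[k]] <- FALSE
    if (any(mask)) nb_mean <- box_mean3(loss$percent, mask = mask)
  }
  if (is.na(accepted)) {
    exhausted <- TRUE
    accepted <- ord[length(ord)]
    rejected <- rejected - 1L                   # last candidate is used, not rejected
    mask[idx[accepted]] <- TRUE
    nb_mean <- box_mean3(loss$percent, mask = mask)
    warning("all candidate maxima were flagged as cold spots; ",
            "reporting the last candidate's neighborhood mean",
            call. = FALSE)
  }

  lesion_px <- p >= area_threshold
  structure(
    list(
      max_percent_loss = unname(nb_mean[idx[accepted]]),
      max_location = c(x = xx[accepted], y = yy[accepted]),
      raw_max_percent = unname(p[ord[1L]]),
      cold_spots_rejected = rejected,
      lesion_area_px = sum(lesion_px),
      mean_percent_loss = if (any(lesion_px)) mean(p[lesion_px]) else NA_real_,
      rel_tolerance = rel_tolerance,
      area_threshold = area_threshold,
      exhausted = exhausted
    ),
    class = "qlf_metrics"
  )
}

#' @export
print.qlf_metrics <- function(x, ...) {
  cat("Lesion metrics (robust maximum fluorescence loss)\n")
  cat(sprintf("  max percent loss : %.2f %% (3x3 mean at x=%d, y=%d)\n",
              x$max_percent_loss, x$max_location[["x"]], x$max_location[["y"]]))
  cat(sprintf("  raw single-pixel max : %.2f %%\n", x$raw_max_percent))
  cat(sprintf("  cold spots rejected  : %d\n", x$cold_spots_rejected))
  cat(sprintf("  lesion area (>= %g %%) : %d px\n",
              x$area_threshold, x$lesion_area_px))
  if (!is.na(x$mean_percent_loss))
    cat(sprintf("  mean loss over lesion : %.2f %%\n", x$mean_percent_loss))
  invisible(x)
}

#' Export lesion metrics as a one-row data frame
#'
#' @param metrics A `qlf_metrics` object.
#' @param image_id Optional identifier recorded in the first column.
#' @return A one-row data frame with unit-suffixed columns.
#' @export
metrics_as_table <- function(metrics, image_id = NA_character_) {
  stopifnot(inherits(metrics, "qlf_metrics"))
  data.frame(
    image_id = image_id,
    max_loss_percent = metrics$max_percent_loss,
    max_x = metrics$max_location[["x"]],
    max_y = metrics$max_location[["y"]],
    raw_max_percent = metrics$raw_max_percent,
    cold_spots_rejected = metrics$cold_spots_rejected,
    lesion_area_px = metrics$lesion_area_px,
    mean_loss_percent = metrics$mean_percent_loss
  )
}
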