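#' Packaged depth-calibration measurements
#'
#' Six paired observations from demineralized enamel specimens: the largest
#' histological caries depth measured on polarized-light micrographs of
#' tooth sections (µm) and the maximum percent fluorescence loss measured
#' on the corresponding QLF image. These pairs are the packaged default
#' calibration set for [fit_calibration()].
#'
#' @param path Optional path to an alternative CSV with columns `depth_um`
#'   and `loss_percent`; defaults to the packaged fixture.
#' @return A data frame with columns `depth_um` and `loss_percent`.
#' @export
calibration_pairs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "calibration_pairs.csv",
                        package = "qlfquant", mustWork = TRUE)
  if (!file.exists(path))
    stop(sprintf("calibration file '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("depth_um", "loss_percent") %in% names(df)))
    stop("calibration CSV must have columns 'depth_um' and 'loss_percent'",
         call. = FALSE)
  df
}

#' Fit the depth-to-fluorescence-loss calibration line
#'
#' Ordinary least squares of percent fluorescence loss (response, %) on
#' demineralization depth (predictor, µm), with the full inference set for
#' a simple linear regression: Pearson correlation, the two-tailed t test
#' for the slope (n - 2 df), the model F test (1, n - 2 df) and their
#' p-values. For a single predictor F equals t² so the two tests share one
#' p-value.
#'
#' @param depth Numeric vector of depths (µm), or a data frame with
#'   columns `depth_um` and `loss_percent` (as from [calibration_pairs()]).
#' @param loss Numeric vector of percent fluorescence losses; ignored when
#'   `depth` is a data frame.
#' @return An object of class `qlf_calibration` with fields `slope`
#'   (% per µm), `intercept` (%), `r`, `t_slope`, `F`, `p_t`, `p_F`,
#'   `residual_se`, `n`, `df`, plus the centroid and depth sum of squares
#'   used for inverse prediction.
#' @export
fit_calibration <- function(depth, loss = NULL) {
  if (is.data.frame(depth)) {
    loss <- depth$loss_percent
    depth <- depth$depth_um
  }
  if (length(depth) != length(loss))
    stop("`depth` and `loss` must have equal length", call. = FALSE)
  n <- length(depth)
  if (n < 3L)
    stop("calibration needs at least 3 paired observations", call. = FALSE)
  if (anyNA(depth) || anyNA(loss) || any(!is.finite(c(depth, loss))))
    stop("calibration values must be finite", call. = FALSE)
  if (any(depth <= 0) || any(loss <= 0))
    stop("calibration values must be positive", call. = FALSE)
  if (stats::var(depth) == 0)
    stop("degenerate design: all depths are equal", call. = FALSE)

  fit <- stats::lm(loss ~ depth)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  t_slope <- unname(sm$coefficients["depth", "t value"])
  df <- n - 2L
  f_stat <- t_slope^2
  p_t <- 2 * stats::pt(abs(t_slope), df, lower.tail = FALSE)

  structure(
    list(
      slope = slope, intercept = intercept,
      r = stats::cor(depth, loss),
      t_slope = t_slope, F = f_stat,
      p_t = p_t,
      p_F = stats::pf(f_stat, 1, df, lower.tail = FALSE),
      residual_se = sm$sigma,
      se_slope = unname(sm$coefficients["depth", "Std. Error"]),
      se_intercept = unname(sm$coefficients["(Intercept)", "Std. Error"]),
      n = n, df = df,
      depth_mean = mean(depth), loss_mean = mean(loss),
      s_xx = sum((depth - mean(depth))^2),
      fit = fit
    ),
    class = "qlf_calibration"
  )
}

#' @export
print.qlf_calibration <- function(x, ...) {
  cat("Depth-to-fluorescence-loss calibration (OLS, loss % on depth um)\n")
  cat(sprintf("  n = %d pairs\n", x$n))
  cat(sprintf("  loss = %.2f * depth + %.2f   (full precision: %.6g, %.6g)\n",
              x$slope, x$intercept, x$slope, x$intercept))
  cat(sprintf("  r = %.4f\n", x$r))
  cat(sprintf("  t (slope, %d df) = %.2f,  F (1, %d df) = %.2f\n",
              x$df, x$t_slope, x$df, x$F))
  cat(sprintf("  two-tailed p = %.4f\n", x$p_t))
  invisible(x)
}

#' Predict percent fluorescence loss at a given depth
#'
#' @param calibration A `qlf_calibration`.
#' @param depth_um Depth(s) in µm.
#' @return Predicted percent loss(es).
#' @export
predict_loss <- function(calibration, depth_um) {
  stopifnot(inherits(calibration, "qlf_calibration"))
  calibration$intercept + calibration$slope * depth_um
}

#' Estimate demineralization depth from a measured fluorescence loss
#'
#' Inverts the calibration line: the point estimate is
#' `(loss - intercept) / slope`, with a standard inverse-prediction
#' (calibration) interval
#' `x0 ± t_{alpha/2, n-2} * (s/|slope|) * sqrt(1 + 1/n + (x0 - mean_x)^2 / S_xx)`
#' for a single new observation. A negative point estimate is returned
#' with a warning: the measured loss then lies below the calibration
#' line's range.
#'
#' @param calibration A `qlf_calibration` with non-zero slope.
#' @param measured_loss Measured percent fluorescence loss(es), >= 0.
#' @param level Confidence level for the interval; default 0.95.
#' @return A data frame with columns `loss_percent`, `depth_um`,
#'   `lower_um`, `upper_um` and `level`.
#' @export
estimate_depth <- function(calibration, measured_loss, level = 0.95) {
  stopifnot(inherits(calibration, "qlf_calibration"))
  if (calibration$slope == 0)
    stop("calibration slope is zero; depth cannot be inferred from loss",
         call. = FALSE)
  if (any(measured_loss < 0))
    stop("`measured_loss` must be >= 0", call. = FALSE)
  x0 <- (measured_loss - calibration$intercept) / calibration$slope
  se <- (calibration$residual_se / abs(calibration$slope)) *
    sqrt(1 + 1 / calibration$n +
           (x0 - calibration$depth_mean)^2 / calibration$s_xx)
  tq <- stats::qt(1 - (1 - level) / 2, calibration$df)
  if (any(x0 < 0))
    warning("estimated depth is negative: measured loss lies below the ",
            "calibration range", call. = FALSE)
  data.frame(
    loss_percent = measured_loss,
    depth_um = x0,
    lower_um = x0 - tq * se,
    upper_um = x0 + tq * se,
    level = level
  )
}
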