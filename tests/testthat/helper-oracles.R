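# Independent scalar oracles and random-case generators shared across
# tests. These deliberately re-derive results by the most direct route
# (per-pixel loops, textbook formulas) so they stay independent of the
# vectorized production code they check.

# direct scalar transcription of the two-step interpolation on a rectangle
oracle_rectangle_sound <- function(px, x0, y0, x1, y1) {
  sound <- matrix(NA_real_, nrow(px), ncol(px))
  for (y in (y0 + 1):(y1 - 1)) {
    for (x in (x0 + 1):(x1 - 1)) {
      l_g <- px[y + 1, x0 + 1]
      l_h <- px[y + 1, x1 + 1]
      l_mx <- l_g + (l_h - l_g) * (x - x0) / (x1 - x0)
      # horizontal interpolation between the corners on the top/bottom edges
      le_i <- px[y0 + 1, x0 + 1] +
        (px[y0 + 1, x1 + 1] - px[y0 + 1, x0 + 1]) * (x - x0) / (x1 - x0)
      lf_i <- px[y1 + 1, x0 + 1] +
        (px[y1 + 1, x1 + 1] - px[y1 + 1, x0 + 1]) * (x - x0) / (x1 - x0)
      d_e <- px[y0 + 1, x + 1] - le_i
      d_f <- px[y1 + 1, x + 1] - lf_i
      l_my <- d_e + (d_f - d_e) * (y - y0) / (y1 - y0)
      sound[y + 1, x + 1] <- l_mx + l_my
    }
  }
  sound
}

# textbook even-odd (ray crossing) point-in-polygon test for one point
oracle_point_in_polygon <- function(x, y, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((v[i, 2] > y) != (v[j, 2] > y)) {
      xint <- v[i, 1] + (y - v[i, 2]) * (v[j, 1] - v[i, 1]) / (v[j, 2] - v[i, 2])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# random star-shaped (hence simple) polygon fitting inside the image with
# the given margin from the bounds
random_simple_polygon <- function(height, width, n_vertices = 6, margin = 1.5) {
  cx <- runif(1, width * 0.35, width * 0.65)
  cy <- runif(1, height * 0.35, height * 0.65)
  rmax <- min(cx - margin, width - 1 - margin - cx,
              cy - margin, height - 1 - margin - cy)
  # jittered evenly spaced angles: star-shaped (hence simple) and never a
  # sliver
  ang <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices +
    runif(n_vertices, 0, 0.6 * 2 * pi / n_vertices)
  rad <- runif(n_vertices, 0.55 * rmax, rmax)
  polygon_roi(cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang)))
}

# random affine intensity field a + bx*x + by*y, positive everywhere
random_affine_image <- function(height, width) {
  a <- runif(1, 80, 200)
  bx <- runif(1, -1, 1)
  by <- runif(1, -1, 1)
  px <- outer(0:(height - 1), 0:(width - 1), function(y, x) a + bx * x + by * y)
  px <- px - min(px) + runif(1, 10, 50)
  fluorescence_image(px, 16L)
}
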