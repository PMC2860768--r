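# Coordinate convention used throughout: 0-based pixel indices, x = column,
# y = row, pixel centers at integer coordinates. Pixel (x, y) occupies the
# unit square [x - 0.5, x + 0.5] x [y - 0.5, y + 0.5] and maps to matrix
# element [y + 1, x + 1].

#' Construct a polygon region of interest
#'
#' An ordered vertex list delimiting the lesion analysis region; the polygon
#' is closed implicitly (last vertex connects back to the first). All edges
#' are expected to lie on sound tooth structure — the border intensities are
#' the anchors from which the sound fluorescence level inside is
#' reconstructed. Real-valued (sub-pixel) vertices are accepted and resolved
#' at rasterization.
#'
#' @param vertices An n x 2 numeric matrix (or data frame / list of pairs)
#'   of (x, y) pixel coordinates, n >= 3. The polygon must be simple (no
#'   self-intersecting edges).
#' @return An object of class `qlf_roi`.
#' @export
polygon_roi <- function(vertices) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  if (is.list(vertices) && !is.matrix(vertices))
    vertices <- do.call(rbind, lapply(vertices, as.numeric))
  if (!is.matrix(vertices) || ncol(vertices) != 2L || !is.numeric(vertices))
    stop("`vertices` must be an n x 2 numeric matrix of (x, y) pairs",
         call. = FALSE)
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stop("polygon vertices must be finite", call. = FALSE)
  # drop an explicitly repeated closing vertex
  n <- nrow(vertices)
  if (n > 1L && all(vertices[1L, ] == vertices[n, ]))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3L)
    stop("a polygon ROI needs at least 3 distinct vertices", call. = FALSE)
  if (!.polygon_is_simple(vertices))
    stop("polygon is self-intersecting; the ROI boundary must be a simple closed curve",
         call. = FALSE)
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(vertices = vertices), class = "qlf_roi")
}

#' @export
print.qlf_roi <- function(x, ...) {
  v <- x$vertices
  cat(sprintf("<qlf_roi> %d vertices, bbox x [%g, %g], y [%g, %g]\n",
              nrow(v), min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2])))
  invisible(x)
}

#' Read a polygon ROI from a JSON sidecar file
#'
#' The sidecar holds a single `"vertices"` entry: a list of `[x, y]` pairs.
#'
#' @param path Path to the JSON file.
#' @return A [polygon_roi()] object.
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read ROI: file '%s' does not exist", path),
         call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$vertices))
    stop(sprintf("'%s' has no \"vertices\" entry", path), call. = FALSE)
  polygon_roi(obj$vertices)
}

#' Write a polygon ROI to a JSON sidecar file
#'
#' @param roi A [polygon_roi()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "qlf_roi"))
  v <- roi$vertices
  jsonlite::write_json(
    list(vertices = lapply(seq_len(nrow(v)), function(i) unname(v[i, ]))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# simple-polygon test: no two non-adjacent edges intersect, and adjacent
# edges meet only at their shared vertex
.polygon_is_simple <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (.segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

.orient <- function(p, q, r) {
  val <- (q[2] - p[2]) * (r[1] - q[1]) - (q[1] - p[1]) * (r[2] - q[2])
  if (abs(val) < 1e-12) 0 else sign(val)
}

.on_segment <- function(p, q, r) {
  # collinear r on segment pq?
  r[1] <= max(p[1], q[1]) + 1e-12 && r[1] >= min(p[1], q[1]) - 1e-12 &&
    r[2] <= max(p[2], q[2]) + 1e-12 && r[2] >= min(p[2], q[2]) - 1e-12
}

.segments_intersect <- function(p1, q1, p2, q2) {
  o1 <- .orient(p1, q1, p2); o2 <- .orient(p1, q1, q2)
  o3 <- .orient(p2, q2, p1); o4 <- .orient(p2, q2, q1)
  if (o1 != o2 && o3 != o4) return(TRUE)
  if (o1 == 0 && .on_segment(p1, q1, p2)) return(TRUE)
  if (o2 == 0 && .on_segment(p1, q1, q2)) return(TRUE)
  if (o3 == 0 && .on_segment(p2, q2, p1)) return(TRUE)
  if (o4 == 0 && .on_segment(p2, q2, q1)) return(TRUE)
  FALSE
}

# Supercover rasterization of one segment: every pixel whose unit square the
# segment passes through, including both side pixels at exact corner
# crossings (so a chain of border pixels can never be crossed diagonally by
# a row or column without being seen). Returns an m x 2 matrix of (x, y).
.supercover_segment <- function(x0, y0, x1, y1) {
  # shift so pixel (i, j) covers cell [i, i+1) x [j, j+1)
  u0 <- x0 + 0.5; v0 <- y0 + 0.5
  u1 <- x1 + 0.5; v1 <- y1 + 0.5
  cx <- floor(u0); cy <- floor(v0)
  ex <- floor(u1); ey <- floor(v1)
  du <- u1 - u0; dv <- v1 - v0
  sx <- if (du > 0) 1L else -1L
  sy <- if (dv > 0) 1L else -1L
  t_max_x <- if (du != 0) ((cx + (du > 0)) - u0) / du else Inf
  t_max_y <- if (dv != 0) ((cy + (dv > 0)) - v0) / dv else Inf
  t_dx <- if (du != 0) abs(1 / du) else Inf
  t_dy <- if (dv != 0) abs(1 / dv) else Inf
  max_steps <- 2L * (abs(ex - cx) + abs(ey - cy)) + 8L
  xs <- integer(0); ys <- integer(0)
  xs[1] <- cx; ys[1] <- cy
  k <- 1L
  step <- 0L
  while (!(cx == ex && cy == ey) && step < max_steps) {
    step <- step + 1L
    if (is.finite(t_max_x) && is.finite(t_max_y) &&
        abs(t_max_x - t_max_y) < 1e-12) {
      # exact corner crossing: record both side pixels, then step diagonally
      k <- k + 1L; xs[k] <- cx + sx; ys[k] <- cy
      k <- k + 1L; xs[k] <- cx; ys[k] <- cy + sy
      cx <- cx + sx; cy <- cy + sy
      t_max_x <- t_max_x + t_dx
      t_max_y <- t_max_y + t_dy
    } else if (t_max_x < t_max_y) {
      cx <- cx + sx
      t_max_x <- t_max_x + t_dx
    } else {
      cy <- cy + sy
      t_max_y <- t_max_y + t_dy
    }
    k <- k + 1L; xs[k] <- cx; ys[k] <- cy
  }
  if (xs[k] != ex || ys[k] != ey) {
    k <- k + 1L; xs[k] <- ex; ys[k] <- ey
  }
  cbind(x = xs, y = ys)
}

# even-odd interior test for all pixel centers of one row (y integer);
# half-open edge rule so vertices are counted once
.row_crossings <- function(v, y) {
  n <- nrow(v)
  ya <- v[, 2]
  yb <- v[c(2:n, 1L), 2]
  xa <- v[, 1]
  xb <- v[c(2:n, 1L), 1]
  hit <- (ya <= y & yb > y) | (yb <= y & ya > y)
  if (!any(hit)) return(numeric(0))
  t <- (y - ya[hit]) / (yb[hit] - ya[hit])
  sort(xa[hit] + t * (xb[hit] - xa[hit]))
}

#' Rasterize a polygon ROI against an image grid
#'
#' Splits the image grid into the polygon's border (every pixel traversed by
#' a polygon edge, by supercover line rasterization) and interior (pixel
#' centers strictly inside by the even-odd rule, minus the border), and
#' precomputes, for every interior pixel, its four interpolation anchors:
#' the nearest border pixels left and right along its row and above and
#' below along its column. Supercover rasterization guarantees these
#' anchors exist — an interior span cannot escape through a diagonal gap in
#' the border chain.
#'
#' @param roi A [polygon_roi()] object.
#' @param height,width Image dimensions in pixels.
#' @return An object of class `qlf_raster` with fields:
#'   \describe{
#'     \item{interior_mask, border_mask}{logical `height x width` matrices.}
#'     \item{anchor_left, anchor_right}{x-coordinate (0-based) of the row
#'       anchors, `NA` outside the interior.}
#'     \item{anchor_top, anchor_bottom}{y-coordinate of the column anchors.}
#'     \item{run_left, run_right}{for each border pixel, the x-coordinates
#'       of the endpoints of the maximal contiguous border run containing it
#'       on its row (used for horizontal interpolation along the border).}
#'   }
#' @export
rasterize <- function(roi, height, width) {
  stopifnot(inherits(roi, "qlf_roi"))
  v <- roi$vertices
  if (any(v[, 1] < 0) || any(v[, 1] > width - 1) ||
      any(v[, 2] < 0) || any(v[, 2] > height - 1))
    stop(sprintf(
      "polygon exceeds image bounds (vertices must lie in [0, %d] x [0, %d])",
      width - 1L, height - 1L), call. = FALSE)

  border <- matrix(FALSE, height, width)
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    px <- .supercover_segment(v[i, 1], v[i, 2], v[j, 1], v[j, 2])
    px[, 1] <- pmin(pmax(px[, 1], 0L), width - 1L)
    px[, 2] <- pmin(pmax(px[, 2], 0L), height - 1L)
    border[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- TRUE
  }

  interior <- matrix(FALSE, height, width)
  y_range <- max(0L, floor(min(v[, 2]))):min(height - 1L, ceiling(max(v[, 2])))
  for (y in y_range) {
    cr <- .row_crossings(v, y)
    if (length(cr) < 2L) next
    # even-odd: x inside iff an odd number of crossings lie strictly beyond x
    xs <- 0:(width - 1L)
    beyond <- vapply(xs, function(x) sum(cr > x), numeric(1))
    interior[y + 1L, xs[beyond %% 2 == 1] + 1L] <- TRUE
  }
  interior <- interior & !border
  if (!any(interior))
    stop("polygon ROI has an empty interior", call. = FALSE)

  anchor_left <- anchor_right <- matrix(NA_integer_, height, width)
  anchor_top <- anchor_bottom <- matrix(NA_integer_, height, width)
  run_left <- run_right <- matrix(NA_integer_, height, width)

  for (r in seq_len(height)) {
    bx <- which(border[r, ]) - 1L
    if (length(bx)) {
      # contiguous border runs on this row
      brk <- c(0L, which(diff(bx) > 1L), length(bx))
      for (k in seq_len(length(brk) - 1L)) {
        run <- bx[(brk[k] + 1L):brk[k + 1L]]
        run_left[r, run + 1L] <- run[1L]
        run_right[r, run + 1L] <- run[length(run)]
      }
    }
    ix <- which(interior[r, ]) - 1L
    if (!length(ix)) next
    for (x in ix) {
      lo <- bx[bx < x]; hi <- bx[bx > x]
      if (!length(lo) || !length(hi))
        stop("rasterization produced an interior pixel without row anchors",
             call. = FALSE)
      anchor_left[r, x + 1L] <- lo[length(lo)]
      anchor_right[r, x + 1L] <- hi[1L]
    }
  }
  for (cc in seq_len(width)) {
    by <- which(border[, cc]) - 1L
    iy <- which(interior[, cc]) - 1L
    if (!length(iy)) next
    for (y in iy) {
      lo <- by[by < y]; hi <- by[by > y]
      if (!length(lo) || !length(hi))
        stop("rasterization produced an interior pixel without column anchors",
             call. = FALSE)
      anchor_top[y + 1L, cc] <- lo[length(lo)]
      anchor_bottom[y + 1L, cc] <- hi[1L]
    }
  }

  structure(
    list(
      height = height, width = width,
      interior_mask = interior, border_mask = border,
      anchor_left = anchor_left, anchor_right = anchor_right,
      anchor_top = anchor_top, anchor_bottom = anchor_bottom,
      run_left = run_left, run_right = run_right
    ),
    class = "qlf_raster"
  )
}

#' @export
print.qlf_raster <- function(x, ...) {
  cat(sprintf("<qlf_raster> %d x %d grid, %d interior px, %d border px\n",
              x$width, x$height, sum(x$interior_mask), sum(x$border_mask)))
  invisible(x)
}

#' Smoothed border intensities
#'
#' Recomputes the intensity of every pixel on the polygon edges as the mean
#' of the 3 x 3 pixel area centered on it, the window clipped at the image
#' boundary (mean over the available pixels, never padded). These smoothed
#' values are the interpolation anchors: averaging suppresses single-pixel
#' sensor noise on the sound border that would otherwise propagate into the
#' whole reconstructed field.
#'
#' @param image A [fluorescence_image()] object.
#' @param raster A [rasterize()]d ROI of the same shape.
#' @return A numeric matrix of the image's shape holding the smoothed value
#'   at border pixels and `NA` elsewhere.
#' @export
smoothed_border_values <- function(image, raster) {
  stopifnot(inherits(image, "qlf_image"), inherits(raster, "qlf_raster"))
  if (image$height != raster$height || image$width != raster$width)
    stop("image and rasterized ROI have different shapes", call. = FALSE)
  sm <- box_mean3(image$pixels)
  sm[!raster$border_mask] <- NA_real_
  sm
}
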