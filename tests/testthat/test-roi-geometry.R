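test_that("an axis-aligned rectangle rasterizes to the expected pixel sets", {
  roi <- polygon_roi(cbind(c(1, 8, 8, 1), c(1, 1, 6, 6)))
  ra <- rasterize(roi, 10, 10)

  expected_interior <- matrix(FALSE, 10, 10)
  expected_interior[3:6, 3:8] <- TRUE          # 2<=y<=5, 2<=x<=7 (0-based)
  expect_identical(ra$interior_mask, expected_interior)

  expected_border <- matrix(FALSE, 10, 10)
  expected_border[2, 2:9] <- TRUE              # y = 1
  expected_border[7, 2:9] <- TRUE              # y = 6
  expected_border[2:7, 2] <- TRUE              # x = 1
  expected_border[2:7, 9] <- TRUE              # x = 8
  expect_identical(ra$border_mask, expected_border)

  # no overlap; rectangle anchors are the edges themselves
  expect_false(any(ra$interior_mask & ra$border_mask))
  expect_true(all(ra$anchor_left[ra$interior_mask] == 1L))
  expect_true(all(ra$anchor_right[ra$interior_mask] == 8L))
  expect_true(all(ra$anchor_top[ra$interior_mask] == 1L))
  expect_true(all(ra$anchor_bottom[ra$interior_mask] == 6L))
  # border runs on the top edge span the full edge
  expect_equal(ra$run_left[2, 5], 1L)
  expect_equal(ra$run_right[2, 5], 8L)
})

test_that("triangle interior matches a brute-force even-odd oracle", {
  roi <- polygon_roi(cbind(c(1, 7, 1), c(1, 1, 7)))
  ra <- rasterize(roi, 10, 10)
  v <- roi$vertices
  for (y in 0:9) {
    for (x in 0:9) {
      expected <- oracle_point_in_polygon(x, y, v) && !ra$border_mask[y + 1, x + 1]
      expect_identical(ra$interior_mask[y + 1, x + 1], expected)
    }
  }
})

test_that("every interior pixel of a non-convex polygon has four anchors on its own span", {
  # L-shaped polygon on a 20 x 20 grid
  roi <- polygon_roi(cbind(c(2, 17, 17, 10, 10, 2),
                           c(2, 2, 8, 8, 17, 17)))
  ra <- rasterize(roi, 20, 20)
  idx <- which(ra$interior_mask)
  expect_gt(length(idx), 0)
  for (i in idx) {
    y <- (i - 1) %% 20; x <- (i - 1) %/% 20
    al <- ra$anchor_left[i]; ar <- ra$anchor_right[i]
    at <- ra$anchor_top[i]; ab <- ra$anchor_bottom[i]
    expect_false(anyNA(c(al, ar, at, ab)))
    expect_true(al < x && x < ar)
    expect_true(at < y && y < ab)
    # anchors bound the pixel's own contiguous span: everything strictly
    # between the anchors on the row/column is interior
    if (ar - al > 1)
      expect_true(all(ra$interior_mask[y + 1, (al + 2):ar]))
    if (ab - at > 1)
      expect_true(all(ra$interior_mask[(at + 2):ab, x + 1]))
  }
})

test_that("rasterization is invariant to vertex rotation, reversal and integer translation", {
  set.seed(21)
  for (rep in 1:5) {
    roi <- random_simple_polygon(24, 24, n_vertices = 7)
    ra <- rasterize(roi, 24, 24)
    v <- roi$vertices
    n <- nrow(v)

    rot <- polygon_roi(v[c(3:n, 1:2), ])
    rev <- polygon_roi(v[n:1, ])
    expect_identical(rasterize(rot, 24, 24)$interior_mask, ra$interior_mask)
    expect_identical(rasterize(rev, 24, 24)$border_mask, ra$border_mask)

    shifted <- polygon_roi(sweep(v, 2, c(2, 3), "+"))
    ra_s <- rasterize(shifted, 30, 30)
    big <- matrix(FALSE, 30, 30)
    big[1:24 + 3, 1:24 + 2] <- ra$interior_mask
    expect_identical(ra_s$interior_mask, big)
  }
})

test_that("degenerate and out-of-bounds polygons are rejected", {
  expect_error(polygon_roi(cbind(c(0, 1), c(0, 1))), "at least 3")
  # bow-tie self-intersection
  expect_error(polygon_roi(cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))),
               "self-intersecting")
  roi <- polygon_roi(cbind(c(1, 8, 8, 1), c(1, 1, 6, 6)))
  expect_error(rasterize(roi, 5, 5), "bounds")
  # sliver with no strictly-interior pixel centers
  thin <- polygon_roi(cbind(c(1, 8, 8, 1), c(1, 1, 1.4, 1.4)))
  expect_error(rasterize(thin, 10, 10), "empty interior")
})

test_that("border smoothing averages the available 3 x 3 window", {
  roi <- polygon_roi(cbind(c(1, 8, 8, 1), c(1, 1, 6, 6)))
  ra <- rasterize(roi, 10, 10)

  img_const <- fluorescence_image(matrix(100, 10, 10), 8L)
  sm <- smoothed_border_values(img_const, ra)
  expect_true(all(sm[ra$border_mask] == 100))
  expect_true(all(is.na(sm[!ra$border_mask])))

  # hot pixel on the border is averaged down, not taken at face value
  px <- matrix(100, 10, 10)
  px[2, 5] <- 255                       # border pixel at x=4, y=1
  sm_hot <- smoothed_border_values(fluorescence_image(px, 8L), ra)
  expect_equal(sm_hot[2, 5], (255 + 8 * 100) / 9)

  # clipped corner window: 2 x 2 reach only
  expect_equal(box_mean3(matrix(c(4, 12, 8, 16), 2, 2))[1, 1],
               (4 + 8 + 12 + 16) / 4)

  # smoothing never leaves the window's [min, max]
  set.seed(5)
  rnd <- fluorescence_image(matrix(runif(100, 0, 255), 10, 10), 8L)
  sm_r <- smoothed_border_values(rnd, ra)
  expect_true(all(sm_r[ra$border_mask] >= min(rnd$pixels) &
                    sm_r[ra$border_mask] <= max(rnd$pixels)))

  bad <- fluorescence_image(matrix(1, 12, 12), 8L)
  expect_error(smoothed_border_values(bad, ra), "shape")
})
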