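test_that("constant fields are reproduced exactly with zero loss", {
  img <- fluorescence_image(matrix(100, 12, 12), 8L)
  lm_rect <- interpolate_rectangle(img, 1, 1, 10, 10)
  expect_true(all(lm_rect$sound[lm_rect$interior_mask] == 100))
  expect_true(all(lm_rect$delta[lm_rect$interior_mask] == 0))
  expect_true(all(lm_rect$percent[lm_rect$valid_mask] == 0))

  roi <- polygon_roi(cbind(c(2, 9, 10, 6, 2), c(2, 1, 8, 10, 7)))
  lm_poly <- interpolate_polygon(img, rasterize(roi, 12, 12))
  expect_true(all(abs(lm_poly$delta[lm_poly$interior_mask]) < 1e-12))
})

test_that("the two-step scheme is exact on affine fields", {
  px <- outer(0:11, 0:11, function(y, x) 5 + 2 * x + 3 * y)
  img <- fluorescence_image(px, 8L)

  lm_rect <- interpolate_rectangle(img, 1, 1, 10, 10)
  expect_equal(lm_rect$sound[lm_rect$interior_mask],
               px[lm_rect$interior_mask], tolerance = 1e-12)
  expect_true(all(abs(lm_rect$delta[lm_rect$interior_mask]) < 1e-9))

  # against the brute-force scalar transcription
  oracle <- oracle_rectangle_sound(px, 1, 1, 10, 10)
  expect_equal(lm_rect$sound[lm_rect$interior_mask],
               oracle[lm_rect$interior_mask], tolerance = 1e-12)

  # polygon form, with smoothing active on the borders (full 3x3 windows
  # preserve affine fields)
  roi <- polygon_roi(cbind(c(2, 9, 9, 2), c(2, 2, 9, 9)))
  lm_poly <- interpolate_polygon(img, rasterize(roi, 12, 12))
  expect_true(all(abs(lm_poly$delta[lm_poly$interior_mask]) < 1e-9))
})

test_that("a lesion dip on a plane is recovered exactly by the reconstruction", {
  # plane + Gaussian dip of depth 30 centered mid-ROI: anchors see only the
  # plane, so the reconstruction equals the plane and the dip becomes loss
  h <- 15; w <- 15
  plane <- outer(0:(h - 1), 0:(w - 1), function(y, x) 120 + x + 0.5 * y)
  dip <- 30 * outer(0:(h - 1), 0:(w - 1),
                    function(y, x) exp(-((x - 7)^2 + (y - 7)^2) / 2))
  img <- fluorescence_image(plane - dip, 8L)
  lm <- interpolate_rectangle(img, 1, 1, 13, 13)

  # dip is ~1e-10 at the rectangle edges, so reconstruction = plane
  expect_equal(lm$sound[lm$interior_mask], plane[lm$interior_mask],
               tolerance = 1e-6)
  expect_equal(lm$percent[8, 8], 100 * 30 / plane[8, 8], tolerance = 1e-6)
})

test_that("production rectangle code matches the scalar oracle on random images", {
  set.seed(33)
  for (rep in 1:10) {
    px <- matrix(runif(16 * 16, 10, 255), 16, 16)
    img <- fluorescence_image(px, 8L)
    lm <- interpolate_rectangle(img, 1, 2, 14, 13)
    oracle <- oracle_rectangle_sound(px, 1, 2, 14, 13)
    inside <- lm$interior_mask
    expect_lt(max(abs(lm$sound[inside] - oracle[inside]) /
                    pmax(abs(oracle[inside]), 1)), 1e-9)
  }
})

test_that("the polygon form reduces to the rectangle form when smoothing is a no-op", {
  # random inner content, constant 3-pixel frame under the rectangle outline
  set.seed(7)
  px <- matrix(140, 16, 16)
  px[6:11, 6:11] <- runif(36, 60, 200)
  img <- fluorescence_image(px, 8L)

  lm_rect <- interpolate_rectangle(img, 2, 2, 13, 13)
  roi <- polygon_roi(cbind(c(2, 13, 13, 2), c(2, 2, 13, 13)))
  lm_poly <- interpolate_polygon(img, rasterize(roi, 16, 16))

  inside <- lm_rect$interior_mask
  expect_identical(inside, lm_poly$interior_mask)
  expect_equal(lm_poly$sound[inside], lm_rect$sound[inside],
               tolerance = 1e-12)
  expect_equal(lm_poly$percent[lm_poly$valid_mask],
               lm_rect$percent[lm_rect$valid_mask], tolerance = 1e-12)
})

test_that("reconstruction depends only on border pixels (anchor locality)", {
  set.seed(9)
  px <- matrix(runif(400, 50, 200), 20, 20)
  img <- fluorescence_image(px, 8L)
  roi <- polygon_roi(cbind(c(3, 16, 16, 3), c(3, 3, 16, 16)))
  ra <- rasterize(roi, 20, 20)
  lm1 <- interpolate_polygon(img, ra)

  # perturb pixels strictly interior (2 px inside the border, outside any
  # border smoothing window)
  px2 <- px
  px2[8:12, 8:12] <- px2[8:12, 8:12] + 75
  lm2 <- interpolate_polygon(fluorescence_image(px2, 8L), ra)
  expect_identical(lm2$sound, lm1$sound)
  expect_false(identical(lm2$delta, lm1$delta))
})

test_that("scaling intensities scales sound and delta but not percent", {
  set.seed(13)
  px <- matrix(runif(256, 20, 200), 16, 16)
  img <- fluorescence_image(px, 8L)
  roi <- polygon_roi(cbind(c(2, 13, 13, 2), c(2, 2, 13, 13)))
  ra <- rasterize(roi, 16, 16)
  lm1 <- interpolate_polygon(img, ra)
  lm3 <- interpolate_polygon(fluorescence_image(3 * px, 16L), ra)
  inside <- lm1$interior_mask
  expect_equal(lm3$sound[inside], 3 * lm1$sound[inside], tolerance = 1e-12)
  expect_equal(lm3$delta[inside], 3 * lm1$delta[inside], tolerance = 1e-9)
  expect_equal(lm3$percent[lm3$valid_mask], lm1$percent[lm1$valid_mask],
               tolerance = 1e-9)
})

test_that("degenerate rectangles and shape mismatches are rejected", {
  img <- fluorescence_image(matrix(1, 8, 8), 8L)
  expect_error(interpolate_rectangle(img, 1, 1, 2, 6), "degenerate")
  expect_error(interpolate_rectangle(img, 1, 1, 9, 6), "bounds")
  roi <- polygon_roi(cbind(c(1, 6, 6, 1), c(1, 1, 6, 6)))
  ra <- rasterize(roi, 8, 8)
  big <- fluorescence_image(matrix(1, 9, 9), 8L)
  expect_error(interpolate_polygon(big, ra), "shape")
})

test_that("loss maps export as tables and multi-layer TIFFs", {
  px <- outer(0:9, 0:9, function(y, x) 100 + x)
  img <- fluorescence_image(px, 8L)
  lm <- interpolate_rectangle(img, 1, 1, 8, 8)
  tab <- lossmap_as_table(lm)
  expect_equal(nrow(tab), sum(lm$interior_mask))
  expect_named(tab, c("x", "y", "observed", "sound", "delta", "percent"))
  i <- which(tab$x == 4 & tab$y == 4)
  expect_equal(tab$observed[i], px[5, 5])
  expect_equal(tab$sound[i], lm$sound[5, 5])

  f <- withr::local_tempfile(fileext = ".tif")
  write_lossmap_tiff(lm, f)
  back <- read_lossmap_tiff(f, bit_depth = 8L)
  expect_equal(back$sound[5, 5], lm$sound[5, 5], tolerance = 1e-5)
  expect_equal(back$delta[5, 5], lm$delta[5, 5], tolerance = 1e-4)
  expect_equal(back$percent[5, 5], lm$percent[5, 5], tolerance = 1e-4)
})
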