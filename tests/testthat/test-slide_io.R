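# minimal re-exposure of the hue matcher for the contour-exclusion check
.match_hue_public <- function(sl) {
  g <- sl$pixels[, , 2] == 255 & sl$pixels[, , 1] == 0
  g
}

test_that("build_mask recovers contour interiors and areas", {
  # one green 500x500 px rectangle contour at 0.908 um/px
  sl <- make_contour_slide(1000, 1000, 0.908, green = c(250, 250, 749, 749))
  m <- build_mask(sl)
  expect_s3_class(m, "region_mask")
  # interior of a 500 px contour, contour line excluded: ~498^2 px
  expect_equal(m$included_area_mm2, 500^2 * 0.908^2 / 1e6, tolerance = 0.02)
  expect_false(any(m$mask & .match_hue_public(sl)))

  # red 100x100 rectangle inside reduces the area by ~100^2 px
  sl2 <- make_contour_slide(1000, 1000, 0.908, green = c(250, 250, 749, 749),
                            red = c(400, 400, 499, 499))
  m2 <- build_mask(sl2)
  expect_equal(m$included_area_mm2 - m2$included_area_mm2,
               100^2 * 0.908^2 / 1e6, tolerance = 0.1)

  # no green contour at all
  blank <- annotated_slide(array(255, c(100, 100, 3)), 0.908)
  expect_error(build_mask(blank), "no tumour region")

  # red contour outside any green region: warn and ignore
  sl3 <- make_contour_slide(1000, 1000, 0.908, green = c(250, 250, 749, 749),
                            red = c(50, 50, 150, 150))
  expect_warning(m3 <- build_mask(sl3), "ignored")
  expect_equal(m3$included_area_mm2, m$included_area_mm2, tolerance = 1e-6)
})

test_that("build_mask bridges hand-drawn gaps up to the closing radius", {
  sl <- make_contour_slide(400, 400, 0.908, green = c(100, 100, 299, 299))
  # cut a 4 px gap in the top edge
  sl$pixels[100, 200:203, ] <- 255
  m <- expect_no_error(build_mask(sl, closing_radius_px = 3))
  expect_gt(m$included_area_mm2, 190^2 * 0.908^2 / 1e6)
})

test_that("orientation_angle matches symmetry and constructed tilts", {
  horiz <- matrix(FALSE, 300, 500)
  horiz[101:200, 51:450] <- TRUE       # 400 wide x 100 tall
  expect_equal(orientation_angle(region_mask(horiz, 0.908)), 0)

  vert <- matrix(FALSE, 500, 300)
  vert[51:450, 101:200] <- TRUE
  expect_equal(orientation_angle(region_mask(vert, 0.908)), 90)

  for (deg in c(-60, -30, 10, 30, 75)) {
    em <- make_ellipse_mask(600, 600, 200, 80, deg)
    expect_equal(orientation_angle(em), deg, tolerance = 0.5)
  }

  single <- matrix(FALSE, 10, 10); single[5, 5] <- TRUE
  expect_warning(a <- orientation_angle(region_mask(single, 0.908)))
  expect_equal(a, 0)
})

test_that("rotate_and_crop normalises orientation and is idempotent", {
  # already-horizontal rectangle: crop only
  sl <- make_contour_slide(600, 800, 0.908, green = c(200, 100, 399, 699))
  m <- build_mask(sl)
  rc <- rotate_and_crop(sl, m)
  expect_equal(dim(rc$mask$mask), c(198, 598), tolerance = 0)
  # vertical rectangle: output wider than tall
  slv <- make_contour_slide(800, 600, 0.908, green = c(100, 200, 699, 399))
  mv <- build_mask(slv)
  rcv <- rotate_and_crop(slv, mv)
  expect_gt(ncol(rcv$mask$mask), nrow(rcv$mask$mask))
  expect_equal(dim(rcv$mask$mask), c(198, 598), tolerance = 0)

  # tilted ellipse: orientation after normalisation ~ 0, area preserved
  em <- make_ellipse_mask(700, 700, 250, 100, 30)
  slE <- annotated_slide(array(200, c(700, 700, 3)), 0.908)
  rcE <- rotate_and_crop(slE, em)
  expect_equal(orientation_angle(rcE$mask), 0, tolerance = 0.5)
  expect_equal(rcE$mask$included_area_mm2, em$included_area_mm2,
               tolerance = 0.01)
  # masked-out pixels black
  expect_true(all(rcE$slide$pixels[array(rep(!rcE$mask$mask, 3),
                                         dim(rcE$slide$pixels))] == 0))
})

test_that("PNG round trip preserves the raster", {
  sl <- make_contour_slide(60, 80, 0.454, green = c(10, 10, 49, 59))
  f <- tempfile(fileext = ".png")
  write_slide_png(sl, f)
  sl2 <- read_slide_png(f, 0.454)
  expect_equal(sl2$pixels, sl$pixels)
  unlink(f)
})
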