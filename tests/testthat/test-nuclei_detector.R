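# helper: uniform-colour slide
flat_slide <- function(rgb, h = 40, w = 40, res = 0.454) {
  img <- array(0, c(h, w, 3))
  for (k in 1:3) img[, , k] <- rgb[k]
  annotated_slide(img, res)
}

test_that("smoothing preserves constants and removes salt noise", {
  sl <- flat_slide(c(120, 80, 60))
  sm <- smooth_image(sl, detection_params("20x"))
  expect_equal(sm$pixels, sl$pixels, tolerance = 1e-10)

  sl$pixels[20, 20, ] <- 255   # single salt pixel
  sm2 <- smooth_image(sl, detection_params("20x"))
  expect_equal(sm2$pixels[20, 20, 1], 120, tolerance = 1e-10)

  tiny <- flat_slide(c(10, 10, 10), h = 3, w = 3)
  expect_error(smooth_image(tiny, detection_params("20x")))
})

test_that("Gaussian impulse response matches a direct convolution oracle", {
  img <- array(0, c(21, 21, 3))
  img[11, 11, ] <- 255
  sl <- annotated_slide(img, 0.454)
  p <- detection_params("20x", median_kernel_px = 1)  # isolate the Gaussian
  sm <- smooth_image(sl, p)
  x <- seq(-2, 2)
  k1 <- exp(-x^2 / (2 * 0.5^2)); k1 <- k1 / sum(k1)
  expected <- 255 * outer(k1, k1)
  expect_equal(sm$pixels[9:13, 9:13, 1], expected, tolerance = 1)
})

test_that("brown thresholding follows the RGB bounds and the mask", {
  img <- array(0, c(10, 10, 3))
  img[, , 1] <- 150; img[, , 2] <- 90; img[, , 3] <- 60   # DAB brown
  img[1:3, 1:3, 1] <- 80; img[1:3, 1:3, 2] <- 90; img[1:3, 1:3, 3] <- 180  # blue
  sl <- annotated_slide(img, 0.454)
  p <- detection_params("20x", blue_upper = 140)
  bw <- threshold_brown(sl, p)
  expect_true(bw[5, 5])
  expect_false(bw[2, 2])
  msk <- region_mask(matrix(FALSE, 10, 10), 0.454)
  expect_false(any(threshold_brown(sl, p, msk)))
})

test_that("raising blue_upper_threshold never decreases the white count", {
  set.seed(42)
  img <- array(runif(30 * 30 * 3, 0, 255), c(30, 30, 3))
  img[, , 1] <- pmax(img[, , 1], img[, , 2] + 1)     # enforce R > G ordering
  img[, , 3] <- pmin(img[, , 3], img[, , 2])
  sl <- annotated_slide(img, 0.454)
  counts <- vapply(seq(0, 255, by = 25), function(bu)
    sum(threshold_brown(sl, detection_params("20x", blue_upper = bu))),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("clean_and_fill removes isolated pixels and fills holes", {
  b <- matrix(FALSE, 30, 30)
  b[15, 15] <- TRUE                    # lone pixel
  p <- detection_params("20x", box_blur_kernel_px = 1)
  expect_false(any(clean_and_fill(b, p)))

  # white annulus with black centre becomes a solid disk
  b2 <- matrix(FALSE, 41, 41)
  rows <- matrix(1:41, 41, 41); cols <- t(rows)
  d <- sqrt((rows - 21)^2 + (cols - 21)^2)
  b2[d >= 8 & d <= 12] <- TRUE
  out <- clean_and_fill(b2, p)
  expect_true(all(out[d <= 12]))
})

test_that("clean_and_fill equals a naive pixel-loop oracle", {
  set.seed(7)
  b <- matrix(runif(40 * 40) < 0.4, 40, 40)
  k <- 3
  p <- detection_params("10x")
  out <- clean_and_fill(b, p)
  # oracle: box blur (replicate padding) >= 0.5, isolated-pixel removal,
  # hole filling by border flood fill -- all as explicit loops
  nr <- nrow(b); nc <- ncol(b)
  blur <- matrix(FALSE, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    s <- 0
    for (di in -1:1) for (dj in -1:1)
      s <- s + b[min(max(i + di, 1), nr), min(max(j + dj, 1), nc)]
    blur[i, j] <- s / 9 >= 0.5
  }
  iso <- blur
  for (i in 1:nr) for (j in 1:nc) if (blur[i, j]) {
    nb <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && blur[ii, jj])
        nb <- nb + 1
    }
    if (nb == 0) iso[i, j] <- FALSE
  }
  # flood fill black from border (4-neighbourhood)
  outside <- matrix(FALSE, nr, nc)
  queue <- which(!iso & (row(iso) %in% c(1, nr) | col(iso) %in% c(1, nc)))
  outside[queue] <- TRUE
  while (length(queue)) {
    q <- queue[1]; queue <- queue[-1]
    i <- (q - 1) %% nr + 1; j <- (q - 1) %/% nr + 1
    for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + dd[1]; jj <- j + dd[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          !iso[ii, jj] && !outside[ii, jj]) {
        outside[ii, jj] <- TRUE
        queue <- c(queue, ii + (jj - 1) * nr)
      }
    }
  }
  oracle <- iso | (!iso & !outside)
  expect_identical(out, oracle)
})

test_that("split_and_measure finds disk centroids and filters by size", {
  res <- 0.454
  b <- matrix(FALSE, 200, 200)
  rows <- matrix(1:200, 200, 200); cols <- t(rows)
  centres <- list(c(40, 40), c(40, 120), c(120, 40), c(120, 120), c(80, 170))
  r_px <- sqrt(40 / pi) / res    # 40 um^2 disks
  for (cc in centres)
    b[(rows - cc[1])^2 + (cols - cc[2])^2 <= r_px^2] <- TRUE
  p <- detection_params("20x")
  pat <- split_and_measure(b, p, res)
  expect_equal(pat$n_cells, 5)
  found <- cbind(pat$x_um / res + 0.5, pat$y_um / res + 0.5)  # px coords
  for (cc in centres) {
    d <- sqrt((found[, 1] - cc[2])^2 + (found[, 2] - cc[1])^2)
    expect_lt(min(d), 1.5)
  }

  # dumbbell: two overlapping disks -> 2 centroids
  b2 <- matrix(FALSE, 100, 150)
  rows2 <- matrix(1:100, 100, 150); cols2 <- t(matrix(1:150, 150, 100))
  b2[(rows2 - 50)^2 + (cols2 - 60)^2 <= 12^2] <- TRUE
  b2[(rows2 - 50)^2 + (cols2 - 80)^2 <= 12^2] <- TRUE
  pat2 <- split_and_measure(b2, p, res)
  expect_equal(pat2$n_cells, 2)

  # tiny speck below min area -> dropped
  b3 <- matrix(FALSE, 50, 50); b3[25, 25:26] <- TRUE
  expect_equal(split_and_measure(b3, p, res)$n_cells, 0)
})

test_that("detection on rendered fixtures attains recall/precision >= 0.95", {
  pat <- gen_pattern("hardcore", list(n = 60, delta_um = 18),
                     c(400, 400), seed = 11)
  sl <- render_ihc(pat, seed = 12)
  mask <- build_mask(sl)
  det <- detect_cells(sl, mask)
  gt <- attr(sl, "ground_truth_pattern")
  mar <- attr(sl, "margin_um")
  gx <- gt$x_um + mar; gy <- gt$y_um + mar
  # greedy matching within 5 um
  matched <- 0
  used <- rep(FALSE, det$n_cells)
  for (i in seq_along(gx)) {
    d <- sqrt((det$x_um - gx[i])^2 + (det$y_um - gy[i])^2)
    d[used] <- Inf
    if (length(d) && min(d) <= 5) { matched <- matched + 1; used[which.min(d)] <- TRUE }
  }
  recall <- matched / length(gx)
  precision <- matched / det$n_cells
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("centroid coordinates are resolution-invariant (20x vs 10x)", {
  pat <- gen_pattern("hardcore", list(n = 40, delta_um = 20),
                     c(300, 300), seed = 5)
  sl20 <- render_ihc(pat, style = list(resolution_um_per_px = 0.454), seed = 3)
  sl10 <- render_ihc(pat, style = list(resolution_um_per_px = 0.908), seed = 3)
  d20 <- detect_cells(sl20, build_mask(sl20))
  d10 <- detect_cells(sl10, build_mask(sl10))
  expect_equal(d20$n_cells, d10$n_cells, tolerance = 0.05)
  n <- min(d20$n_cells, d10$n_cells)
  # match the two detections; median displacement below ~1 px at 10x
  meddist <- median(vapply(seq_len(d20$n_cells), function(i)
    min(sqrt((d10$x_um - d20$x_um[i])^2 + (d10$y_um - d20$y_um[i])^2)),
    numeric(1)))
  expect_lt(meddist, 1.0)
})
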