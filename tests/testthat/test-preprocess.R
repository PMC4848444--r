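test_that("retina circle is recovered from a synthetic disc", {
  px <- make_disc_image(256, c(128, 128), 100)
  circ <- detect_retina_circle(px)
  expect_lt(max(abs(circ$center - c(128, 128))), 2)
  expect_lt(abs(circ$radius - 100), 2)
  # deterministic
  circ2 <- detect_retina_circle(px)
  expect_identical(circ, circ2)
  # covers at least 95% of bright pixels
  bright <- which(pmax(px[, , 1], px[, , 2], px[, , 3]) > 20, arr.ind = TRUE)
  inside <- (bright[, 1] - circ$center[1])^2 +
    (bright[, 2] - circ$center[2])^2 <= (circ$radius + 1)^2
  expect_gte(mean(inside), 0.95)
})

test_that("an all-dark image is an explicit failure, never a fabricated circle", {
  expect_error(detect_retina_circle(array(0, c(64, 64, 3))), "no retina")
  expect_error(detect_retina_circle(array(5, c(64, 64, 3))), "no retina")
})

test_that("a disc touching the raster border gets a radius clipped to fit", {
  px <- make_disc_image(200, c(100, 60), 80)  # touches the left border
  circ <- detect_retina_circle(px)
  d <- dim(px)
  expect_gte(circ$center[2] - circ$radius, 0.5)
  # exhaustive fit oracle: the unclipped enclosing radius from the mask
  bright <- which(pmax(px[, , 1], px[, , 2], px[, , 3]) > 20, arr.ind = TRUE)
  ctr <- colMeans(bright)
  r_full <- sqrt(max((bright[, 1] - ctr[1])^2 + (bright[, 2] - ctr[2])^2))
  r_border <- min(ctr[1] - 1, d[1] - ctr[1], ctr[2] - 1, d[2] - ctr[2])
  expect_equal(circ$radius, min(r_full, r_border), tolerance = 1e-6)
})

test_that("ROI is the even-sided inscribed square, fully inside the circle", {
  px <- make_disc_image(500, c(230, 270), 100)
  img <- fundus_image(px, c(230, 270), 100, id = "disc")
  roi <- extract_roi(img)
  expect_equal(roi$side, 140)  # floor(100 * sqrt(2)) = 141 -> even 140
  # membership: every ROI pixel lies inside the circle
  half <- roi$side / 2
  rows <- (230 - half + 1):(230 + half)
  cols <- (270 - half + 1):(270 + half)
  d2 <- outer((rows - 230)^2, (cols - 270)^2, "+")
  expect_true(all(d2 <= 100^2))
  expect_true(all(roi$pixels[, , 1] > 0))  # never leaves the disc
})

test_that("ROI extraction is idempotent on an in-circle square crop", {
  roi <- one_roi()
  s <- roi$side
  # reinterpret the crop as an image whose inscribed square is itself
  pad <- array(0, c(s + 80, s + 80, 3))
  pad[41:(40 + s), 41:(40 + s), ] <- roi$pixels
  ctr <- 40 + s / 2
  img2 <- fundus_image(pad, c(ctr, ctr), s / sqrt(2) + 1e-9, id = "crop")
  roi2 <- extract_roi(img2)
  expect_equal(roi2$side, s)
  expect_equal(roi2$pixels, roi$pixels)
})

test_that("a tiny retina circle is rejected", {
  px <- make_disc_image(128, c(64, 64), 5)
  img <- fundus_image(px, c(64, 64), 5, id = "tiny")
  expect_error(extract_roi(img), "ROI too small")
})

test_that("median kernel is one-fourth the ROI side, forced odd", {
  expect_equal(illumination_kernel_size(100), 25)
  expect_equal(illumination_kernel_size(120), 31)  # 30 -> odd 31
  expect_equal(illumination_kernel_size(140), 35)
})

test_that("a constant green channel normalises to a flat 128", {
  g <- matrix(77, 32, 32)
  out <- normalize_illumination(g)
  expect_true(all(out == 128))
})

test_that("a single bright dot is amplified x2 over a flat 128 background", {
  g <- matrix(100, 16, 16)
  g[8, 8] <- 130
  out <- normalize_illumination(g)
  # direct evaluation of the formula: median filter = 100 everywhere
  expect_equal(out[8, 8], 2 * (130 - 100) + 128)
  off <- out[-8, ] # all rows except the dot row
  expect_true(all(abs(off - 128) < 1e-9))
})

test_that("normalisation cancels smooth illumination gradients", {
  roi <- one_roi()
  g <- roi$pixels[, , 2]
  s <- nrow(g)
  ramp <- 20 * outer(seq_len(s), rep(1, s)) / s  # scale >> kernel
  a <- normalize_illumination(g)
  b <- normalize_illumination(pmin(pmax(g + ramp, 0), 255))
  expect_gte(mean(abs(a - b) < 5), 0.99)
})

test_that("preprocessing is byte-deterministic", {
  roi1 <- extract_roi(small_dataset()$images[[3]])
  roi2 <- extract_roi(small_dataset()$images[[3]])
  expect_identical(roi1, roi2)
})
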