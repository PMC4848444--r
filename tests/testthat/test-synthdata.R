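test_that("the default spec mirrors the reference cohort distribution", {
  spec <- synth_spec()
  expect_equal(unname(spec$n_per_cell["good", ]), c(50, 43, 24, 22))
  expect_equal(unname(spec$n_per_cell["poor", ]), c(29, 36, 41, 34))
  expect_equal(sum(spec$n_per_cell), 279)
})

test_that("invalid specs fail before any image is generated", {
  expect_error(synth_spec(n_per_cell = matrix(-1, 2, 4)), "non-negative")
  expect_error(synth_spec(n_per_cell = matrix(1, 3, 4)), "2 x 4")
  expect_error(synth_spec(image_side = 32), "at least 96")
  expect_error(synth_spec(soft_drusen = list(n_min = 1, n_mean = 2,
                                             r_min = 4, r_max = 500)),
               "smaller than the retina")
})

test_that("generation is byte-identical for a fixed seed", {
  spec <- synth_spec(n_per_cell = matrix(1, 2, 4), image_side = 96,
                     seed = 7)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  for (i in seq_along(d1$images))
    expect_identical(d1$images[[i]]$pixels, d2$images[[i]]$pixels)
  expect_identical(d1$manifest, d2$manifest)
})

test_that("category 1 images carry no lesion primitives", {
  ds <- small_dataset()
  cat1 <- which(ds$manifest$label == 1)
  for (i in cat1) expect_equal(nrow(ds$lesions[[i]]), 0)
})

test_that("soft drusen are larger than hard drusen by construction", {
  ds <- small_dataset()
  les <- do.call(rbind, ds$lesions)
  hard <- les$radius[les$type == "hard_drusen"]
  soft <- les$radius[les$type == "soft_drusen"]
  expect_gt(length(hard), 0)
  expect_gt(length(soft), 0)
  expect_gt(mean(soft), mean(hard))
  expect_gt(min(soft), max(hard) * 0.9)
})

test_that("degrade at strength 0 is the identity", {
  img <- small_dataset()$images[[1]]
  for (a in c("blur", "shadow", "haze", "arc"))
    expect_identical(degrade(img$pixels, a, 0), img$pixels)
  expect_error(degrade(img$pixels, "vignette", 0.5), "unknown artifact")
})

test_that("full haze halves the RMS contrast and is monotone", {
  img <- small_dataset()$images[[2]]
  base <- rms_contrast(img$pixels)
  hazed <- vapply(c(0.25, 0.5, 0.75, 1),
                  function(s) rms_contrast(degrade(img$pixels, "haze", s)),
                  numeric(1))
  expect_lt(hazed[4], 0.5 * base)
  expect_true(all(diff(hazed) < 0))
  blur <- vapply(c(0.3, 0.6, 1),
                 function(s) rms_contrast(degrade(img$pixels, "blur", s)),
                 numeric(1))
  expect_true(all(diff(c(base, blur)) < 0))
})

test_that("Gaussian blur obeys the semigroup property", {
  img <- small_dataset()$images[[3]]
  s1 <- 0.4; s2 <- 0.3
  twice <- degrade(degrade(img$pixels, "blur", s1), "blur", s2)
  once <- degrade(img$pixels, "blur", sqrt(s1^2 + s2^2))
  rmse <- sqrt(mean((twice - once)^2))
  expect_lt(rmse, 1)  # within one intensity level
})

test_that("a written dataset round-trips through the manifest", {
  dir <- withr::local_tempdir()
  spec <- synth_spec(n_per_cell = matrix(1, 2, 4), image_side = 96,
                     seed = 19)
  ds <- generate_dataset(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "lesions.json")))
  back <- read_dataset(file.path(dir, "manifest.csv"))
  expect_length(back, 8)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$pixels, ds$images[[i]]$pixels)
    expect_equal(back[[i]]$label, ds$images[[i]]$label)
    # detected circle close to the generating geometry
    expect_lt(abs(back[[i]]$radius - ds$images[[i]]$radius), 3)
    expect_lt(max(abs(back[[i]]$center - ds$images[[i]]$center)), 3)
  }
})
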