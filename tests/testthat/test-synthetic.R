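test_that("samples are pure functions of (seed, index)", {
  cfg <- synthetic_config(n_images = 4, image_size = c(32, 32), seed = 11)
  s1 <- generate_sample(cfg, 2)
  s2 <- generate_sample(cfg, 2)
  expect_identical(s1, s2)
  s3 <- generate_sample(cfg, 3)
  expect_false(identical(s1$image, s3$image))
  cfg2 <- synthetic_config(n_images = 4, image_size = c(32, 32), seed = 12)
  expect_false(identical(generate_sample(cfg2, 2)$image, s1$image))
  # generation does not disturb the caller's RNG stream
  set.seed(99); a <- runif(3)
  set.seed(99); invisible(generate_sample(cfg, 1)); b <- runif(3)
  expect_identical(a, b)
})

test_that("masks are nonempty, binary, and track the configured extremes", {
  cfg <- synthetic_config(n_images = 2, image_size = c(32, 32), seed = 5)
  s <- generate_sample(cfg, 1)
  expect_true(all(s$mask %in% c(0, 1)))
  expect_gt(sum(s$mask), 0)
  expect_equal(dim(s$image)[1:2], dim(s$mask))
  # a radius far beyond the frame fills the mask completely
  big <- synthetic_config(n_images = 1, image_size = c(24, 24), seed = 5,
                          lesions_per_image = c(1, 1), radius_range = c(3, 3))
  expect_true(all(generate_sample(big, 1)$mask == 1))
})

test_that("zero contrast makes the image independent of the mask", {
  # with contrast 0 the foreground term is multiplied out, so a change that
  # affects only the foreground rendering (the boundary blur) cannot alter
  # the image, although it still owns the same mask
  c1 <- synthetic_config(n_images = 1, image_size = c(48, 48), seed = 21,
                         contrast = 0, blur_sigma = 0.5)
  c2 <- synthetic_config(n_images = 1, image_size = c(48, 48), seed = 21,
                         contrast = 0, blur_sigma = 4)
  for (i in 1:3) {
    s1 <- generate_sample(c1, i); s2 <- generate_sample(c2, i)
    expect_identical(s1$image, s2$image)
    expect_identical(s1$mask, s2$mask)
  }
  # and the lesion leaves no intensity footprint on average
  diffs <- vapply(1:20, function(i) {
    s <- generate_sample(c1, i)
    if (sum(s$mask) == 0 || mean(s$mask) > 0.5) return(NA_real_)
    mean(s$image[, , 1][s$mask == 1]) - mean(s$image[, , 1][s$mask == 0])
  }, numeric(1))
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.05)
})

test_that("foreground fraction tracks its analytic expectation", {
  r1 <- 0.08; r2 <- 0.15
  cfg <- synthetic_config(n_images = 200, image_size = c(48, 48), seed = 31,
                          lesions_per_image = c(1, 1),
                          radius_range = c(r1, r2))
  fr <- mean(vapply(1:200, function(i) mean(generate_sample(cfg, i)$mask),
                    numeric(1)))
  m <- 48
  expected <- pi * (m^2 * (r1^2 + r1 * r2 + r2^2) / 3) * 0.8 / (48 * 48)
  expect_lt(abs(fr - expected) / expected, 0.2)
})

test_that("PNG write and read round-trip exactly", {
  cfg <- synthetic_config(n_images = 3, image_size = c(24, 24), seed = 41)
  dir <- tempfile()
  ids <- write_dataset(cfg, dir)
  expect_length(ids, 3)
  back <- read_dataset(dir)
  orig <- generate_dataset(cfg)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$image, orig[[i]]$image, tolerance = 1e-12)
    expect_identical(back[[i]]$mask, orig[[i]]$mask)
  }
  expect_length(attr(back, "errors"), 0)
  # empty dataset: no error
  d0 <- tempfile()
  write_dataset(synthetic_config(n_images = 0), d0)
  expect_length(read_dataset(d0), 0)
})

test_that("defective directories are reported faithfully", {
  cfg <- synthetic_config(n_images = 2, image_size = c(16, 16), seed = 51)
  dir <- tempfile()
  ids <- write_dataset(cfg, dir)
  # a mask with a non-binary value is a validation error naming the file
  bad <- matrix(0, 16, 16); bad[3, 3] <- 128 / 255
  png::writePNG(bad, file.path(dir, "masks", paste0(ids[1], ".png")))
  expect_error(read_dataset(dir), paste0(ids[1], ".*not binary|not binary"))
  # a missing mask skips the sample with a warning and an error entry
  png::writePNG(matrix(0.5, 16, 16), file.path(dir, "images", "orphan.png"))
  file.remove(file.path(dir, "masks", paste0(ids[1], ".png")))
  w <- testthat::capture_warnings(res <- read_dataset(dir))
  expect_match(w, "no matching mask", all = TRUE)
  expect_length(res, 1)
  expect_match(attr(res, "errors"), "orphan|missing", all = FALSE)
})

test_that("identity augmentation is a no-op and right angles compose", {
  cfg <- synthetic_config(n_images = 1, image_size = c(32, 32), seed = 61)
  s <- generate_sample(cfg, 1)
  expect_identical(augment(s, aug_config(), seed = 1), s)
  r90 <- augment(s, aug_config(rotate = c(90, 90)), seed = 1)
  r180a <- augment(r90, aug_config(rotate = c(90, 90)), seed = 1)
  r180b <- augment(s, aug_config(rotate = c(180, 180)), seed = 1)
  expect_identical(r180a$mask, r180b$mask)
  expect_identical(r180a$image, r180b$image)
})

test_that("augmentation keeps masks binary and image/mask synchronised", {
  cfg <- synthetic_config(n_images = 1, image_size = c(48, 48), seed = 71,
                          contrast = 1, noise_sigma = 0, blur_sigma = 0.5,
                          lesions_per_image = c(1, 1),
                          radius_range = c(0.1, 0.15))
  s <- generate_sample(cfg, 1)
  ac <- aug_config(rotate = c(35, 35))
  a <- augment(s, ac, seed = 3)
  expect_true(all(a$mask %in% c(0, 1)))
  # intensity-weighted centroid and mask centroid move together
  # weight by intensity well above the background band, so only the lesion
  # (contrast 1 on a ~0.45 background) contributes
  w0 <- pmax(s$image[, , 1] - 0.8, 0)
  w1 <- pmax(a$image[, , 1] - 0.8, 0)
  shift_img <- mask_centroid(w1) - mask_centroid(w0)
  shift_mask <- mask_centroid(a$mask) - mask_centroid(s$mask)
  expect_lt(max(abs(shift_img - shift_mask)), 1)
  # crop + resize keeps sizes and binarity
  b <- augment(s, aug_config(crop = 0.6), seed = 4)
  expect_equal(dim(b$image), dim(s$image))
  expect_true(all(b$mask %in% c(0, 1)))
})
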