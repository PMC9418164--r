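test_that("fixture generation is a pure function of its config", {
  cfg <- fixture_config(n_images = 3, image_size = c(24, 24), seed = 7)
  a <- generate_fixture_set(cfg)
  b <- generate_fixture_set(cfg)
  expect_identical(a, b)
  c <- generate_fixture_set(fixture_config(n_images = 3,
                                           image_size = c(24, 24), seed = 8))
  expect_false(identical(a, c))
  # generation does not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(2)
  set.seed(1); invisible(generate_fixture_set(cfg)); r2 <- runif(2)
  expect_identical(r1, r2)
})

test_that("undeformed single blobs are ellipses of the expected area", {
  cfg <- fixture_config(n_images = 6, image_size = c(64, 64),
                        blobs_per_image = c(1, 1),
                        blob_radius_frac = c(0.25, 0.25),
                        deform_amplitude = 0, background_noise_sd = 0,
                        seed = 3)
  for (s in generate_fixture_set(cfg)) {
    a <- 0.25 * 64; b <- 0.25 * 64        # fixed radius range -> known axes
    expect_lt(abs(sum(s$mask) - pi * a * b) / (pi * a * b), 0.05)
  }
})

test_that("with full contrast and no noise, a luminance threshold recovers the mask exactly", {
  cfg <- fixture_config(n_images = 4, image_size = c(48, 48),
                        intensity_contrast = 1, background_noise_sd = 0,
                        seed = 9)
  for (s in generate_fixture_set(cfg)) {
    lum <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    th <- (min(lum) + max(lum)) / 2
    expect_identical((lum > th) * 1, s$mask)
  }
})

test_that("images stay in [0, 1], masks stay binary and non-empty", {
  set.seed(1)
  for (s in generate_fixture_set(fixture_config(n_images = 6, seed = 2))) {
    expect_true(min(s$image) >= 0 && max(s$image) <= 1)
    expect_true(all(s$mask %in% c(0, 1)))
    expect_gt(sum(s$mask), 0)
  }
})

test_that("the foreground is learnable by a trivial threshold classifier on noise-free fixtures", {
  cfg <- fixture_config(n_images = 12, background_noise_sd = 0, seed = 4)
  dices <- vapply(generate_fixture_set(cfg), function(s) {
    lum <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    th <- EBImage::otsu(EBImage::Image(lum), range = c(0, 1))
    evaluate(list((lum > th) * 1), list(s$mask))$dice
  }, numeric(1))
  expect_gt(mean(dices), 0.8)
})

test_that("difficulty report summarises foreground, blobs and contrast", {
  img <- array(0.4, c(64, 64, 3))
  mask <- matrix(0, 64, 64); mask[1:32, 1:32] <- 1   # 1024 of 4096 px
  img[, , 1][mask == 1] <- 0.9
  s <- image_sample("manual", img, mask)
  rep1 <- fixture_difficulty_report(list(s))
  expect_equal(rep1$per_sample$foreground_fraction, 0.25)
  empty <- image_sample("none", array(0.4, c(8, 8, 3)), matrix(0, 8, 8))
  expect_warning(rep2 <- fixture_difficulty_report(list(empty)), "empty")
  expect_equal(rep2$per_sample$foreground_fraction, 0)
  expect_true(rep2$per_sample$empty)
  expect_error(fixture_difficulty_report(list(image_sample("x", img))), "mask")
})

test_that("blob-count histogram support stays within the configured range", {
  cfg <- fixture_config(n_images = 30, image_size = c(48, 48),
                        blobs_per_image = c(1, 3), seed = 6)
  rep <- fixture_difficulty_report(generate_fixture_set(cfg))
  counts <- as.integer(names(rep$blob_histogram))
  expect_true(all(counts >= 1 & counts <= 3))
})

test_that("degenerate geometry is rejected", {
  expect_error(fixture_config(blob_radius_frac = c(0.3, 0.6)), "exceeds")
  expect_error(fixture_config(blob_radius_frac = c(0.3, 0.2)), "minima")
  expect_error(fixture_config(n_images = 0), "n_images")
  expect_error(fixture_config(intensity_contrast = 0), "contrast")
})

test_that("written fixtures round-trip through the dataset reader", {
  dir <- tempfile("fixt")
  samples <- easy_fixtures(n = 3, size = 32)
  write_fixture_dataset(samples, dir)
  loaded <- load_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                         target_size = c(32, 32))
  expect_length(loaded, 3)
  expect_identical(vapply(loaded, function(s) s$id, character(1)),
                   vapply(samples, function(s) s$id, character(1)))
  for (i in seq_along(loaded)) {
    expect_identical(loaded[[i]]$mask, samples[[i]]$mask)   # binarity survives
    expect_lt(max(abs(loaded[[i]]$image - samples[[i]]$image)), 1 / 255)
  }
})
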