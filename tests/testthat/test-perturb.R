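test_that("right-angle rotations compose to the exact identity", {
  set.seed(1)
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  sp <- perturbation_spec("rotation", angle = 90)
  out <- img
  for (i in 1:4) out <- apply_perturbation(out, sp)
  expect_identical(out, img)
  for (ang in c(90, 180, 270)) {
    sp <- perturbation_spec("rotation", angle = ang)
    expect_identical(align_prediction(apply_perturbation(img, sp), sp), img)
  }
})

test_that("Gaussian noise is seeded, clipped, and identity at sd = 0", {
  set.seed(2)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(apply_perturbation(img, perturbation_spec("gaussian_noise", sd = 0)), img)
  sp <- perturbation_spec("gaussian_noise", sd = 0.1, seed = 99)
  a <- apply_perturbation(img, sp)
  b <- apply_perturbation(img, sp)
  expect_identical(a, b)
  expect_true(min(a) >= 0 && max(a) <= 1)
  expect_gt(max(abs(a - img)), 0)
  # noise does not disturb the caller's RNG stream
  set.seed(5); r1 <- runif(3)
  set.seed(5); invisible(apply_perturbation(img, sp)); r2 <- runif(3)
  expect_identical(r1, r2)
  # alignment is a no-op for noise
  expect_identical(align_prediction(img[, , 1], sp), img[, , 1])
})

test_that("scaling at factor 1 is the identity and inverts approximately otherwise", {
  set.seed(3)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  sp1 <- perturbation_spec("random_scaling", factor = 1)
  expect_lt(max(abs(apply_perturbation(img, sp1) - img)), 1e-6)
  # smooth map: the round trip is exact up to bilinear resampling error
  smooth <- outer(seq(0, 1, length.out = 32), seq(0, 1, length.out = 32),
                  function(a, b) 0.5 + 0.3 * sin(2 * pi * a) * cos(2 * pi * b))
  for (f in c(0.8, 1.25)) {
    sp <- perturbation_spec("random_scaling", factor = f)
    back <- align_prediction(apply_perturbation(smooth, sp), sp)
    expect_lt(mean(abs(back - smooth)), 0.02)
  }
  expect_error(perturbation_spec("random_scaling", factor = 2), "factor")
})

test_that("an equivariant stub network yields zero consistency residual", {
  set.seed(4)
  img <- generate_fixture_set(fixture_config(n_images = 1,
                                             image_size = c(32, 32),
                                             seed = 5))[[1]]$image
  ref <- stub_identity_net(img)
  for (ang in c(90, 180, 270)) {
    sp <- perturbation_spec("rotation", angle = ang)
    aligned <- align_prediction(stub_identity_net(apply_perturbation(img, sp)), sp)
    expect_identical(aligned, ref)
  }
})

test_that("build_bundle wires reference and aligned maps per spec", {
  set.seed(6)
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  specs3 <- list(perturbation_spec("random_scaling", factor = 1.1, seed = 1),
                 perturbation_spec("gaussian_noise", sd = 0.02, seed = 2),
                 perturbation_spec("rotation", angle = 180, seed = 3))
  b3 <- build_bundle(stub_identity_net, img, specs3)
  expect_length(b3$aligned, 3)
  expect_s3_class(b3, "consistency_bundle")
  b1 <- build_bundle(stub_identity_net, img, specs3[2])
  expect_length(b1$aligned, 1)
  # rotation-only bundle of an equivariant net has zero consistency loss
  br <- build_bundle(stub_identity_net, img, specs3[3])
  expect_equal(consistency_loss(br), 0)
  expect_error(build_bundle(stub_identity_net, img, list()), "at least one")
  expect_error(build_bundle(stub_identity_net, img,
                            list(specs3[[2]], specs3[[2]])), "one spec per")
})

test_that("bundles reject shape mismatches", {
  sp <- perturbation_spec("gaussian_noise")
  expect_error(consistency_bundle(matrix(0, 4, 4), list(matrix(0, 5, 5)),
                                  list(sp)), "shape")
  expect_error(consistency_bundle(matrix(0, 4, 4), list(), list(sp)),
               "differ in length")
})

test_that("sampled specs stay inside the documented parameter ranges", {
  set.seed(8)
  for (i in 1:20) {
    sp <- sample_perturbation_specs(c("random_scaling", "rotation"))
    expect_gte(sp[[1]]$factor, 0.8); expect_lte(sp[[1]]$factor, 1.25)
    expect_true(sp[[2]]$angle %in% c(90, 180, 270))
  }
})
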