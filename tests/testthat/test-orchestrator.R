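# Easy, low-noise fixtures: orchestrator tests exercise the mechanics, not
# segmentation difficulty.
small_split <- function(n = 14, n_labeled = 6, size = 32, seed = 9) {
  samples <- generate_fixture_set(fixture_config(
    n_images = n, image_size = c(size, size), intensity_contrast = 0.9,
    background_noise_sd = 0.02, deform_amplitude = 0.1,
    blob_radius_frac = c(0.15, 0.3), seed = seed))
  split_dataset(samples, c(0.8, 0.1, 0.1), n_labeled = n_labeled, seed = seed)
}

test_that("a short cl_cupl run trains end to end and writes its artifacts", {
  sp <- small_split()
  cfg <- quick_config("cl_cupl", sp, epochs = 2)
  res <- train(cfg)
  expect_s3_class(res, "training_result")
  expect_true(all(is.finite(res$loss_history$supervised)))
  expect_true(all(is.finite(res$loss_history$overall)))
  steps_per_epoch <- ceiling(length(sp$labeled) / (cfg$batch_size %/% 2))
  expect_equal(nrow(res$loss_history), cfg$epochs * steps_per_epoch)
  expect_equal(nrow(res$eval_per_epoch), cfg$epochs)
  expect_true(file.exists(res$best_checkpoint))
  expect_true(file.exists(file.path(res$out_dir, "loss_log.csv")))
  expect_true(file.exists(file.path(res$out_dir, "manifest.tsv")))
  expect_equal(res$cupl_rounds, 1L)  # epochs 2, warmup 1, interval 1
  unlink(res$out_dir, recursive = TRUE)
})

test_that("training is bit-reproducible under the same config", {
  sp <- small_split(n = 10, n_labeled = 4)
  cfg <- quick_config("cl", sp, epochs = 2)
  h1 <- train(cfg)$loss_history
  h2 <- train(cfg)$loss_history
  expect_identical(h1, h2)
})

test_that("the labeled and unlabeled streams never mix", {
  sp <- small_split()
  res_b <- train(quick_config("baseline", sp, epochs = 2))
  expect_equal(unname(res_b$counters["consistency_images"]), 0)
  expect_equal(unname(res_b$counters["pseudo_images"]), 0)
  expect_equal(unname(res_b$counters["supervised_images"]),
               2 * length(sp$labeled))
  res_c <- train(quick_config("cl", sp, epochs = 2))
  expect_gt(unname(res_c$counters["consistency_images"]), 0)
  expect_equal(unname(res_c$counters["supervised_images"]),
               2 * length(sp$labeled))
})

test_that("the lambda ramp starts at zero and never decreases", {
  sp <- small_split(n = 10, n_labeled = 4)
  res <- train(quick_config("cl", sp, epochs = 3))
  lam <- res$loss_history$lambda
  expect_equal(lam[1], 0)
  by_epoch <- tapply(lam, res$loss_history$epoch, unique)
  expect_true(all(diff(unlist(by_epoch)) >= -1e-12))
})

test_that("CUPL refresh cadence follows warmup and interval", {
  sp <- small_split(n = 12, n_labeled = 4)
  cfg <- quick_config("cl_cupl", sp, epochs = 5)
  cfg$cupl <- cupl_config(warmup_epochs = 2L, update_interval_epochs = 2L)
  res <- train(cfg)
  # generation at epochs 2 and 4 -> floor((5 - 2) / 2) + 1 = 2 rounds
  expect_equal(res$cupl_rounds, 2L)
  res0 <- train(quick_config("cl", sp, epochs = 2))
  expect_equal(res0$cupl_rounds, 0L)
})

test_that("checkpoint evaluation is deterministic and validates inputs", {
  sp <- small_split(n = 10, n_labeled = 4)
  res <- train(quick_config("baseline", sp, epochs = 2))
  e1 <- evaluate_checkpoint(res$best_checkpoint, sp$test)
  e2 <- evaluate_checkpoint(res$best_checkpoint, sp$test)
  expect_identical(e1$per_image, e2$per_image)
  expect_error(evaluate_checkpoint(res$best_checkpoint, list()), "empty")
  expect_error(evaluate_checkpoint(tempfile(), sp$test), "not found")
  unlink(res$out_dir, recursive = TRUE)
})

test_that("a converged toy run overfits its own labeled set", {
  sp <- small_split(n = 10, n_labeled = 6)
  cfg <- quick_config("baseline", sp, epochs = 40)
  res <- train(cfg)
  on_train <- evaluate_checkpoint(res$best_checkpoint, sp$labeled)
  on_test <- evaluate_checkpoint(res$best_checkpoint, sp$test)
  expect_gte(on_train$dice, on_test$dice)
  expect_gt(on_train$dice, 0.6)
  unlink(res$out_dir, recursive = TRUE)
})

test_that("configs are validated before any training happens", {
  sp <- small_split(n = 10, n_labeled = 4)
  expect_error(run_config(regime = "cl_cupl", data = sp, cupl = NULL), "cupl")
  cfg <- quick_config("cl", fixture_config(n_images = 10,
                                           image_size = c(32, 32), seed = 1),
                      epochs = 1)
  cfg$n_labeled <- 99L
  expect_error(train(cfg), "exceeds")
})

test_that("YAML run configs round-trip through the reader", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "regime: cl",
    "epochs: 3",
    "batch_size: 8",
    "lr: 0.001",
    "seed: 4",
    "n_labeled: 5",
    "model:",
    "  levels: 3",
    "  base_channels: 2",
    "  input_size: [32, 32]",
    "cupl:",
    "  warmup_epochs: 1",
    "fixtures:",
    "  n_images: 12",
    "  image_size: [32, 32]",
    "  seed: 2"), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$regime, "cl")
  expect_equal(cfg$epochs, 3L)
  expect_equal(cfg$model$base_channels, 2L)
  expect_s3_class(cfg$data, "fixture_config")
})
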