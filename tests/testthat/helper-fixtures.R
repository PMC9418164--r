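# Shared fixtures and stub networks for the test suite.

# A small noise-free, high-contrast fixture set (easy to segment).
easy_fixtures <- function(n = 8, size = 32, seed = 7, ...) {
  generate_fixture_set(fixture_config(
    n_images = n, image_size = c(size, size), background_noise_sd = 0,
    intensity_contrast = 1, seed = seed, ...))
}

# Stub network: the identity on images, reduced to a single-channel map by
# channel averaging (a linear op, so it commutes with the geometric
# perturbations).
stub_identity_net <- function(image) {
  if (length(dim(image)) == 3L) (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  else image
}

# Stub network returning a constant map.
stub_const_net <- function(value) {
  force(value)
  function(image) matrix(value, nrow = dim(image)[1], ncol = dim(image)[2])
}

tiny_model <- function(size = 32, levels = 3L, base = 2L, ...) {
  model_config(levels = levels, base_channels = base,
               input_size = c(size, size), ...)
}

# A quick low-resolution training config used by orchestrator tests.
quick_config <- function(regime, data, epochs = 2L, seed = 5L, ...) {
  run_config(regime = regime, model = tiny_model(32, base = 2L), data = data,
             epochs = epochs, batch_size = 8L, lr = 1e-2, ramp_epochs = 2L,
             cupl = cupl_config(warmup_epochs = 1L, update_interval_epochs = 1L),
             alpha = 0.9,  # EMA horizon scaled to the short step budget
             seed = seed, ...)
}

random_mask <- function(h, w, p = 0.3) matrix(rbinom(h * w, 1, p), h, w)
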