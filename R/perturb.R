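# Input perturbations for consistency training: random scaling, Gaussian
# noise, and right-angle rotation.  Rotations are restricted to multiples of
# 90 degrees so that applying and inverting them is exact on the pixel grid;
# scaling resamples bilinearly and returns to the original frame by center
# crop (zoom in) or edge-replicated pad (zoom out), so its inverse is exact
# only up to resampling error away from the border.

#' Describe one input perturbation
#'
#' @param kind `"random_scaling"`, `"gaussian_noise"` or `"rotation"`.
#' @param factor Scale factor in `[0.8, 1.25]` (scaling only).
#' @param sd Noise standard deviation on the `[0, 1]` intensity scale
#'   (noise only; default 0.03).
#' @param angle Rotation angle, one of 90, 180, 270 (rotation only).
#' @param seed Seed for the noise field; required so the same spec replays
#'   the identical perturbation.
#' @return A `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("random_scaling", "gaussian_noise", "rotation"),
                              factor = NULL, sd = 0.03, angle = NULL,
                              seed = 1L) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, seed = as.integer(seed))
  if (kind == "random_scaling") {
    if (is.null(factor)) factor <- 1
    if (factor < 0.8 || factor > 1.25)
      stopf("scaling factor must be in [0.8, 1.25], got %g", factor)
    spec$factor <- factor
  } else if (kind == "gaussian_noise") {
    if (sd < 0) stopf("noise sd must be >= 0")
    spec$sd <- sd
  } else {
    if (is.null(angle)) angle <- 90
    if (!angle %in% c(90, 180, 270))
      stopf("rotation angle must be one of 90, 180, 270, got %g", angle)
    spec$angle <- angle
  }
  structure(spec, class = "perturbation_spec")
}

# Draw one spec per requested kind with parameters sampled from the caller's
# RNG stream (factor uniform on [0.8, 1.25], angle uniform on {90, 180, 270}).
sample_perturbation_specs <- function(kinds, noise_sd = 0.03) {
  lapply(kinds, function(k) {
    switch(k,
      random_scaling = perturbation_spec("random_scaling",
                                         factor = runif(1, 0.8, 1.25),
                                         seed = sample.int(2147483646L, 1)),
      gaussian_noise = perturbation_spec("gaussian_noise", sd = noise_sd,
                                         seed = sample.int(2147483646L, 1)),
      rotation = perturbation_spec("rotation",
                                   angle = sample(c(90, 180, 270), 1),
                                   seed = sample.int(2147483646L, 1)),
      stopf("unknown perturbation kind: %s", k))
  })
}

# 90-degree counterclockwise rotation of a matrix, exact on the grid.
rot90m <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

rotate_array <- function(x, k) {
  k <- k %% 4L
  if (k == 0L) return(x)
  if (is.matrix(x)) {
    for (i in seq_len(k)) x <- rot90m(x)
    return(x)
  }
  d <- dim(x)
  slices <- lapply(seq_len(prod(d[-(1:2)])), function(s) {
    m <- array(x, c(d[1], d[2], prod(d[-(1:2)])))[, , s]
    for (i in seq_len(k)) m <- rot90m(m)
    m
  })
  out <- array(unlist(slices), c(dim(slices[[1]]), d[-(1:2)]))
  out
}

resize_array <- function(x, H2, W2, nearest = FALSE) {
  img <- EBImage::Image(x, colormode = if (length(dim(x)) == 3)
    EBImage::Color else EBImage::Grayscale)
  out <- EBImage::resize(img, w = H2, h = W2,
                         filter = if (nearest) "none" else "bilinear")
  a <- as.array(out)
  dim(a) <- if (length(dim(x)) == 3) c(H2, W2, dim(x)[3]) else c(H2, W2)
  a
}

# Center-crop or edge-replicate-pad the first two dims back to H x W.
crop_or_pad <- function(x, H, W) {
  d <- dim(x)
  if (d[1] >= H) {
    off <- (d[1] - H) %/% 2
    x <- if (length(d) == 3) x[(off + 1):(off + H), , , drop = FALSE]
         else x[(off + 1):(off + H), , drop = FALSE]
  } else {
    pre <- (H - d[1]) %/% 2; post <- H - d[1] - pre
    ridx <- c(rep(1L, pre), seq_len(d[1]), rep(d[1], post))
    x <- if (length(d) == 3) x[ridx, , , drop = FALSE] else x[ridx, , drop = FALSE]
  }
  d <- dim(x)
  if (d[2] >= W) {
    off <- (d[2] - W) %/% 2
    x <- if (length(d) == 3) x[, (off + 1):(off + W), , drop = FALSE]
         else x[, (off + 1):(off + W), drop = FALSE]
  } else {
    pre <- (W - d[2]) %/% 2; post <- W - d[2] - pre
    cidx <- c(rep(1L, pre), seq_len(d[2]), rep(d[2], post))
    x <- if (length(d) == 3) x[, cidx, , drop = FALSE] else x[, cidx, drop = FALSE]
  }
  x
}

# Geometric part of a perturbation applied to any map (image or probability
# map); this is what transformation consistency applies to the reference
# prediction.
perturb_geom <- function(x, spec) {
  switch(spec$kind,
    rotation = rotate_array(x, spec$angle %/% 90L),
    random_scaling = {
      d <- dim(x)
      if (abs(spec$factor - 1) < 1e-12) return(x)
      H2 <- max(1L, as.integer(round(d[1] * spec$factor)))
      W2 <- max(1L, as.integer(round(d[2] * spec$factor)))
      crop_or_pad(resize_array(x, H2, W2), d[1], d[2])
    },
    gaussian_noise = x,
    stopf("unknown perturbation kind: %s", spec$kind))
}

#' Apply a perturbation to an image
#'
#' @param image `H x W` or `H x W x C` array with values in `[0, 1]`.
#' @param spec A [perturbation_spec()].
#' @return Perturbed array of the same shape (noise output is clipped back to
#'   `[0, 1]`).
#' @export
apply_perturbation <- function(image, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (spec$kind == "gaussian_noise") {
    if (spec$sd == 0) return(image)
    noise <- with_seed(spec$seed, array(rnorm(length(image), sd = spec$sd),
                                        dim = dim(image)))
    return(pmin(pmax(image + noise, 0), 1))
  }
  perturb_geom(image, spec)
}

#' Align a prediction made on a perturbed input back to the reference frame
#'
#' Rotations are inverted exactly; scaling is inverted by the reverse
#' resample (crop the padded region / re-embed the cropped region), which is
#' exact only up to bilinear resampling error; Gaussian noise needs no
#' alignment.
#'
#' @param pred Probability map (`H x W` or `H x W x C`) produced on the
#'   perturbed input.
#' @param spec The [perturbation_spec()] that produced the input.
#' @return Map in the reference frame.
#' @export
align_prediction <- function(pred, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  switch(spec$kind,
    gaussian_noise = pred,
    rotation = rotate_array(pred, 4L - spec$angle %/% 90L),
    random_scaling = {
      d <- dim(pred)
      f <- spec$factor
      if (abs(f - 1) < 1e-12) return(pred)
      H2 <- max(1L, as.integer(round(d[1] * f)))
      W2 <- max(1L, as.integer(round(d[2] * f)))
      if (f > 1) {
        # forward: upscale then crop; inverse: re-embed into the upscaled
        # frame (border filled by edge replication) and downscale
        canvas <- crop_or_pad(pred, H2, W2)
        resize_array(canvas, d[1], d[2])
      } else {
        # forward: downscale then pad; inverse: crop the live window and
        # upscale
        live <- crop_or_pad(pred, H2, W2)
        resize_array(live, d[1], d[2])
      }
    },
    stopf("unknown perturbation kind: %s", spec$kind))
}

#' Reference and aligned perturbed predictions for one image
#'
#' @param net A `segnet`, or any function mapping an image to a probability
#'   map (useful for stub networks in tests).
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param specs List of 1-3 [perturbation_spec()]s, at most one per kind.
#' @return A `consistency_bundle` with `reference`, `aligned` (same order as
#'   `specs`), and `specs`.
#' @export
build_bundle <- function(net, image, specs) {
  if (length(specs) < 1L) stopf("at least one perturbation spec is required")
  if (length(specs) > 3L) stopf("at most three perturbation specs are allowed")
  kinds <- vapply(specs, function(s) s$kind, character(1))
  if (anyDuplicated(kinds)) stopf("at most one spec per perturbation kind")
  fn <- if (is.function(net)) net else function(img) {
    predict(net, img)$fused[, , 1]
  }
  reference <- fn(image)
  aligned <- lapply(specs, function(sp)
    align_prediction(fn(apply_perturbation(image, sp)), sp))
  consistency_bundle(reference, aligned, specs)
}

#' Construct a consistency bundle
#'
#' @param reference Reference probability map.
#' @param aligned List of aligned perturbed probability maps.
#' @param specs The corresponding perturbation specs.
#' @return A `consistency_bundle`.
#' @export
consistency_bundle <- function(reference, aligned, specs) {
  if (length(aligned) != length(specs))
    stopf("aligned maps (%d) and specs (%d) differ in length",
          length(aligned), length(specs))
  for (a in aligned)
    if (!identical(dim(a), dim(reference)))
      stopf("aligned map shape differs from the reference")
  structure(list(reference = reference, aligned = aligned, specs = specs),
            class = "consistency_bundle")
}
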