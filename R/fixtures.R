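# Synthetic polyp-like fixtures: RGB images with one or more smooth,
# deformed-ellipse foreground regions tinted toward red/pink over a textured
# background, plus exact binary masks.  The generator makes every stage of
# the framework exercisable without external data; it emulates the geometry
# (blobs of varying shape, size and scale) of endoscopic polyp datasets, not
# their photometric realism.

#' Fixture generator configuration
#'
#' @param n_images Number of image/mask pairs.
#' @param image_size `(height, width)` in pixels.
#' @param blobs_per_image `(min, max)` number of polyp blobs per image.
#' @param blob_radius_frac `(min, max)` blob semi-axis as a fraction of the
#'   image side.
#' @param intensity_contrast Fraction in `(0, 1]` by which foreground colour
#'   is pulled from the background towards the polyp tint; 1 = full tint.
#' @param background_noise_sd Per-pixel i.i.d. Gaussian noise sd on the
#'   `[0, 1]` scale.
#' @param deform_amplitude Amplitude of the low-frequency radial boundary
#'   perturbation; 0 gives exact ellipses.
#' @param seed Seed; the whole set is a pure function of the config.
#' @return A `fixture_config`.
#' @export
fixture_config <- function(n_images = 16L, image_size = c(64L, 64L),
                           blobs_per_image = c(1L, 3L),
                           blob_radius_frac = c(0.08, 0.24),
                           intensity_contrast = 0.3,
                           background_noise_sd = 0.14,
                           deform_amplitude = 0.25, seed = 1L) {
  if (n_images < 1L) stopf("n_images must be >= 1")
  if (blobs_per_image[1] > blobs_per_image[2] ||
      blob_radius_frac[1] > blob_radius_frac[2])
    stopf("range minima must not exceed maxima")
  if (any(blob_radius_frac <= 0) || any(blob_radius_frac >= 1))
    stopf("blob_radius_frac must lie in (0, 1)")
  if (2 * blob_radius_frac[2] * (1 + deform_amplitude) >= 1)
    stopf("blob radius range (with deformation) exceeds the image")
  if (intensity_contrast <= 0 || intensity_contrast > 1)
    stopf("intensity_contrast must be in (0, 1]")
  if (background_noise_sd < 0 || deform_amplitude < 0)
    stopf("noise sd and deform amplitude must be >= 0")
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 blobs_per_image = as.integer(blobs_per_image),
                 blob_radius_frac = blob_radius_frac,
                 intensity_contrast = intensity_contrast,
                 background_noise_sd = background_noise_sd,
                 deform_amplitude = deform_amplitude,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

BG_BASE <- c(0.55, 0.35, 0.33)   # pinkish mucosa background
FG_TINT <- c(0.95, 0.62, 0.60)   # brighter, redder polyp tint
TEXTURE_AMPLITUDE <- 0.06

# Smooth low-frequency texture: coarse Gaussian grid upsampled bilinearly.
smooth_texture <- function(H, W, cells = 6L) {
  g <- matrix(rnorm(cells * cells), cells, cells)
  t <- resize_array(g, H, W)
  t <- t / max(1e-9, max(abs(t)))
  t * TEXTURE_AMPLITUDE
}

blob_mask <- function(H, W, cx, cy, a, b, phi, deform, coefs, phases) {
  xs <- matrix(seq_len(H), H, W) - cx
  ys <- matrix(seq_len(W), H, W, byrow = TRUE) - cy
  xr <- cos(phi) * xs + sin(phi) * ys
  yr <- -sin(phi) * xs + cos(phi) * ys
  r <- sqrt((xr / a)^2 + (yr / b)^2)
  if (deform > 0) {
    th <- atan2(yr / b, xr / a)
    rho <- 1
    for (k in seq_along(coefs))
      rho <- rho + deform * coefs[k] * cos((k + 1) * th + phases[k])
    r <= pmax(rho, 0.2)
  } else {
    r <= 1
  }
}

#' Generate a synthetic fixture set
#'
#' Fully deterministic given the config: the same config (including seed)
#' yields byte-identical samples.
#'
#' @param config A [fixture_config()].
#' @return List of `image_sample` objects with exact masks.  Each sample
#'   additionally carries the blob count used (`attr(sample, "n_blobs")`).
#' @export
generate_fixture_set <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  H <- config$image_size[1]; W <- config$image_size[2]
  side <- min(H, W)
  with_seed(config$seed, {
    lapply(seq_len(config$n_images), function(i) {
      tex <- smooth_texture(H, W)
      nb <- if (config$blobs_per_image[1] == config$blobs_per_image[2])
        config$blobs_per_image[1]
      else sample(config$blobs_per_image[1]:config$blobs_per_image[2], 1)
      mask <- matrix(FALSE, H, W)
      for (k in seq_len(nb)) {
        a <- runif(1, config$blob_radius_frac[1], config$blob_radius_frac[2]) * side
        b <- runif(1, config$blob_radius_frac[1], config$blob_radius_frac[2]) * side
        rmax <- max(a, b) * (1 + config$deform_amplitude)
        cx <- runif(1, rmax + 1, H - rmax)
        cy <- runif(1, rmax + 1, W - rmax)
        phi <- runif(1, 0, pi)
        coefs <- runif(3, 0.3, 1)
        phases <- runif(3, 0, 2 * pi)
        mask <- mask | blob_mask(H, W, cx, cy, a, b, phi,
                                 config$deform_amplitude, coefs, phases)
      }
      m <- mask * 1
      img <- array(0, c(H, W, 3))
      for (ch in 1:3) {
        bg <- BG_BASE[ch] + tex
        fg <- BG_BASE[ch] +
          config$intensity_contrast * (FG_TINT[ch] - BG_BASE[ch]) + 0.5 * tex
        img[, , ch] <- (1 - m) * bg + m * fg
      }
      if (config$background_noise_sd > 0)
        img <- img + array(rnorm(length(img), sd = config$background_noise_sd),
                           dim = dim(img))
      img <- pmin(pmax(img, 0), 1)
      s <- image_sample(id = sprintf("fix%04d", i), image = img, mask = m,
                        source_path = "<synthetic>",
                        original_size = c(H, W))
      attr(s, "n_blobs") <- nb
      s
    })
  })
}

#' Summarise fixture difficulty
#'
#' @param samples List of `image_sample`s, all with masks.
#' @return List with `per_sample` (id, foreground fraction, connected blob
#'   count, foreground-background luminance contrast, empty flag),
#'   `foreground_fraction` summary stats, and `blob_histogram` (table of
#'   connected-component counts).
#' @export
fixture_difficulty_report <- function(samples) {
  rows <- lapply(samples, function(s) {
    if (is.null(s$mask)) stopf("sample %s has no mask", s$id)
    m <- s$mask
    fg <- mean(m)
    nblob <- if (fg > 0) max(EBImage::bwlabel(m)) else 0L
    lum <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    contrast <- if (fg > 0 && fg < 1) mean(lum[m == 1]) - mean(lum[m == 0])
                else NA_real_
    data.frame(id = s$id, foreground_fraction = fg, n_blobs = nblob,
               contrast = contrast, empty = fg == 0)
  })
  per_sample <- do.call(rbind, rows)
  if (any(per_sample$empty))
    warning(sprintf("%d sample(s) have an empty foreground",
                    sum(per_sample$empty)))
  list(per_sample = per_sample,
       foreground_fraction = summary(per_sample$foreground_fraction),
       blob_histogram = table(per_sample$n_blobs))
}

#' Write fixtures as an image/mask directory dataset
#'
#' Layout matches what [load_dataset()] reads: `<dir>/images/<id>.png` and
#' `<dir>/masks/<id>.png`.
#'
#' @param samples List of `image_sample`s.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture_dataset <- function(samples, dir) {
  img_dir <- file.path(dir, "images"); msk_dir <- file.path(dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    EBImage::writeImage(EBImage::Image(s$image, colormode = EBImage::Color),
                        file.path(img_dir, paste0(s$id, ".png")))
    if (!is.null(s$mask))
      EBImage::writeImage(EBImage::Image(s$mask),
                          file.path(msk_dir, paste0(s$id, ".png")))
  }
  invisible(dir)
}
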