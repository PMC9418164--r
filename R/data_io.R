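# Reading image/mask directory datasets, deterministic splitting, and the
# labeled/unlabeled partition.
#
# Masks are matched to images by file stem.  Images are bilinearly resized to
# the network resolution and normalised to [0, 1]; masks are resized
# nearest-neighbour (preserving binarity) and binarized at 0.5.  Unlabeled
# samples drop their mask from the public record but retain it in a
# `hidden_truth` field that only evaluation code may touch.

#' One image (with optional mask) and its provenance
#'
#' @param id Sample identifier (file stem).
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mask Optional `H x W` binary matrix.
#' @param source_path Where the image came from.
#' @param original_size `(height, width)` before resizing.
#' @return An `image_sample`.
#' @export
image_sample <- function(id, image, mask = NULL, source_path = "",
                         original_size = dim(image)[1:2]) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stopf("image for %s must be H x W x 3, got %s", id,
          paste(dim(image), collapse = "x"))
  if (min(image) < 0 || max(image) > 1)
    stopf("image values for %s must lie in [0, 1]", id)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(image)[1:2]))
      stopf("mask/image spatial dimensions differ for %s", id)
    if (!is_binary(mask)) stopf("mask for %s is not binary", id)
  }
  structure(list(id = id, image = image, mask = mask,
                 source_path = source_path,
                 original_size = as.integer(original_size)),
            class = "image_sample")
}

read_image_rgb <- function(path) {
  img <- tryCatch(EBImage::readImage(path), error = function(e)
    stopf("unreadable image file %s: %s", path, conditionMessage(e)))
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 2L) a <- array(rep(a, 3L), c(d, 3L))
  else if (d[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
  else a <- array(rep(a[, , 1], 3L), c(d[1], d[2], 3L))
  pmin(pmax(a, 0), 1)
}

list_image_files <- function(dir) {
  fs <- list.files(dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                   full.names = TRUE)
  fs[order(sub("\\.[^.]+$", "", basename(fs)), method = "radix")]
}

#' Load an image(/mask) directory dataset
#'
#' @param image_dir Directory of PNG/JPEG images.
#' @param mask_dir Optional directory of masks; every image stem must have a
#'   mask file there.
#' @param target_size `(height, width)` network resolution; images are
#'   resized bilinearly, masks nearest-neighbour and binarized at 0.5.
#' @return List of `image_sample`s in deterministic lexicographic id order.
#' @export
load_dataset <- function(image_dir, mask_dir = NULL,
                         target_size = c(256L, 256L)) {
  if (!dir.exists(image_dir)) stopf("image directory does not exist: %s", image_dir)
  files <- list_image_files(image_dir)
  if (length(files) == 0L) stopf("no PNG/JPEG images found in %s", image_dir)
  mask_files <- NULL
  if (!is.null(mask_dir)) {
    if (!dir.exists(mask_dir)) stopf("mask directory does not exist: %s", mask_dir)
    mf <- list_image_files(mask_dir)
    mask_files <- setNames(mf, sub("\\.[^.]+$", "", basename(mf)))
  }
  lapply(files, function(f) {
    id <- sub("\\.[^.]+$", "", basename(f))
    img <- read_image_rgb(f)
    osize <- dim(img)[1:2]
    if (!identical(as.integer(osize), as.integer(target_size)))
      img <- pmin(pmax(resize_array(img, target_size[1], target_size[2]), 0), 1)
    mask <- NULL
    if (!is.null(mask_dir)) {
      mp <- unname(mask_files[id])
      if (is.na(mp)) stopf("no mask found for image stem '%s'", id)
      m <- tryCatch(as.array(EBImage::readImage(mp)), error = function(e)
        stopf("unreadable mask file %s: %s", mp, conditionMessage(e)))
      if (length(dim(m)) == 3L) m <- m[, , 1]
      if (!identical(as.integer(dim(m)), as.integer(target_size)))
        m <- resize_array(m, target_size[1], target_size[2], nearest = TRUE)
      mask <- (m >= 0.5) * 1
    }
    image_sample(id = id, image = img, mask = mask, source_path = f,
                 original_size = osize)
  })
}

#' Deterministic train/val/test split and labeled/unlabeled partition
#'
#' Shuffling is driven solely by `seed`; the same inputs and seed always give
#' the identical split.  The train pool is partitioned into `n_labeled`
#' labeled samples (masks kept) and the remainder as unlabeled; unlabeled
#' masks move to a `hidden_truth` field reserved for evaluation.
#'
#' @param samples List of `image_sample`s, all with masks.
#' @param ratios `(train, val, test)` fractions summing to 1.
#' @param n_labeled Number of labeled training samples.
#' @param seed Integer split seed.
#' @return A `dataset_split` with `labeled`, `unlabeled`, `val`, `test`, and
#'   `seed`.
#' @export
split_dataset <- function(samples, ratios = c(0.8, 0.1, 0.1), n_labeled,
                          seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stopf("ratios must sum to 1")
  n <- length(samples)
  n_val <- floor(ratios[2] * n)
  n_test <- floor(ratios[3] * n)
  n_train <- n - n_val - n_test
  if (n_labeled > n_train)
    stopf("n_labeled = %d exceeds the train pool of %d samples",
          n_labeled, n_train)
  ids <- vapply(samples, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate sample ids")
  ord <- with_seed(seed, sample.int(n))
  train_idx <- ord[seq_len(n_train)]
  val_idx <- ord[n_train + seq_len(n_val)]
  test_idx <- ord[n_train + n_val + seq_len(n_test)]
  labeled <- samples[train_idx[seq_len(n_labeled)]]
  unlabeled <- lapply(samples[train_idx[setdiff(seq_len(n_train),
                                                seq_len(n_labeled))]],
                      function(s) {
    hidden <- s$mask
    s$mask <- NULL
    s$hidden_truth <- hidden
    s
  })
  structure(list(labeled = labeled, unlabeled = unlabeled,
                 val = samples[val_idx], test = samples[test_idx],
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Write a plain-text dataset manifest
#'
#' One row per sample: id, role (labeled/unlabeled/val/test), source path.
#'
#' @param split A `dataset_split`.
#' @param path Output TSV path.
#' @return The manifest `data.frame`, invisibly.
#' @export
write_manifest <- function(split, path) {
  rows <- do.call(rbind, lapply(c("labeled", "unlabeled", "val", "test"),
    function(role) {
      ss <- split[[role]]
      if (length(ss) == 0L) return(NULL)
      data.frame(id = vapply(ss, function(s) s$id, character(1)),
                 role = role,
                 path = vapply(ss, function(s) s$source_path, character(1)))
    }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

split_ids <- function(split) {
  lapply(split[c("labeled", "unlabeled", "val", "test")],
         function(ss) vapply(ss, function(s) s$id, character(1)))
}
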