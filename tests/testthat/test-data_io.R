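write_pairs <- function(n = 4, h = 40, w = 50, dir = tempfile("ds")) {
  samples <- lapply(seq_len(n), function(i) {
    img <- array(runif(h * w * 3), c(h, w, 3))
    mask <- matrix(0, h, w); mask[5:20, 5:20] <- 1
    image_sample(sprintf("img%02d", i), img, mask)
  })
  write_fixture_dataset(samples, dir)
  dir
}

test_that("loading resizes images bilinearly and masks to exact binarity", {
  set.seed(1)
  dir <- write_pairs(n = 4, h = 40, w = 50)
  ds <- load_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                     target_size = c(32, 32))
  expect_length(ds, 4)
  for (s in ds) {
    expect_equal(dim(s$image), c(32, 32, 3))
    expect_equal(dim(s$mask), c(32, 32))
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(min(s$image) >= 0 && max(s$image) <= 1)
    expect_equal(s$original_size, c(40L, 50L))
  }
  # deterministic lexicographic order by id
  expect_identical(vapply(ds, function(s) s$id, character(1)),
                   sprintf("img%02d", 1:4))
})

test_that("an image already at target size survives up to encoding round-trip", {
  set.seed(2)
  dir <- write_pairs(n = 1, h = 32, w = 32)
  orig <- EBImage::readImage(list.files(file.path(dir, "images"),
                                        full.names = TRUE))
  ds <- load_dataset(file.path(dir, "images"), target_size = c(32, 32))
  expect_lt(max(abs(ds[[1]]$image - as.array(orig))), 1e-9)
})

test_that("grey masks binarize at the 0.5 threshold after decoding", {
  dir <- tempfile("grey")
  dir.create(file.path(dir, "images"), recursive = TRUE)
  dir.create(file.path(dir, "masks"), recursive = TRUE)
  EBImage::writeImage(EBImage::Image(array(0.5, c(8, 8, 3)),
                                     colormode = EBImage::Color),
                      file.path(dir, "images", "a.png"))
  grey <- matrix(rep(c(0, 127, 255) / 255, length.out = 64), 8, 8)
  EBImage::writeImage(EBImage::Image(grey), file.path(dir, "masks", "a.png"))
  ds <- load_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                     target_size = c(8, 8))
  expect_identical(ds[[1]]$mask, (grey >= 0.5) * 1)
})

test_that("loader failures carry the offending stem or path", {
  dir <- write_pairs(n = 2)
  unlink(list.files(file.path(dir, "masks"), full.names = TRUE)[1])
  expect_error(load_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                            target_size = c(16, 16)), "img01")
  expect_error(load_dataset(tempfile("nope")), "exist")
  empty <- tempfile("empty"); dir.create(empty)
  expect_error(load_dataset(empty), "no PNG/JPEG")
})

test_that("splits reproduce, partition cleanly, and hide unlabeled masks", {
  set.seed(3)
  samples <- lapply(1:100, function(i)
    image_sample(sprintf("s%03d", i), array(runif(48), c(4, 4, 3)),
                 random_mask(4, 4)))
  sp1 <- split_dataset(samples, c(0.8, 0.1, 0.1), n_labeled = 5, seed = 21)
  sp2 <- split_dataset(samples, c(0.8, 0.1, 0.1), n_labeled = 5, seed = 21)
  expect_identical(split_ids(sp1), split_ids(sp2))
  ids <- unlist(split_ids(sp1))
  expect_length(ids, 100)
  expect_false(anyDuplicated(ids) > 0)
  expect_length(sp1$labeled, 5)
  expect_length(sp1$unlabeled, 75)
  expect_length(sp1$val, 10)
  expect_length(sp1$test, 10)
  for (s in sp1$unlabeled) {
    expect_null(s$mask)
    expect_false(is.null(s$hidden_truth))
  }
  sp3 <- split_dataset(samples, c(0.8, 0.1, 0.1), n_labeled = 5, seed = 22)
  expect_false(identical(split_ids(sp1), split_ids(sp3)))
})

test_that("the 80:10:10 split at benchmark scale yields 50/750/100/100", {
  samples <- lapply(1:1000, function(i)
    image_sample(sprintf("k%04d", i), array(0.5, c(2, 2, 3)),
                 matrix(0, 2, 2)))
  sp <- split_dataset(samples, c(0.8, 0.1, 0.1), n_labeled = 50, seed = 1)
  expect_length(sp$labeled, 50)
  expect_length(sp$unlabeled, 750)
  expect_length(sp$val, 100)
  expect_length(sp$test, 100)
})

test_that("degenerate partitions and oversubscription are handled", {
  samples <- lapply(1:10, function(i)
    image_sample(sprintf("t%02d", i), array(0.5, c(2, 2, 3)), matrix(1, 2, 2)))
  full <- split_dataset(samples, c(0.8, 0.1, 0.1), n_labeled = 8, seed = 1)
  expect_length(full$unlabeled, 0)
  expect_error(split_dataset(samples, c(0.8, 0.1, 0.1), n_labeled = 9, seed = 1),
               "exceeds")
  expect_error(split_dataset(samples, c(0.7, 0.1, 0.1), n_labeled = 2, seed = 1),
               "sum to 1")
})

test_that("manifests record every sample with its role", {
  samples <- lapply(1:10, function(i)
    image_sample(sprintf("m%02d", i), array(0.5, c(2, 2, 3)), matrix(1, 2, 2)))
  sp <- split_dataset(samples, c(0.8, 0.1, 0.1), n_labeled = 4, seed = 2)
  path <- tempfile(fileext = ".tsv")
  m <- write_manifest(sp, path)
  expect_true(file.exists(path))
  expect_equal(nrow(m), 10)
  expect_setequal(unique(m$role), c("labeled", "unlabeled", "val", "test"))
})
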