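make_unlabeled <- function(n, size = 16, seed = 3) {
  lapply(generate_fixture_set(fixture_config(n_images = n,
                                             image_size = c(size, size),
                                             seed = seed)), function(s) {
    s$hidden_truth <- s$mask
    s$mask <- NULL
    s
  })
}

test_that("pseudo-labels come from the teacher with teacher-student MSE disagreement", {
  unl <- make_unlabeled(3)
  recs <- generate_pseudo_labels(stub_const_net(0.7), stub_const_net(0.7), unl)
  expect_length(recs, 3)
  for (r in recs) {
    expect_true(all(r$current == 0.7))
    expect_equal(r$disagreement, 0)
    expect_false(r$accepted)
  }
  # brute-force disagreement oracle
  teacher <- function(img) img[, , 1]
  student <- function(img) img[, , 2]
  recs2 <- generate_pseudo_labels(teacher, student, unl)
  for (i in seq_along(unl)) {
    manual <- 0
    im <- unl[[i]]$image
    for (p in seq_len(nrow(im) * ncol(im)))
      manual <- manual + (im[, , 1][p] - im[, , 2][p])^2
    expect_equal(recs2[[i]]$disagreement, manual / (nrow(im) * ncol(im)),
                 tolerance = 1e-9)
  }
  expect_identical(generate_pseudo_labels(teacher, student, list()), list())
})

test_that("the confidence filter keeps the lowest-disagreement quantile", {
  recs <- list(pseudo_label_record("a", matrix(0.5, 2, 2), disagreement = 0.01),
               pseudo_label_record("b", matrix(0.5, 2, 2), disagreement = 0.5),
               pseudo_label_record("c", matrix(0.5, 2, 2), disagreement = 0.02))
  out <- confidence_filter(recs, 2 / 3)
  kept <- vapply(Filter(function(r) r$accepted, out), function(r) r$id, character(1))
  expect_setequal(kept, c("a", "c"))
  all_in <- confidence_filter(recs, 1)
  expect_true(all(vapply(all_in, function(r) r$accepted, logical(1))))
  # deterministic lexicographic tie-break at the cutoff
  ties <- list(pseudo_label_record("z", matrix(0.5, 2, 2), disagreement = 0.3),
               pseudo_label_record("y", matrix(0.5, 2, 2), disagreement = 0.3))
  kept_tie <- Filter(function(r) r$accepted, confidence_filter(ties, 0.5))
  expect_equal(kept_tie[[1]]$id, "y")
})

test_that("raising keep_fraction never drops a previously accepted id", {
  set.seed(4)
  recs <- lapply(1:20, function(i)
    pseudo_label_record(sprintf("r%02d", i), matrix(0.5, 2, 2),
                        disagreement = runif(1)))
  prev <- character(0)
  for (kf in c(0.2, 0.4, 0.6, 0.8, 1)) {
    kept <- vapply(Filter(function(r) r$accepted, confidence_filter(recs, kf)),
                   function(r) r$id, character(1))
    expect_true(all(prev %in% kept))
    prev <- kept
  }
})

test_that("averaging follows the midpoint recursion and stays in [0, 1]", {
  prev <- matrix(0.4, 3, 3); cur <- matrix(0.6, 3, 3)
  r <- pseudo_label_record("a", cur, previous = prev, accepted = TRUE)
  up <- average_update(list(r))[[1]]
  expect_equal(up$current, matrix(0.5, 3, 3))
  expect_equal(up$previous, cur)          # pre-update current
  expect_equal(up$round, 1L)
  # agreement is a fixed point
  same <- pseudo_label_record("b", cur, previous = cur, accepted = TRUE)
  expect_equal(average_update(list(same))[[1]]$current, cur)
  # three rounds with a constant fresh map m from initial p
  p0 <- matrix(0.2, 2, 2); m <- matrix(0.9, 2, 2)
  state <- p0
  for (i in 1:3) {
    r <- pseudo_label_record("c", m, previous = state, accepted = TRUE)
    state <- average_update(list(r))[[1]]$current
  }
  expect_equal(state, p0 / 8 + m * (1 / 8 + 1 / 4 + 1 / 2), tolerance = 1e-12)
  expect_true(all(state >= 0 & state <= 1))
  expect_error(average_update(list(pseudo_label_record("d", cur))), "accepted")
})

test_that("averaging contracts toward a stable teacher output", {
  set.seed(6)
  m <- matrix(runif(16), 4, 4)
  state <- matrix(runif(16), 4, 4)
  gap <- max(abs(state - m))
  for (i in 1:6) {
    r <- pseudo_label_record("e", m, previous = state, accepted = TRUE)
    state <- average_update(list(r))[[1]]$current
    g <- max(abs(state - m))
    expect_lte(g, gap + 1e-12)
    gap <- g
  }
  expect_lt(gap, 0.02 * 1)   # halved six times
})

test_that("training targets preserve ids, stay soft, and require acceptance", {
  unl <- make_unlabeled(4)
  recs <- generate_pseudo_labels(stub_const_net(0.3), stub_const_net(0.31), unl)
  recs <- confidence_filter(recs, 1)
  targets <- to_training_targets(recs, unl)
  expect_length(targets, 4)
  expect_setequal(vapply(targets, function(t) t$sample$id, character(1)),
                  vapply(unl, function(s) s$id, character(1)))
  for (t in targets)
    expect_true(min(t$target) >= 0 && max(t$target) <= 1)
  expect_identical(to_training_targets(list(), unl), list())
  bad <- recs; bad[[1]]$accepted <- FALSE
  expect_error(to_training_targets(bad, unl), "accepted")
})

test_that("pseudo-label snapshots write 16-bit soft masks with an index", {
  unl <- make_unlabeled(2)
  recs <- confidence_filter(
    generate_pseudo_labels(stub_const_net(0.42), stub_const_net(0.4), unl), 1)
  dir <- tempfile("snap")
  idx <- write_pseudo_snapshot(recs, dir, round = 1)
  expect_equal(nrow(idx), 2)
  pngs <- list.files(file.path(dir, "round001"), pattern = "\\.png$")
  expect_length(pngs, 2)
  back <- as.array(EBImage::readImage(
    file.path(dir, "round001", pngs[1])))
  expect_lt(max(abs(back - 0.42)), 1e-3)  # well below 8-bit quantisation
})
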