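# Continuous Update of Pseudo-Label (CUPL).
#
# Every refresh round the teacher labels all unlabeled images; only the
# images with low teacher-student disagreement (pixel-mean squared
# difference) are kept, each kept soft label is averaged with its previous
# round's value, and the accepted records join the training stream as
# soft-target cross-entropy examples.  Labels stay soft throughout; they are
# binarized only inside metric computation.

#' CUPL configuration
#'
#' @param update_interval_epochs Pseudo-labels are refreshed every this many
#'   epochs (default 10).
#' @param keep_fraction Fraction of unlabeled images kept per round, lowest
#'   teacher-student disagreement first (default 0.8).
#' @param warmup_epochs Epochs of consistency-only training before the first
#'   pseudo-label generation (default 40).
#' @param average_with_previous Average each refreshed label with its
#'   previous-round value (default `TRUE`).
#' @param binarize_fresh Binarize each freshly generated teacher map at 0.5
#'   before averaging (default `FALSE`: labels stay soft, so averaging keeps
#'   the teacher's confidence information).
#' @return A `cupl_config`.
#' @export
cupl_config <- function(update_interval_epochs = 10L, keep_fraction = 0.8,
                        warmup_epochs = 40L, average_with_previous = TRUE,
                        binarize_fresh = FALSE) {
  if (update_interval_epochs < 1L) stopf("update interval must be >= 1")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stopf("keep_fraction must be in (0, 1]")
  structure(list(update_interval_epochs = as.integer(update_interval_epochs),
                 keep_fraction = keep_fraction,
                 warmup_epochs = as.integer(warmup_epochs),
                 average_with_previous = isTRUE(average_with_previous),
                 binarize_fresh = isTRUE(binarize_fresh)),
            class = "cupl_config")
}

#' One pseudo-label record
#'
#' @param id Unlabeled image id.
#' @param current `H x W` soft label in `[0, 1]`.
#' @param previous Optional previous-round soft label.
#' @param disagreement Teacher-student pixel-mean squared difference.
#' @param accepted Confidence-filter flag.
#' @param round CUPL round counter.
#' @return A `pseudo_label_record`.
#' @export
pseudo_label_record <- function(id, current, previous = NULL,
                                disagreement = 0, accepted = FALSE,
                                round = 0L) {
  if (min(current) < 0 || max(current) > 1)
    stopf("pseudo-label for %s outside [0, 1]", id)
  if (!is.finite(disagreement) || disagreement < 0)
    stopf("disagreement for %s must be finite and >= 0", id)
  structure(list(id = id, current = current, previous = previous,
                 disagreement = disagreement, accepted = isTRUE(accepted),
                 round = as.integer(round)),
            class = "pseudo_label_record")
}

#' Generate pseudo-labels from the teacher
#'
#' `current` is the teacher's fused probability map; `disagreement` is the
#' pixel-mean squared difference between teacher and student maps.  When
#' `prior` records are supplied (the previous round), each new record's
#' `previous` is the prior record's current label.
#'
#' @param teacher A `segnet` (teacher weights) or function image -> map.
#' @param student A `segnet` (student weights) or function image -> map.
#' @param unlabeled List of `image_sample`s without masks.
#' @param prior Optional list of last-round `pseudo_label_record`s.
#' @param batch_size Forward-pass batch size.
#' @param binarize Binarize the teacher map at 0.5 before storing it as the
#'   record's current label (the disagreement score always uses the raw
#'   probability maps).
#' @return List of `pseudo_label_record`s (empty for empty input).
#' @export
generate_pseudo_labels <- function(teacher, student, unlabeled, prior = NULL,
                                   batch_size = 16L, binarize = FALSE) {
  if (length(unlabeled) == 0L) return(list())
  prior_by_id <- list()
  rnd <- 0L
  if (!is.null(prior) && length(prior)) {
    for (r in prior) prior_by_id[[r$id]] <- r
    rnd <- prior[[1]]$round
  }
  tmaps <- predict_maps(teacher, unlabeled, batch_size)
  smaps <- predict_maps(student, unlabeled, batch_size)
  lapply(seq_along(unlabeled), function(i) {
    s <- unlabeled[[i]]
    pr <- prior_by_id[[s$id]]
    cur <- if (binarize) (tmaps[[i]] >= 0.5) * 1 else tmaps[[i]]
    pseudo_label_record(id = s$id, current = cur,
                        previous = if (!is.null(pr)) pr$current,
                        disagreement = mean((tmaps[[i]] - smaps[[i]])^2),
                        accepted = FALSE, round = rnd)
  })
}

# Fused probability maps for a list of samples, batched.
predict_maps <- function(net, samples, batch_size = 16L) {
  if (is.function(net))
    return(lapply(samples, function(s) net(s$image)))
  n <- length(samples)
  out <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    d <- dim(samples[[idx[1]]]$image)
    x <- array(0, c(d[1], d[2], 3L, length(idx)))
    for (k in seq_along(idx)) x[, , , k] <- samples[[idx[k]]]$image
    fused <- segnet_forward(net, x)$fused
    for (k in seq_along(idx)) out[[idx[k]]] <- fused[, , 1, k]
  }
  out
}

#' Keep the most confident pseudo-labels
#'
#' Records are ranked by ascending disagreement (ties broken by id) and the
#' lowest `ceiling(keep_fraction * n)` are marked accepted.
#'
#' @param records List of `pseudo_label_record`s.
#' @param keep_fraction Fraction in `(0, 1]`.
#' @return The records, reordered ascending by disagreement, with `accepted`
#'   set.
#' @export
confidence_filter <- function(records, keep_fraction = 0.8) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stopf("keep_fraction must be in (0, 1]")
  if (length(records) == 0L) return(records)
  dis <- vapply(records, function(r) r$disagreement, numeric(1))
  ids <- vapply(records, function(r) r$id, character(1))
  ord <- order(dis, ids, method = "radix")
  records <- records[ord]
  n_keep <- ceiling(keep_fraction * length(records))
  for (i in seq_along(records)) records[[i]]$accepted <- i <= n_keep
  records
}

#' Average accepted pseudo-labels with their previous round
#'
#' For accepted records with a previous map the current label becomes the
#' elementwise midpoint `(current + previous) / 2`; first-round records keep
#' their current label.  `previous` is set to the pre-update current label
#' and the round counter increments.
#'
#' @param records Accepted `pseudo_label_record`s.
#' @return Updated records.
#' @export
average_update <- function(records) {
  lapply(records, function(r) {
    if (!r$accepted) stopf("record %s has not been accepted", r$id)
    fresh <- r$current
    if (!is.null(r$previous)) {
      if (!identical(dim(r$previous), dim(r$current)))
        stopf("current/previous shape mismatch for %s", r$id)
      r$current <- (r$current + r$previous) / 2
    }
    r$previous <- fresh
    r$round <- r$round + 1L
    r
  })
}

#' Turn accepted records into training targets
#'
#' @param records Accepted `pseudo_label_record`s.
#' @param unlabeled The unlabeled `image_sample` list (source of the images).
#' @return List of `list(sample, target)` pairs; targets stay soft in
#'   `[0, 1]`.
#' @export
to_training_targets <- function(records, unlabeled) {
  by_id <- setNames(unlabeled, vapply(unlabeled, function(s) s$id, character(1)))
  lapply(records, function(r) {
    if (!r$accepted) stopf("record %s has not been accepted", r$id)
    s <- by_id[[r$id]]
    if (is.null(s)) stopf("no unlabeled sample with id %s", r$id)
    list(sample = s, target = r$current)
  })
}

# Snapshot a CUPL round: 16-bit PNG soft masks plus a CSV index.
write_pseudo_snapshot <- function(records, dir, round) {
  rd <- file.path(dir, sprintf("round%03d", round))
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  idx <- do.call(rbind, lapply(records, function(r) {
    EBImage::writeImage(EBImage::Image(r$current),
                        file.path(rd, paste0(r$id, ".png")), bits = 16L)
    data.frame(id = r$id, round = r$round, disagreement = r$disagreement,
               accepted = r$accepted)
  }))
  write.csv(idx, file.path(rd, "index.csv"), row.names = FALSE)
  invisible(idx)
}
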