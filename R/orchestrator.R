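# Training orchestration: the three regimes (supervised baseline,
# baseline + consistency loss, baseline + consistency + CUPL), evaluation,
# and multi-seed regime comparison.
#
# Each optimizer step draws a labeled sub-batch (supervised BCE on the
# student) and, for the semi-supervised regimes, an unlabeled sub-batch: the
# teacher predicts the clean unlabeled images and the student is regressed
# onto the geometrically transformed teacher prediction under each
# configured perturbation (transformation consistency).  The teacher is
# EMA-updated after every optimizer step.  CUPL refreshes pseudo-labels at a
# fixed epoch interval after a warmup; accepted soft labels join the
# training stream as an extra cross-entropy term alongside the consistency
# loss.

#' Training run configuration
#'
#' @param regime `"baseline"` (supervised only), `"cl"` (+ consistency loss)
#'   or `"cl_cupl"` (+ consistency + CUPL).
#' @param model A [model_config()].
#' @param data A `dataset_split`, a [fixture_config()] (fixtures are
#'   generated and split internally), or a `list(image_dir=, mask_dir=)`.
#' @param n_labeled,n_unlabeled Training-pool partition sizes (used when
#'   `data` is not already a `dataset_split`; `n_unlabeled = NULL` keeps the
#'   whole remainder).
#' @param ratios Train/val/test split fractions.
#' @param epochs Training epochs (default 200).
#' @param batch_size Total batch size (default 40); in semi-supervised
#'   regimes it is split evenly between the labeled and unlabeled streams.
#' @param lr Adam learning rate (default 1e-5).
#' @param lambda_max,ramp_epochs Consistency weight plateau and ramp length
#'   (see [lambda_schedule()]).
#' @param perturbations Perturbation kinds applied to the unlabeled stream.
#' @param noise_sd Gaussian-noise perturbation sd.
#' @param cupl A [cupl_config()].
#' @param alpha Teacher EMA coefficient (default 0.999).
#' @param seed Run seed; drives the split, initialisation and every
#'   stochastic training choice.
#' @param out_dir Output directory for logs/checkpoints (`NULL` = a fresh
#'   temporary directory).
#' @param eval_val Evaluate the teacher on the validation split after every
#'   epoch.
#' @param snapshot_pseudo Write per-round pseudo-label PNG snapshots.
#' @return A `run_config`.
#' @export
run_config <- function(regime = c("baseline", "cl", "cl_cupl"),
                       model = model_config(), data, n_labeled = 50L,
                       n_unlabeled = NULL, ratios = c(0.8, 0.1, 0.1),
                       epochs = 200L, batch_size = 40L, lr = 1e-5,
                       lambda_max = 1, ramp_epochs = 40L,
                       perturbations = c("random_scaling", "gaussian_noise",
                                         "rotation"),
                       noise_sd = 0.03, cupl = cupl_config(), alpha = 0.999,
                       seed = 1L, out_dir = NULL, eval_val = TRUE,
                       snapshot_pseudo = FALSE) {
  regime <- match.arg(regime)
  if (regime == "cl_cupl" && !inherits(cupl, "cupl_config"))
    stopf("regime cl_cupl requires a cupl_config")
  perturbations <- match.arg(perturbations,
                             c("random_scaling", "gaussian_noise", "rotation"),
                             several.ok = TRUE)
  structure(list(regime = regime, model = model, data = data,
                 n_labeled = as.integer(n_labeled),
                 n_unlabeled = if (!is.null(n_unlabeled)) as.integer(n_unlabeled),
                 ratios = ratios, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lambda_max = lambda_max, ramp_epochs = as.integer(ramp_epochs),
                 perturbations = perturbations, noise_sd = noise_sd,
                 cupl = cupl, alpha = alpha, seed = as.integer(seed),
                 out_dir = out_dir, eval_val = isTRUE(eval_val),
                 snapshot_pseudo = isTRUE(snapshot_pseudo)),
            class = "run_config")
}

resolve_data <- function(config) {
  d <- config$data
  if (inherits(d, "dataset_split")) return(d)
  samples <- if (inherits(d, "fixture_config")) {
    generate_fixture_set(d)
  } else if (is.list(d) && !is.null(d$image_dir)) {
    load_dataset(d$image_dir, d$mask_dir, target_size = config$model$input_size)
  } else stopf("cannot resolve the data field of the run config")
  split <- split_dataset(samples, config$ratios, config$n_labeled,
                         seed = config$seed)
  if (!is.null(config$n_unlabeled)) {
    if (config$n_unlabeled > length(split$unlabeled))
      stopf("n_unlabeled = %d exceeds the %d available unlabeled samples",
            config$n_unlabeled, length(split$unlabeled))
    split$unlabeled <- split$unlabeled[seq_len(config$n_unlabeled)]
  }
  split
}

samples_to_tensors <- function(samples, idx = seq_along(samples),
                               targets = NULL) {
  d <- dim(samples[[idx[1]]]$image)
  x <- array(0, c(d[1], d[2], 3L, length(idx)))
  y <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (k in seq_along(idx)) {
    s <- samples[[idx[k]]]
    x[, , , k] <- s$image
    if (!is.null(targets)) y[, , 1, k] <- targets[[idx[k]]]
    else if (!is.null(s$mask)) y[, , 1, k] <- s$mask
  }
  list(x = x, y = y)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] %+0% b[[nm]]
  a
}

#' Train one regime
#'
#' Fully reproducible: the same `run_config` (including seed) yields a
#' bit-identical loss history on one platform.
#'
#' @param config A [run_config()].
#' @return A `training_result`: `loss_history` (one row per optimizer step),
#'   `eval_per_epoch` (teacher validation metrics, one row per epoch),
#'   `best_checkpoint` (path), `cupl_rounds`, `pseudo_quality` (accepted vs
#'   rejected pseudo-label Dice against hidden fixture truth, when
#'   available), `counters` (stream bookkeeping), `split_ids`, and `seed`.
#' @export
train <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir %||% file.path(tempfile("cuplseg_run_"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  split <- resolve_data(config)
  labeled <- split$labeled
  unlabeled <- if (config$regime == "baseline") list() else split$unlabeled
  n_lab <- length(labeled)
  n_unl <- length(unlabeled)
  if (n_lab == 0L) stopf("no labeled samples to train on")

  net <- build_model(config$model, seed = config$seed)
  teacher <- init_teacher(net, alpha = config$alpha)
  opt <- adam_init(net$params)

  unl_bs <- if (n_unl > 0L) min(config$batch_size %/% 2L, n_unl) else 0L
  lab_bs <- min(config$batch_size - unl_bs, n_lab)
  steps_per_epoch <- ceiling(n_lab / lab_bs)

  history <- vector("list", config$epochs * steps_per_epoch)
  evals <- vector("list", config$epochs)
  pseudo_records <- NULL
  pseudo_targets <- list()
  cupl_rounds <- 0L
  counters <- c(supervised_images = 0, consistency_images = 0,
                pseudo_images = 0)
  best <- list(dice = -Inf, params = NULL, teacher = NULL, epoch = NA_integer_)
  hrow <- 0L; gstep <- 0L

  for (epoch in seq_len(config$epochs) - 1L) {
    lambda <- if (config$regime == "baseline") 0
              else lambda_schedule(epoch, config$lambda_max, config$ramp_epochs)
    ord <- sample.int(n_lab)
    for (step in seq_len(steps_per_epoch)) {
      idx <- ord[((step - 1L) * lab_bs + 1L):min(step * lab_bs, n_lab)]
      tb <- samples_to_tensors(labeled, idx)
      fw <- segnet_forward(net, tb$x, want_cache = TRUE)
      L <- supervised_bce(fw$fused, tb$y)
      grads <- segnet_backward(net, fw, bce_grad(fw$fused, tb$y))
      counters["supervised_images"] <- counters["supervised_images"] + length(idx)

      CL <- 0
      if (config$regime != "baseline" && n_unl > 0L) {
        uidx <- sample.int(n_unl, unl_bs)
        ub <- samples_to_tensors(unlabeled, uidx)
        tnet <- teacher_net(teacher, net)
        zref <- segnet_forward(tnet, ub$x)$fused
        specs <- sample_perturbation_specs(config$perturbations,
                                           config$noise_sd)
        nspec <- length(specs)
        cl_terms <- numeric(nspec)
        for (si in seq_len(nspec)) {
          sp <- specs[[si]]
          xp <- ub$x
          target <- zref
          for (k in seq_len(unl_bs)) {
            xp[, , , k] <- apply_perturbation(ub$x[, , , k], sp)
            target[, , 1, k] <- perturb_geom(zref[, , 1, k], sp)
          }
          fwp <- segnet_forward(net, xp, want_cache = TRUE)
          diff <- fwp$fused - target
          cl_terms[si] <- mean(diff^2)
          if (lambda > 0) {
            df <- lambda * 2 * diff / (length(diff) * nspec)
            grads <- add_grads(grads, segnet_backward(net, fwp, df))
          }
        }
        CL <- mean(cl_terms)
        counters["consistency_images"] <- counters["consistency_images"] + unl_bs
      }

      Lp <- NA_real_
      if (config$regime == "cl_cupl" && length(pseudo_targets) > 0L) {
        p_bs <- min(lab_bs, length(pseudo_targets))
        pidx <- sample.int(length(pseudo_targets), p_bs)
        d <- dim(pseudo_targets[[1]]$sample$image)
        px <- array(0, c(d[1], d[2], 3L, p_bs))
        py <- array(0, c(d[1], d[2], 1L, p_bs))
        for (k in seq_len(p_bs)) {
          px[, , , k] <- pseudo_targets[[pidx[k]]]$sample$image
          py[, , 1, k] <- pseudo_targets[[pidx[k]]]$target
        }
        fwp <- segnet_forward(net, px, want_cache = TRUE)
        Lp <- supervised_bce(fwp$fused, py, soft = TRUE)
        grads <- add_grads(grads, segnet_backward(net, fwp, bce_grad(fwp$fused, py)))
        counters["pseudo_images"] <- counters["pseudo_images"] + p_bs
      }

      st <- adam_step(net$params, grads, opt, config$lr)
      net$params <- st$params
      opt <- st$state
      teacher <- ema_update(teacher, net)
      gstep <- gstep + 1L
      hrow <- hrow + 1L
      history[[hrow]] <- loss_report(gstep, epoch, L, CL, lambda, Lp)
    }

    if (config$eval_val && length(split$val) > 0L) {
      tnet <- teacher_net(teacher, net)
      maps <- predict_maps(tnet, split$val, batch_size = 16L)
      ev <- evaluate(maps, lapply(split$val, function(s) s$mask))
      evals[[epoch + 1L]] <- cbind(data.frame(epoch = epoch), eval_result_row(ev))
      if (ev$dice > best$dice)
        best <- list(dice = ev$dice, params = net$params, teacher = teacher,
                     epoch = epoch)
    } else {
      evals[[epoch + 1L]] <- data.frame(epoch = epoch, dice = NA_real_,
                                        jaccard = NA_real_, accuracy = NA_real_,
                                        recall = NA_real_, precision = NA_real_)
    }

    if (config$regime == "cl_cupl" && n_unl > 0L &&
        epoch >= config$cupl$warmup_epochs &&
        (epoch - config$cupl$warmup_epochs) %% config$cupl$update_interval_epochs == 0L) {
      tnet <- teacher_net(teacher, net)
      recs <- generate_pseudo_labels(tnet, net, unlabeled,
                                     prior = pseudo_records,
                                     binarize = config$cupl$binarize_fresh)
      recs <- confidence_filter(recs, config$cupl$keep_fraction)
      accepted <- Filter(function(r) r$accepted, recs)
      rejected <- Filter(function(r) !r$accepted, recs)
      if (config$cupl$average_with_previous)
        accepted <- average_update(accepted)
      else
        accepted <- lapply(accepted, function(r) { r$round <- r$round + 1L; r })
      pseudo_records <- c(accepted, rejected)
      pseudo_targets <- to_training_targets(accepted, unlabeled)
      cupl_rounds <- cupl_rounds + 1L
      if (config$snapshot_pseudo)
        write_pseudo_snapshot(pseudo_records, file.path(out_dir, "pseudo"),
                              cupl_rounds)
    }
  }

  if (is.null(best$params)) {
    best$params <- net$params
    best$teacher <- teacher
  }
  best_net <- net
  best_net$params <- best$params
  ckpt <- file.path(out_dir, "best_checkpoint.rds")
  save_checkpoint(best_net, best$teacher, ckpt,
                  extra = list(regime = config$regime, seed = config$seed,
                               best_epoch = best$epoch))
  loss_history <- do.call(rbind, history)
  write.csv(loss_history, file.path(out_dir, "loss_log.csv"),
            row.names = FALSE)
  write_manifest(split, file.path(out_dir, "manifest.tsv"))

  pseudo_quality <- pseudo_label_quality(pseudo_records, split$unlabeled)

  structure(list(loss_history = loss_history,
                 eval_per_epoch = do.call(rbind, evals),
                 best_checkpoint = ckpt, cupl_rounds = cupl_rounds,
                 pseudo_records = pseudo_records,
                 pseudo_quality = pseudo_quality,
                 counters = counters, split_ids = split_ids(split),
                 seed = config$seed, regime = config$regime,
                 net = net, teacher = teacher, out_dir = out_dir),
            class = "training_result")
}

# Dice of binarized pseudo-labels against the hidden fixture truth,
# summarised for accepted vs rejected records.  Evaluation-only: this is the
# one place the hidden ground truth of unlabeled samples is consulted.
pseudo_label_quality <- function(records, unlabeled) {
  if (is.null(records) || length(records) == 0L) return(NULL)
  truth_by_id <- list()
  for (s in unlabeled)
    if (!is.null(s$hidden_truth)) truth_by_id[[s$id]] <- s$hidden_truth
  if (length(truth_by_id) == 0L) return(NULL)
  rows <- do.call(rbind, lapply(records, function(r) {
    tr <- truth_by_id[[r$id]]
    if (is.null(tr)) return(NULL)
    data.frame(id = r$id, accepted = r$accepted,
               dice = metric_row(r$current, tr, 0.5)$dice)
  }))
  list(per_record = rows,
       accepted_dice = mean(rows$dice[rows$accepted]),
       rejected_dice = if (any(!rows$accepted))
         mean(rows$dice[!rows$accepted]) else NA_real_)
}

#' Evaluate a checkpoint on a test set
#'
#' Loads the teacher weights from the checkpoint (the evaluation model) and
#' computes the five metrics at threshold 0.5.
#'
#' @param checkpoint Path to a checkpoint written by [train()].
#' @param test A list of `image_sample`s with masks, or a directory holding
#'   `images/` and `masks/` subdirectories.
#' @param threshold Binarization threshold.
#' @return An `eval_result`.
#' @export
evaluate_checkpoint <- function(checkpoint, test, threshold = 0.5) {
  ck <- load_checkpoint(checkpoint)
  samples <- if (is.character(test)) {
    load_dataset(file.path(test, "images"), file.path(test, "masks"),
                 target_size = ck$net$config$input_size)
  } else test
  if (length(samples) == 0L) stopf("empty test set")
  net <- if (!is.null(ck$teacher)) teacher_net(ck$teacher, ck$net) else ck$net
  maps <- predict_maps(net, samples, batch_size = 16L)
  evaluate(maps, lapply(samples, function(s) s$mask), threshold)
}

#' Train and compare the three regimes over several seeds
#'
#' All regimes within one seed share the identical data split.  Reports the
#' mean and sd of each test metric per regime.
#'
#' @param base_config A [run_config()]; its `regime` and `seed` fields are
#'   overridden per run.
#' @param seeds Integer vector of run seeds.
#' @param regimes Regimes to compare.
#' @return A `regime_comparison`: `table` (per-regime mean/sd of each
#'   metric), `runs` (per-run test metrics), and `pseudo_quality` (per seed,
#'   from the cl_cupl runs).
#' @export
run_regime_comparison <- function(base_config, seeds = 1L,
                                  regimes = c("baseline", "cl", "cl_cupl")) {
  if (length(seeds) < 1L) stopf("at least one seed is required")
  runs <- list(); pq <- list()
  for (seed in seeds) {
    for (regime in regimes) {
      cfg <- base_config
      cfg$regime <- regime
      cfg$seed <- as.integer(seed)
      cfg$out_dir <- NULL
      res <- train(cfg)
      split <- resolve_data(cfg)
      ev <- evaluate_checkpoint(res$best_checkpoint, split$test)
      runs[[length(runs) + 1L]] <-
        cbind(data.frame(regime = regime, seed = seed), eval_result_row(ev))
      if (regime == "cl_cupl" && !is.null(res$pseudo_quality))
        pq[[as.character(seed)]] <- res$pseudo_quality
      unlink(res$out_dir, recursive = TRUE)
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(regimes, function(rg) {
    sub <- runs[runs$regime == rg, ]
    data.frame(regime = rg,
               dice_mean = mean(sub$dice), dice_sd = sd(sub$dice),
               jaccard_mean = mean(sub$jaccard),
               accuracy_mean = mean(sub$accuracy),
               recall_mean = mean(sub$recall),
               precision_mean = mean(sub$precision))
  }))
  structure(list(table = agg, runs = runs, pseudo_quality = pq,
                 seeds = seeds),
            class = "regime_comparison")
}

#' @export
print.regime_comparison <- function(x, ...) {
  cat("Regime comparison over seeds:", paste(x$seeds, collapse = ", "), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Read a YAML run configuration
#'
#' The file mirrors the [run_config()] fields; nested `model`, `cupl` and
#' `fixtures` blocks map onto [model_config()], [cupl_config()] and
#' [fixture_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  model <- do.call(model_config, y$model %||% list())
  cupl <- do.call(cupl_config, y$cupl %||% list())
  data <- if (!is.null(y$fixtures)) do.call(fixture_config, y$fixtures)
          else list(image_dir = y$image_dir, mask_dir = y$mask_dir)
  args <- y[setdiff(names(y), c("model", "cupl", "fixtures", "image_dir",
                                "mask_dir"))]
  args$model <- model
  args$cupl <- cupl
  args$data <- data
  do.call(run_config, args)
}
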