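# The package's desk-scale benchmark protocol: synthetic polyp fixtures at
# 64x64 with a tiny backbone, 20 labeled / 200 unlabeled training images, 60
# epochs, evaluated with the final teacher on a held-out test split.  Chosen
# once so that the supervised baseline sits near the operating point the
# semi-supervised method targets (scarce labels, accuracy well below
# ceiling), making regime comparisons informative.

#' Desk-scale benchmark run configuration
#'
#' 275 synthetic fixtures split 80:10:10; the training pool of 220 is
#' partitioned into 20 labeled and 200 unlabeled images.  The tiny backbone
#' (3 levels, 4 base channels) trains with Adam at lr 1e-2 for 60 epochs,
#' batch 20 (even labeled/unlabeled split); EMA alpha 0.97 keeps the
#' teacher's averaging horizon at about a quarter of the 120-step budget;
#' lambda ramps to 1 over 40 epochs and CUPL starts after the same 40-epoch
#' warmup (the teacher labels only once consistency training has
#' converged), refreshing every 10 epochs.
#'
#' @param regime Training regime.
#' @param seed Run seed (drives split, init, and training stochasticity).
#' @return A [run_config()].
#' @export
benchmark_config <- function(regime = c("baseline", "cl", "cl_cupl"),
                             seed = 1L) {
  regime <- match.arg(regime)
  run_config(
    regime = regime,
    model = model_config(levels = 3L, base_channels = 4L,
                         input_size = c(64L, 64L)),
    data = fixture_config(n_images = 275L, image_size = c(64L, 64L),
                          seed = 11L),
    n_labeled = 20L, n_unlabeled = 200L, epochs = 60L, batch_size = 20L,
    lr = 1e-2, lambda_max = 1, ramp_epochs = 40L, alpha = 0.97,
    cupl = cupl_config(warmup_epochs = 40L, update_interval_epochs = 10L),
    seed = seed, eval_val = FALSE)
}
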