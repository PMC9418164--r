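# Loss functions of the semi-supervised objective.
#
# The training objective combines a supervised binary cross-entropy on the
# labeled stream, a perturbation consistency mean-squared error on the
# unlabeled stream weighted by a ramped coefficient lambda, and (when CUPL is
# active) a soft-target cross-entropy on confidence-filtered pseudo-labels.
# All losses are averaged over pixels so their values are independent of the
# image resolution.

BCE_EPS <- 1e-7

#' Supervised binary cross-entropy
#'
#' Mean over pixels of `-[y log y' + (1 - y) log(1 - y')]`, with predictions
#' clamped to `[1e-7, 1 - 1e-7]`.  Targets may be soft (in `[0, 1]`) when
#' `soft = TRUE`; by default they must be strictly binary.
#'
#' @param pred Probability array.
#' @param target Binary array of the same shape (soft values allowed with
#'   `soft = TRUE`).
#' @param soft Accept soft targets in `[0, 1]`.
#' @return Scalar loss (non-negative).
#' @export
supervised_bce <- function(pred, target, soft = FALSE) {
  if (!identical(dim(pred), dim(target)) &&
      !(is.null(dim(pred)) && is.null(dim(target)) &&
        length(pred) == length(target)))
    stopf("pred and target shapes differ")
  if (!soft && !is_binary(target))
    stopf("target must be binary (0/1); use soft = TRUE for soft targets")
  if (soft && (min(target) < 0 || max(target) > 1))
    stopf("soft targets must lie in [0, 1]")
  p <- pmin(pmax(pred, BCE_EPS), 1 - BCE_EPS)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# Gradient of supervised_bce with respect to the prediction.
bce_grad <- function(pred, target) {
  p <- pmin(pmax(pred, BCE_EPS), 1 - BCE_EPS)
  (p - target) / (p * (1 - p)) / length(p)
}

#' Perturbation consistency loss
#'
#' Mean over the configured perturbations of the per-pixel mean squared
#' difference between the reference prediction and each aligned perturbed
#' prediction.
#'
#' @param bundle A [consistency_bundle()] (reference map plus 1-3 aligned
#'   maps).
#' @return Scalar loss (non-negative).
#' @export
consistency_loss <- function(bundle) {
  stopifnot(inherits(bundle, "consistency_bundle"))
  if (length(bundle$aligned) == 0L) stopf("bundle has no aligned maps")
  terms <- vapply(bundle$aligned,
                  function(a) mean((bundle$reference - a)^2), numeric(1))
  mean(terms)
}

#' Overall loss (supervised + weighted consistency)
#'
#' @param supervised Supervised loss value.
#' @param consistency Consistency loss value.
#' @param lambda_weight Non-negative consistency weight.
#' @return `supervised + lambda_weight * consistency`.
#' @export
overall_loss <- function(supervised, consistency, lambda_weight) {
  if (!is.finite(supervised) || !is.finite(consistency) ||
      !is.finite(lambda_weight))
    stopf("loss components must be finite")
  if (lambda_weight < 0) stopf("lambda_weight must be >= 0, got %g", lambda_weight)
  supervised + lambda_weight * consistency
}

#' Combined loss over labeled data and pseudo-labels
#'
#' Per-set normalisation: `(1/|X|) * labeled_term + (1/|Z|) * pseudo_term`.
#' A term whose count is zero is dropped.
#'
#' @param labeled_term Sum of supervised losses over the labeled set X.
#' @param n_labeled `|X|`.
#' @param pseudo_term Sum of soft-target cross-entropies over the accepted
#'   pseudo-labeled set Z.
#' @param n_pseudo `|Z|`.
#' @return Scalar combined loss.
#' @export
combined_loss <- function(labeled_term, n_labeled, pseudo_term = 0, n_pseudo = 0L) {
  if (n_labeled < 0 || n_pseudo < 0) stopf("counts must be >= 0")
  if (n_labeled == 0 && n_pseudo == 0) stopf("both set sizes are zero")
  out <- 0
  if (n_labeled > 0) out <- out + labeled_term / n_labeled
  if (n_pseudo > 0) out <- out + pseudo_term / n_pseudo
  out
}

#' Consistency weight ramp
#'
#' Sigmoid-shaped ramp from exactly 0 at epoch 0 to exactly `lambda_max` at
#' `ramp_epochs`, constant afterwards:
#' `lambda(e) = lambda_max * (exp(-5 (1 - t)^2) - exp(-5)) / (1 - exp(-5))`
#' with `t = min(1, e / ramp_epochs)`.
#'
#' @param epoch Current epoch (0-based).
#' @param lambda_max Plateau value.
#' @param ramp_epochs Ramp length in epochs.
#' @return Weight in `[0, lambda_max]`, non-decreasing in `epoch`.
#' @export
lambda_schedule <- function(epoch, lambda_max = 1, ramp_epochs = 40L) {
  if (ramp_epochs <= 0) return(lambda_max)
  t <- pmin(1, pmax(0, epoch / ramp_epochs))
  lambda_max * (exp(-5 * (1 - t)^2) - exp(-5)) / (1 - exp(-5))
}

#' One-row loss report for the training log
#'
#' @param step,epoch Step and epoch counters.
#' @param supervised,consistency,lambda_weight,pseudo_term Loss components.
#' @return A one-row `data.frame` with the derived `overall` and `combined`
#'   columns.
#' @export
loss_report <- function(step, epoch, supervised, consistency = 0,
                        lambda_weight = 0, pseudo_term = NA_real_) {
  overall <- overall_loss(supervised, consistency, lambda_weight)
  data.frame(step = step, epoch = epoch, supervised = supervised,
             consistency = consistency, lambda = lambda_weight,
             overall = overall, pseudo = pseudo_term,
             combined = if (is.na(pseudo_term)) overall else overall + pseudo_term)
}
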