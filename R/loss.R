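#' Soft Dice loss
#'
#' `1 - 2 * sum(y * p) / (sum(y) + sum(p) + eps)` over all voxels of a patch.
#' The small `eps` in the denominator guards the all-empty case (both target
#' and prediction empty gives loss `~1` rather than 0/0); its effect on any
#' non-degenerate patch is bounded by `eps`.
#'
#' @param pred probability array in \[0,1\].
#' @param target binary array, same shape.
#' @param eps denominator guard (default 1e-5).
#' @return Scalar loss in \[0,1\] (up to the eps effect).
#' @export
dice_loss <- function(pred, target, eps = 1e-5) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target shapes differ")
  1 - 2 * sum(pred * target) / (sum(pred) + sum(target) + eps)
}

#' Weighted binary cross-entropy loss
#'
#' Mean over voxels of `-(alpha * y * log(p) + (1 - y) * log(1 - p))`.
#' `alpha` upweights positive (fracture) voxels against the overwhelming
#' background class; the published setting is `alpha = 5`. Predictions are
#' clamped to `[1e-7, 1 - 1e-7]` for log safety.
#'
#' @param pred probability array in \[0,1\].
#' @param target binary array, same shape.
#' @param alpha positive-voxel weight (default 5).
#' @return Nonnegative scalar loss.
#' @export
weighted_bce_loss <- function(pred, target, alpha = 5) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target shapes differ")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  -mean(alpha * target * log(p) + (1 - target) * log(1 - p))
}

#' Combined training objective
#'
#' The training loss is the sum of the Dice loss and the weighted BCE loss;
#' the components are reported separately for logging.
#'
#' @inheritParams weighted_bce_loss
#' @param eps Dice denominator guard.
#' @return List of class `loss_values` with `dice`, `wbce`, `total`, `alpha`.
#' @export
total_loss <- function(pred, target, alpha = 5, eps = 1e-5) {
  d <- dice_loss(pred, target, eps)
  w <- weighted_bce_loss(pred, target, alpha)
  structure(list(dice = d, wbce = w, total = d + w, alpha = alpha),
            class = "loss_values")
}

#' @export
print.loss_values <- function(x, ...) {
  cat(sprintf("loss: total %.5f = dice %.5f + wbce %.5f (alpha = %g)\n",
              x$total, x$dice, x$wbce, x$alpha))
  invisible(x)
}

# analytic gradient of the combined loss wrt predictions; used by the
# training loop (the loss sits outside the tape)
total_loss_grad <- function(pred, target, alpha = 5, eps = 1e-5) {
  A <- sum(pred * target)
  B <- sum(pred) + sum(target) + eps
  ddice <- -2 * (target * B - A) / B^2
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  inside <- (pred > 1e-7) & (pred < 1 - 1e-7)
  dwbce <- -(alpha * target / p - (1 - target) / (1 - p)) / length(pred)
  dwbce[!inside] <- 0
  g <- ddice + dwbce
  dim(g) <- dim(pred)
  g
}
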