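# Combined focal + dice training loss and the confusion-matrix metric suite.
#
# Public loss functions operate on plain arrays of foreground probabilities
# (same shape as the binary target mask); the training loop uses the
# differentiable node versions in autograd.R, which share these formulas.

#' Loss configuration
#'
#' @param gamma focusing exponent of the focal term (default 2): larger values
#'   down-weight well-classified pixels.
#' @param alpha class-balance weight of the foreground class (default 0.25);
#'   background pixels are weighted `1 - alpha`.
#' @param eps smoothing constant of the dice denominator (default 1e-6),
#'   preventing 0/0 on empty masks.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(gamma = 2.0, alpha = 0.25, eps = 1e-6) {
  stopifnot(gamma >= 0, alpha > 0, alpha < 1, eps > 0)
  structure(list(gamma = gamma, alpha = alpha, eps = eps),
            class = "loss_config")
}

check_probs <- function(probabilities, targets) {
  if (length(probabilities) != length(targets)) {
    stop("probabilities and targets must have the same shape", call. = FALSE)
  }
  if (any(probabilities < -1e-9) || any(probabilities > 1 + 1e-9)) {
    stop("probabilities outside [0, 1]", call. = FALSE)
  }
  stopifnot_binary(targets, "targets")
  invisible(TRUE)
}

#' Focal loss
#'
#' Mean over pixels of \eqn{-\alpha_t (1-p_t)^\gamma \log p_t}, where
#' \eqn{p_t} is the predicted probability of the pixel's true class and
#' \eqn{\alpha_t} is `alpha` for foreground pixels and `1 - alpha` for
#' background pixels. With `gamma = 0` and `alpha = 0.5` it reduces to half
#' the mean cross-entropy.
#'
#' @param probabilities array of foreground-class probabilities in \[0, 1\],
#'   same shape as `targets`.
#' @param targets binary mask (1 = crop row).
#' @param config a [loss_config()].
#' @return scalar loss.
#' @export
focal_loss <- function(probabilities, targets, config = loss_config()) {
  check_probs(probabilities, targets)
  pt <- ifelse(targets == 1, probabilities, 1 - probabilities)
  at <- ifelse(targets == 1, config$alpha, 1 - config$alpha)
  pt <- clamp(pt, 1e-12, 1)
  mean(-at * (1 - pt)^config$gamma * log(pt))
}

#' Soft dice loss
#'
#' \eqn{1 - (2|A \cap B| + \epsilon) / (|A| + |B| + \epsilon)} with the
#' prediction region A taken as the soft foreground probabilities and B the
#' binary ground truth.
#'
#' @inheritParams focal_loss
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(probabilities, targets, config = loss_config()) {
  check_probs(probabilities, targets)
  inter <- sum(probabilities * targets)
  denom <- sum(probabilities) + sum(targets)
  1 - (2 * inter + config$eps) / (denom + config$eps)
}

#' Combined training loss: focal + dice (unweighted sum)
#'
#' @inheritParams focal_loss
#' @return scalar loss.
#' @export
total_loss <- function(probabilities, targets, config = loss_config()) {
  focal_loss(probabilities, targets, config) +
    dice_loss(probabilities, targets, config)
}

#' Analytic gradient of the combined loss
#'
#' Returns d(total_loss)/d(probabilities), element-wise; used in training and
#' verifiable against finite differences.
#'
#' @inheritParams focal_loss
#' @param component one of "total", "focal", "dice".
#' @return array of the same shape as `probabilities`.
#' @export
loss_gradient <- function(probabilities, targets, config = loss_config(),
                          component = c("total", "focal", "dice")) {
  component <- match.arg(component)
  check_probs(probabilities, targets)
  g <- config$gamma
  npix <- length(probabilities)
  pt <- ifelse(targets == 1, probabilities, 1 - probabilities)
  at <- ifelse(targets == 1, config$alpha, 1 - config$alpha)
  pt <- clamp(pt, 1e-12, 1 - 1e-12)
  # d/dp_t of -a (1-p_t)^g log p_t
  dfdpt <- if (g == 0) {
    -at / pt
  } else {
    at * g * (1 - pt)^(g - 1) * log(pt) - at * (1 - pt)^g / pt
  }
  # p_t = p for foreground, 1 - p for background
  dfocal <- ifelse(targets == 1, dfdpt, -dfdpt) / npix
  inter <- sum(probabilities * targets)
  denom <- sum(probabilities) + sum(targets)
  ddice <- -(2 * targets * (denom + config$eps) - (2 * inter + config$eps)) /
    (denom + config$eps)^2
  out <- switch(component, total = dfocal + ddice, focal = dfocal, dice = ddice)
  dim(out) <- dim(probabilities)
  out
}

#' Pixel confusion matrix of two binary masks
#'
#' @param pred_mask,true_mask binary arrays of identical shape
#'   (1 = crop row foreground).
#' @return object of class `confusion_matrix` with fields TP, FP, FN, TN.
#' @export
confusion <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask)) ||
      length(pred_mask) != length(true_mask)) {
    stop("pred_mask and true_mask must have identical shapes", call. = FALSE)
  }
  stopifnot_binary(pred_mask, "pred_mask")
  stopifnot_binary(true_mask, "true_mask")
  p <- as.vector(pred_mask) == 1
  t <- as.vector(true_mask) == 1
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_matrix")
}

safe_ratio <- function(num, den) {
  if (den == 0) {
    # class absent from both prediction and truth: perfect by convention
    if (num == 0) return(structure(1, degenerate = TRUE))
    return(0)
  }
  num / den
}

#' Segmentation metrics from a confusion matrix
#'
#' Computes per-class IoU, mIoU, precision, recall, mean pixel accuracy, f1
#' and dice coefficient. The background class is treated symmetrically (its
#' true positives are the TN count). Degenerate 0/0 ratios are 1 when the
#' class is absent from both masks, else 0, and flagged via the `degenerate`
#' attribute.
#'
#' @param cm a `confusion_matrix` from [confusion()].
#' @param n_classes number of classes (2 in the binary crop-row setting).
#' @return object of class `seg_metrics`: a list with fields `iou` (named
#'   per-class vector), `miou`, `precision`, `recall`, `mpa`, `f1`, `dice`,
#'   `accuracy`, all in \[0, 1\].
#' @export
metrics_from_confusion <- function(cm, n_classes = 2L) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (n_classes != 2L) stop("only the binary setting is supported", call. = FALSE)
  with(cm, {
    iou_fg <- safe_ratio(TP, TP + FP + FN)
    iou_bg <- safe_ratio(TN, TN + FN + FP)
    pa_fg <- safe_ratio(TP, TP + FN)
    pa_bg <- safe_ratio(TN, TN + FP)
    precision <- safe_ratio(TP, TP + FP)
    recall <- safe_ratio(TP, TP + FN)
    f1 <- safe_ratio(2 * TP, 2 * TP + FP + FN)
    structure(list(
      iou = c(background = as.numeric(iou_bg), foreground = as.numeric(iou_fg)),
      miou = (as.numeric(iou_fg) + as.numeric(iou_bg)) / 2,
      precision = as.numeric(precision),
      recall = as.numeric(recall),
      mpa = (as.numeric(pa_fg) + as.numeric(pa_bg)) / 2,
      f1 = as.numeric(f1),
      dice = as.numeric(f1),       # identical for binary hard masks
      accuracy = (TP + TN) / (TP + FP + FN + TN),
      degenerate = isTRUE(attr(iou_fg, "degenerate")) ||
        isTRUE(attr(iou_bg, "degenerate"))
    ), class = "seg_metrics")
  })
}

#' Segmentation metrics of a predicted mask against ground truth
#'
#' Convenience wrapper: confusion matrix then [metrics_from_confusion()].
#'
#' @inheritParams confusion
#' @return a `seg_metrics` object.
#' @export
evaluate_mask <- function(pred_mask, true_mask) {
  metrics_from_confusion(confusion(pred_mask, true_mask))
}
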