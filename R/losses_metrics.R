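# Training objective and evaluation metrics with their exact conventions:
# class-weighted binary cross-entropy (mean over pixels), Dice and IoU on
# binarised masks, and inverse-frequency class-weight derivation.

#' Class weights for the weighted cross-entropy
#'
#' @param w_background,w_wound Positive finite weights for the background and
#'   wound classes.
#' @return List of class `class_weights`.
#' @export
class_weights <- function(w_background = 1, w_wound = 1) {
  if (!is.finite(w_background) || !is.finite(w_wound) ||
      w_background <= 0 || w_wound <= 0) {
    stop("class weights must be finite and > 0")
  }
  structure(list(w_background = w_background, w_wound = w_wound),
            class = "class_weights")
}

#' Weighted binary cross-entropy
#'
#' `loss = -(1/N) * sum( w_wound * t * log(p) + w_background * (1-t) * log(1-p) )`
#' over all pixels, with probabilities clipped to `[eps, 1-eps]`,
#' `eps = 1e-7`. Equal weights reduce to the standard binary cross-entropy.
#'
#' @param prob Foreground-probability array (any shape), values in `[0, 1]`.
#' @param truth Binary mask of the same shape.
#' @param w A [class_weights()] object (default: equal weights).
#' @return Non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(prob, truth, w = class_weights()) {
  stopifnot(inherits(w, "class_weights"))
  if (!identical(dim(prob), dim(truth)) && length(prob) != length(truth)) {
    stop("prob and truth shapes do not match")
  }
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0, 1]")
  .check_binary(truth)
  eps <- 1e-7
  p <- pmin(pmax(as.numeric(prob), eps), 1 - eps)
  t <- as.numeric(truth)
  -mean(w$w_wound * t * log(p) + w$w_background * (1 - t) * log(1 - p))
}

# gradient of the weighted cross-entropy w.r.t. the pre-sigmoid logit of p:
# d/du = (1/N) * (w_wound*t + w_background*(1-t)) * (p - t)
.wce_logit_grad <- function(prob, truth, w) {
  n <- length(prob)
  wt <- w$w_wound * truth + w$w_background * (1 - truth)
  g <- wt * (prob - truth) / n
  array(g, dim(prob))
}

.check_binary <- function(m) {
  v <- as.numeric(m)
  if (any(v != 0 & v != 1)) stop("mask values must be binary (0/1)")
  invisible(TRUE)
}

#' Dice similarity coefficient
#'
#' `2|P intersect T| / (|P| + |T|)` between two binary masks. Two empty masks
#' score 1 by convention (an all-negative prediction of a wound-free image is
#' perfect).
#'
#' @param pred,truth Binary masks of identical shape.
#' @return Value in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  .metric_counts(pred, truth, function(inter, np, nt) {
    if (np + nt == 0) 1 else 2 * inter / (np + nt)
  })
}

#' Intersection-over-union (Jaccard) score
#'
#' `|P intersect T| / |P union T|`; two empty masks score 1. Related to Dice
#' by `iou = dice / (2 - dice)`.
#'
#' @inheritParams dice_coefficient
#' @return Value in `[0, 1]`.
#' @export
iou_score <- function(pred, truth) {
  .metric_counts(pred, truth, function(inter, np, nt) {
    u <- np + nt - inter
    if (u == 0) 1 else inter / u
  })
}

.metric_counts <- function(pred, truth, f) {
  if (length(pred) != length(truth)) stop("pred and truth shapes do not match")
  .check_binary(pred)
  .check_binary(truth)
  p <- as.numeric(pred)
  t <- as.numeric(truth)
  f(sum(p * t), sum(p), sum(t))
}

#' Derive inverse-frequency class weights from a mask corpus
#'
#' With wound-pixel fraction `f` over the whole corpus, the weights are
#' proportional to the inverse class frequencies and normalised so that
#' `w_background + w_wound = 2`, i.e. `w_wound = 2(1-f)`, `w_background = 2f`,
#' giving the ratio `w_wound / w_background = (1-f)/f`. The ratio is capped at
#' `w_max` (so an all-background corpus yields the capped ratio rather than an
#' infinite weight).
#'
#' @param masks List of binary masks.
#' @param w_max Cap on the weight ratio (default 100).
#' @return A [class_weights()] object.
#' @export
derive_class_weights <- function(masks, w_max = 100) {
  if (!is.list(masks) || length(masks) == 0) stop("non-empty list of masks required")
  fg <- 0
  tot <- 0
  for (m in masks) {
    .check_binary(m)
    fg <- fg + sum(m)
    tot <- tot + length(m)
  }
  f <- fg / tot
  ratio <- if (f <= 0) w_max else min((1 - f) / f, w_max)
  ratio <- max(ratio, 1 / w_max)
  class_weights(w_background = 2 / (1 + ratio), w_wound = 2 * ratio / (1 + ratio))
}

#' Per-image segmentation scores
#'
#' @param pred,truth Binary masks.
#' @param image_id Identifier carried into the result.
#' @return One-row data frame: `image_id`, `dice`, `iou`.
#' @export
metric_sample <- function(pred, truth, image_id = "img") {
  data.frame(image_id = image_id,
             dice = dice_coefficient(pred, truth),
             iou = iou_score(pred, truth),
             stringsAsFactors = FALSE)
}
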