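#' Precision and recall of a predicted mask
#'
#' @param pred,truth Binary masks of identical shape; `truth` must be
#'   nonempty.
#' @return List with `precision`, `recall`, and `empty_pred` flag
#'   (precision is reported as 0 when the prediction is empty).
#' @export
precision_recall <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("pred/truth shape mismatch")
  stopifnot_binary(pred); stopifnot_binary(truth)
  nt <- sum(truth)
  if (nt == 0) stop("ground-truth mask is empty")
  np <- sum(pred)
  ov <- sum(pred * truth)
  list(precision = if (np == 0) 0 else ov / np,
       recall = ov / nt,
       empty_pred = np == 0)
}

#' Weighted F-measure
#'
#' `F = (1 + beta_sq) * p * r / (beta_sq * p + r)`. The conventional
#' saliency-benchmark weighting sets `beta_sq = 0.3`, emphasizing
#' precision. Note the parameter is beta *squared*: the literature's
#' "beta = 0.3" refers to this squared weight.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @param beta_sq Positive squared weight (default 0.3).
#' @return F-measure in `[0, 1]`; 0 (with attribute `degenerate = TRUE`)
#'   when precision and recall are both 0.
#' @export
f_measure <- function(precision, recall, beta_sq = 0.3) {
  if (beta_sq <= 0) stop("beta_sq must be positive")
  if (precision < 0 || precision > 1 || recall < 0 || recall > 1)
    stop("precision and recall must lie in [0, 1]")
  if (precision == 0 && recall == 0)
    return(structure(0, degenerate = TRUE))
  (1 + beta_sq) * precision * recall / (beta_sq * precision + recall)
}

#' Recognition accuracy from a recognition score
#'
#' Object-naming trials are graded 2 (named correctly), 1 (described but
#' not named), or 0; the score is normalized to a percentage:
#' `RA = RS / 2 * 100`.
#'
#' @param rs Integer recognition score in `{0, 1, 2}` (vectorized).
#' @return Percentage in `{0, 50, 100}`.
#' @export
recognition_accuracy <- function(rs) {
  if (!all(rs %in% c(0L, 1L, 2L))) stop("recognition score must be 0, 1 or 2")
  rs / 2 * 100
}

#' Binarize a saliency map at twice its mean
#'
#' The standard saliency-benchmark adaptive rule: threshold at
#' `2 * mean(saliency)`, capped at the map maximum so the mask is never
#' forced empty by the cap itself.
#'
#' @param saliency Raster in `[0, 1]`.
#' @return Binary mask with attribute `threshold`; an all-constant map
#'   yields an empty or full mask with attribute `degenerate = TRUE`.
#' @export
adaptive_threshold_binarize <- function(saliency) {
  if (any(saliency < 0 | saliency > 1)) stop("saliency values must lie in [0,1]")
  thr <- min(2 * mean(saliency), max(saliency))
  mask <- (saliency >= thr) * 1
  attr(mask, "threshold") <- thr
  if (diff(range(saliency)) == 0) attr(mask, "degenerate") <- TRUE
  mask
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Binary masks of identical shape.
#' @return IoU in `[0, 1]` (1 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shape mismatch")
  u <- sum((a + b) > 0)
  if (u == 0) return(1)
  sum(a * b == 1) / u
}

#' Batch evaluation of predicted masks against ground truth
#'
#' @param preds,truths Lists of binary masks (or single masks), paired by
#'   position.
#' @param beta_sq F-measure weight.
#' @return Data frame with one row per pair (`precision`, `recall`,
#'   `f_measure`, `iou`) plus a `"means"` attribute of column means.
#' @export
evaluate_masks <- function(preds, truths, beta_sq = 0.3) {
  if (is.matrix(preds)) preds <- list(preds)
  if (is.matrix(truths)) truths <- list(truths)
  if (length(preds) != length(truths)) stop("pred/truth count mismatch")
  rows <- lapply(seq_along(preds), function(i) {
    pr <- precision_recall(preds[[i]], truths[[i]])
    data.frame(precision = pr$precision, recall = pr$recall,
               f_measure = as.numeric(f_measure(pr$precision, pr$recall,
                                                beta_sq)),
               iou = mask_iou(preds[[i]], truths[[i]]))
  })
  out <- do.call(rbind, rows)
  attr(out, "means") <- colMeans(out)
  out
}
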