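# Segmentation and classification evaluation: confusion counts, overlap
# coefficients (Dice, Jaccard), sensitivity/specificity/accuracy, and ROC
# AUC as the Mann-Whitney concordance probability.

#' Confusion counts between a segmented mask and the ground truth
#'
#' @param si Logical matrix: the segmented image (TRUE = lesion).
#' @param gt Logical matrix: the ground truth, same shape.
#' @return A list of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(si, gt) {
  if (!identical(dim(si), dim(gt)))
    stop_contract("masks must share shape")
  si <- si > 0; gt <- gt > 0
  structure(list(TP = sum(si & gt), FP = sum(si & !gt),
                 FN = sum(!si & gt), TN = sum(!si & !gt)),
            class = "confusion_counts")
}

#' Overlap coefficients from confusion counts
#'
#' `Dice = 2TP / (2TP + FP + FN)`; `Jaccard = TP / (TP + FP + FN)`. Both lie
#' in [0, 1] and satisfy `Dice = 2 Jaccard / (1 + Jaccard)`; Jaccard
#' penalizes misclassification more strongly.
#'
#' @param c A `confusion_counts` (or list with `TP`, `FP`, `FN`).
#' @return The coefficient.
#' @export
dice <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den <= 0) stop_contract("Dice undefined: both masks empty")
  2 * c$TP / den
}

#' @rdname dice
#' @export
jaccard <- function(c) {
  den <- c$TP + c$FP + c$FN
  if (den <= 0) stop_contract("Jaccard undefined: both masks empty")
  c$TP / den
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Ratios with an empty denominator are reported as `NA` (not available)
#' rather than 0; when there are no true negatives and no false positives
#' the accuracy reduces to the sensitivity, the situation that arises when
#' every pixel under evaluation belongs to the positive class.
#'
#' @param c A `confusion_counts`.
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`.
#' @export
sens_spec_acc <- function(c) {
  tot <- c$TP + c$FP + c$FN + c$TN
  if (tot <= 0) stop_contract("all confusion counts are zero")
  sens <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
  spec <- if (c$TN + c$FP > 0) c$TN / (c$TN + c$FP) else NA_real_
  c(sensitivity = sens, specificity = spec, accuracy = (c$TP + c$TN) / tot)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the fraction of
#' (positive, negative) pairs in which the positive sample scores higher,
#' with ties counting one half. Equivalent to the trapezoidal area under
#' the ROC curve, and invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores Numeric vector of per-sample scores (higher = more
#'   positive).
#' @param labels Binary labels (0/1, logical, or a factor/character with the
#'   positive class being the second sorted level).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(factor(labels)) - 1L
  labels <- as.integer(labels > 0)
  if (length(scores) != length(labels))
    stop_contract("scores and labels must align")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_contract("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
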