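#' Segmentation and classification metrics
#'
#' Mask overlap: `Dice = 2|P & T| / (|P| + |T|)`, `Precision = |P & T| /
#' |P|`, `Recall = |P & T| / |T|`, `F = 2PR / (P + R)`. Confusion-matrix
#' rates: `Accuracy = (TP+TN)/(TP+TN+FP+FN)`, `Sensitivity = TP/(TP+FN)`,
#' `Specificity = TN/(TN+FP)`. AUC is the probability that a random
#' positive is scored above a random negative, ties counting one half.
#' Undefined ratios (empty denominators) are reported as 0.
#'
#' @name metrics
NULL

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Area under the ROC curve
#'
#' @param truth 0/1 labels (or logical).
#' @param score numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`; 0.5 when either class is absent or scores are
#'   constant in rank.
#' @export
auc_score <- function(truth, score) {
  truth <- as.integer(as_binary_label(truth))
  stopifnot(length(truth) == length(score))
  if (length(unique(truth)) < 2) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- pROC::roc(response = truth, predictor = as.numeric(score),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

as_binary_label <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) x <- as.numeric(x)
  if (is.logical(x)) x <- as.integer(x)
  if (!all(x %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  as.integer(x)
}

#' Confusion-matrix metrics for binary predictions
#'
#' @param truth 0/1 ground-truth labels.
#' @param estimate 0/1 predicted labels.
#' @param score optional numeric scores for AUC.
#' @return one-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `sensitivity`, `specificity`, and `auc` when scores are given.
#' @export
confusion_metrics <- function(truth, estimate, score = NULL) {
  truth <- as_binary_label(truth)
  estimate <- as_binary_label(estimate)
  if (!length(truth)) stop("empty input", call. = FALSE)
  stopifnot(length(truth) == length(estimate))
  tp <- sum(truth == 1 & estimate == 1)
  fp <- sum(truth == 0 & estimate == 1)
  fn <- sum(truth == 1 & estimate == 0)
  tn <- sum(truth == 0 & estimate == 0)
  out <- tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    accuracy = safe_ratio(tp + tn, tp + tn + fp + fn),
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp)
  )
  if (!is.null(score)) out$auc <- auc_score(truth, score)
  out
}

#' Overlap metrics for a predicted mask against ground truth
#'
#' @param pred,truth logical masks of the same shape.
#' @return one-row tibble: `dice`, `precision`, `recall`, `f_measure`,
#'   plus pixel counts `tp`, `fp`, `fn`, `tn`.
#' @export
mask_metrics <- function(pred, truth) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  assert_same_shape(pred, truth, "masks")
  if (!length(pred)) stop("empty input", call. = FALSE)
  inter <- sum(pred & truth)
  p <- safe_ratio(inter, sum(pred))
  r <- safe_ratio(inter, sum(truth))
  tibble::tibble(
    dice = safe_ratio(2 * inter, sum(pred) + sum(truth)),
    precision = p,
    recall = r,
    f_measure = safe_ratio(2 * p * r, p + r),
    tp = inter,
    fp = sum(pred & !truth),
    fn = sum(!pred & truth),
    tn = sum(!pred & !truth)
  )
}
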