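#' Confusion counts at the 0.5 threshold
#'
#' @param labels Binary truth labels.
#' @param y_pred Predicted binding probabilities.
#' @param threshold Decision threshold; default 0.5 (positive iff
#'   `y_pred > threshold`).
#' @return A tibble with columns `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(labels, y_pred, threshold = 0.5) {
  pred <- as.integer(y_pred > threshold)
  tibble(
    TP = sum(pred == 1L & labels == 1L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L)
  )
}

#' Classification metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = TP/(TP + (FP+FN)/2)` and accuracy. Zero denominators report 0
#' with a warning.
#'
#' @param cc A one-row tibble from [confusion_counts()].
#' @return A one-row tibble `accuracy`, `precision`, `recall`, `f1`.
#' @export
metrics_from_confusion <- function(cc) {
  n <- cc$TP + cc$FP + cc$FN + cc$TN
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); reporting 0.", what))
      0
    } else num / den
  }
  tibble(
    accuracy = safe_div(cc$TP + cc$TN, n, "Accuracy"),
    precision = safe_div(cc$TP, cc$TP + cc$FP, "Precision"),
    recall = safe_div(cc$TP, cc$TP + cc$FN, "Recall"),
    f1 = safe_div(cc$TP, cc$TP + 0.5 * (cc$FP + cc$FN), "F1")
  )
}

#' ROC curve points
#'
#' Sweeps the prediction threshold over all distinct scores and returns
#' the (FPR, TPR) staircase, endpoints included.
#'
#' @inheritParams confusion_counts
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, y_pred) {
  ord <- order(y_pred, decreasing = TRUE)
  lab <- labels[ord]
  sc <- y_pred[ord]
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  tp <- cumsum(lab == 1L)
  fp <- cumsum(lab == 0L)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each tie group
  tibble(
    threshold = c(Inf, sc[keep]),
    fpr = c(0, fp[keep] / n_neg),
    tpr = c(0, tp[keep] / n_pos)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the threshold-swept ROC curve; ties handled by
#' collapsing equal-score groups, which makes the area equal to the
#' normalized Mann-Whitney U statistic. Returns `NA` with a warning when
#' the labels contain a single class.
#'
#' @inheritParams confusion_counts
#' @return AUC in `[0, 1]`, or `NA` for a single-class input.
#' @export
auc_score <- function(labels, y_pred) {
  if (length(unique(labels)) < 2L) {
    warn("AUC undefined for a single-class label vector; returning NA.")
    return(NA_real_)
  }
  r <- roc_points(labels, y_pred)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}
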