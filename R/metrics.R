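#' Confusion counts at a probability threshold
#'
#' A sample is called positive when its score is greater than or equal to
#' the threshold.
#'
#' @param y_true Binary labels (0/1).
#' @param y_score Scores in `[0, 1]`.
#' @param threshold Decision threshold, default 0.5.
#' @return A one-row tibble with columns `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_score, threshold = 0.5) {
  if (length(y_true) != length(y_score)) {
    abort(sprintf("length mismatch: %d labels vs %d scores",
                  length(y_true), length(y_score)),
          class = "stack4mc_contract_error")
  }
  pred <- as.integer(y_score >= threshold)
  tibble(
    TP = sum(pred == 1 & y_true == 1),
    TN = sum(pred == 0 & y_true == 0),
    FP = sum(pred == 1 & y_true == 0),
    FN = sum(pred == 0 & y_true == 1)
  )
}

#' Area under the ROC curve
#'
#' Computed from the rank statistic (Mann-Whitney form) with midrank
#' handling of tied scores; equivalent to the trapezoidal area under the
#' ROC curve over all thresholds.
#'
#' @param y_true Binary labels.
#' @param y_score Scores.
#' @return AUC in `[0, 1]`; 0 with a warning when either class is absent.
#' @export
auc_score <- function(y_true, y_score) {
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined with a single class; reporting 0")
    return(0)
  }
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full classification metrics report
#'
#' Computes accuracy, sensitivity, specificity, Matthews correlation
#' coefficient, F1 score (standard form 2TP / (2TP + FP + FN)) and AUC.
#' Metrics whose denominator is zero are reported as 0 and flagged in the
#' `degenerate` column.
#'
#' @inheritParams confusion_counts
#' @return A one-row tibble with columns `ACC`, `SN`, `SP`, `MCC`, `AUC`,
#'   `F1`, the four confusion counts, `n`, and `degenerate`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
#' @export
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  cc <- confusion_counts(y_true, y_score, threshold)
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  n <- TP + TN + FP + FN
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; return(0) }
    num / den
  }
  acc <- safe_div(TP + TN, n)
  sn <- safe_div(TP, TP + FN)
  sp <- safe_div(TN, TN + FP)
  f1 <- safe_div(2 * TP, 2 * TP + FP + FN)
  mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mcc_den == 0) { degenerate <- TRUE; 0 } else {
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  }
  auc <- if (n == 0) { degenerate <- TRUE; 0 } else {
    if (sum(y_true == 1) == 0 || sum(y_true == 0) == 0) {
      degenerate <- TRUE
      0
    } else auc_score(y_true, y_score)
  }
  if (degenerate) warn("one or more metrics had a zero denominator; reported as 0")
  tibble(ACC = acc, SN = sn, SP = sp, MCC = mcc, AUC = auc, F1 = f1,
         TP = TP, TN = TN, FP = FP, FN = FN, n = n, degenerate = degenerate)
}
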