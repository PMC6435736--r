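## Binary classification of disorder at the Z-score threshold: ROC/AUC
## over probability cutoffs, and the confusion-matrix summary (MCC,
## FPR/FNR/TPR) at a fixed probability cutoff.

#' Binarize Z-scores into disorder labels
#'
#' A residue is labelled disordered iff `Z < threshold` (strict
#' inequality; Z exactly at the threshold is ordered).
#'
#' @param z numeric vector of finite Z-scores.
#' @param threshold disorder criterion (default 8).
#' @return logical vector, `TRUE` = disordered.
#' @export
binarizeZ <- function(z, threshold = 8.0) {
  stopifnot(all(is.finite(z)))
  z < threshold
}

#' ROC curve and AUC of a predictor against the Z criterion
#'
#' Builds the ROC curve of the predicted disorder probability against the
#' binary disorder label `Z < threshold`, one operating point per unique
#' probability cutoff (tied probabilities are grouped, which is what
#' produces the edgy ROC of predictors printed at few decimal places),
#' and integrates the AUC with the trapezoidal rule. With grouped ties
#' this equals the tie-corrected Mann-Whitney statistic
#' (concordant + ties/2) / (nDis * nOrd). Requires both classes; if one
#' is empty, `NA` is returned with a warning. Binary predictions are not
#' meaningful here and are `NA` by policy.
#'
#' @param scores a [PairedScores-class].
#' @param threshold Z-score disorder criterion (default 8).
#' @return list with `roc` (data.frame `cutoff`, `fpr`, `tpr`) and `auc`
#'   (scalar or `NA`).
#' @export
rocAuc <- function(scores, threshold = 8.0) {
  stopifnot(is(scores, "PairedScores"))
  if (scores@isBinary) {
    warning("AUC is not applicable to a binary prediction method")
    return(list(roc = NULL, auc = NA_real_))
  }
  lab <- binarizeZ(scores@z, threshold)
  nPos <- sum(lab); nNeg <- sum(!lab)
  if (nPos == 0L || nNeg == 0L) {
    warning("only one class present after binarization; AUC undefined")
    return(list(roc = NULL, auc = NA_real_))
  }
  ord <- order(scores@p, decreasing = TRUE)
  p <- scores@p[ord]; lab <- lab[ord]
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / nPos)
  fpr <- c(0, fp[last] / nNeg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(cutoff = c(Inf, p[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Confusion-matrix analysis at a probability cutoff
#'
#' Predicts disordered iff `p >= pCutoff`, labels disordered iff
#' `Z < zThreshold`, and summarises the 2x2 table with the Matthews
#' correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' (0 by convention when any marginal is zero), the false positive rate
#' FP/(FP+TN), the false negative rate FN/(FN+TP) and the true positive
#' rate.
#'
#' @param scores a [PairedScores-class].
#' @param zThreshold Z-score disorder criterion (default 8).
#' @param pCutoff probability cutoff (default 0.5).
#' @return list with `tp`, `fp`, `tn`, `fn`, `mcc`, `fpr`, `fnr`, `tpr`.
#' @export
confusionStats <- function(scores, zThreshold = 8.0, pCutoff = 0.5) {
  stopifnot(is(scores, "PairedScores"), length(scores@z) >= 1L)
  lab <- binarizeZ(scores@z, zThreshold)
  pred <- scores@p >= pCutoff
  tp <- sum(pred & lab); fp <- sum(pred & !lab)
  tn <- sum(!pred & !lab); fn <- sum(!pred & lab)
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
       fn = as.integer(fn), mcc = mcc,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
       tpr = if (fn + tp > 0) tp / (fn + tp) else NA_real_)
}
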