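## Bias/discrimination decomposition of predicted probabilities: how high
## a predictor scores truly disordered residues (pZL), truly ordered ones
## (pZH), and what that says about its calibration (pZA) and its power to
## separate the classes (pZD).

#' Bias metrics of a predictor
#'
#' pZL is the mean predicted probability of disorder over residues with
#' `Z < threshold` and pZH the mean over residues with `Z > threshold`
#' (Z exactly at the threshold is excluded from both means, following the
#' strict inequalities that define them). The average
#' `pZA = (pZL + pZH)/2` measures bias -- an unbiased method sits near
#' 0.5 -- and the difference `pZD = pZL - pZH` measures discrimination.
#'
#' @param scores a [PairedScores-class].
#' @param threshold Z-score criterion (default 8).
#' @return a [BiasMetrics-class]; all fields `NA` (with a warning) when
#'   either side of the threshold is empty.
#' @export
biasMetrics <- function(scores, threshold = 8.0) {
  stopifnot(is(scores, "PairedScores"))
  low <- scores@z < threshold
  high <- scores@z > threshold
  nL <- sum(low); nH <- sum(high)
  if (nL == 0L || nH == 0L) {
    warning("empty class on one side of Z = ", threshold,
            "; bias metrics undefined")
    return(new("BiasMetrics", pZL = NA_real_, pZH = NA_real_,
               pZA = NA_real_, pZD = NA_real_,
               nL = as.integer(nL), nH = as.integer(nH)))
  }
  pZL <- mean(scores@p[low])
  pZH <- mean(scores@p[high])
  new("BiasMetrics", pZL = pZL, pZH = pZH, pZA = (pZL + pZH) / 2,
      pZD = pZL - pZH, nL = as.integer(nL), nH = as.integer(nH))
}

#' Classify the prediction bias
#'
#' Applies the pZA rule: below 0.3 the method considerably
#' under-predicts disorder; above 0.7 it over-predicts; otherwise it sits
#' in the unbiased range.
#'
#' @param bias a [BiasMetrics-class] or a pZA value.
#' @return one of `"under-predicts-disorder"`, `"unbiased-range"`,
#'   `"over-predicts-disorder"`.
#' @export
classifyBias <- function(bias) {
  pza <- if (is(bias, "BiasMetrics")) bias@pZA else as.numeric(bias)
  if (is.na(pza)) stop("pZA is undefined")
  if (pza < 0.3) "under-predicts-disorder"
  else if (pza > 0.7) "over-predicts-disorder"
  else "unbiased-range"
}
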