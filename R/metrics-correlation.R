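## Continuous agreement between predicted disorder probability and Z.
## Because Z grows with order while p measures disorder, a good predictor
## has a correlation near -1; predictors are ranked by |R_P|.

#' Pearson correlation between p and Z
#'
#' Product-moment correlation of the paired (p, Z) values. The sign is
#' preserved: -1 is perfect agreement (Z measures order, p disorder), 0
#' is no agreement. A constant vector makes the correlation undefined;
#' `NA` is returned with a warning.
#'
#' @param scores a [PairedScores-class] with n >= 3.
#' @return numeric scalar, `NA` when undefined.
#' @export
pearsonR <- function(scores) {
  stopifnot(is(scores, "PairedScores"))
  if (length(scores@z) < 3L) stop("need at least 3 pairs")
  if (stats::sd(scores@z) == 0 || stats::sd(scores@p) == 0) {
    warning("constant vector: Pearson correlation undefined for '",
            scores@methodName, "'")
    return(NA_real_)
  }
  stats::cor(scores@p, scores@z)
}

#' Spearman rank correlation between p and Z
#'
#' Pearson correlation of the average-ranked values (ties receive average
#' ranks). Not applicable to binary predictors, for which `NA` is
#' returned by policy; likewise for a fully tied vector.
#'
#' @param scores a [PairedScores-class] with n >= 3.
#' @return numeric scalar, `NA` when undefined or binary.
#' @export
spearmanR <- function(scores) {
  stopifnot(is(scores, "PairedScores"))
  if (length(scores@z) < 3L) stop("need at least 3 pairs")
  if (scores@isBinary) return(NA_real_)
  rp <- rank(scores@p); rz <- rank(scores@z)
  if (stats::sd(rp) == 0 || stats::sd(rz) == 0) {
    warning("tied vector: Spearman correlation undefined for '",
            scores@methodName, "'")
    return(NA_real_)
  }
  stats::cor(rp, rz)
}
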