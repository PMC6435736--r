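## Assembly of the full per-method benchmark row, method ranking, and
## cohort-level optimization of the Z-score disorder threshold.

#' Full benchmark row for one predictor
#'
#' Computes every metric of the benchmark for one method over paired
#' (Z, p) scores: Pearson and Spearman correlation, ROC AUC, confusion
#' counts with MCC/FPR/FNR/TPR at the probability cutoff, and the bias
#' metrics. For binary methods Spearman correlation and AUC are `NA` by
#' policy; everything else is still computed.
#'
#' @param scores a [PairedScores-class].
#' @param zThreshold Z-score disorder criterion (default 8).
#' @param pCutoff probability cutoff for the confusion analysis
#'   (default 0.5).
#' @return a [BenchmarkResult-class].
#' @export
benchmarkMethod <- function(scores, zThreshold = 8.0, pCutoff = 0.5) {
  stopifnot(is(scores, "PairedScores"))
  rp <- tryCatch(pearsonR(scores), warning = function(w) {
    warning(conditionMessage(w)); NA_real_
  })
  rs <- suppressWarnings(spearmanR(scores))
  auc <- suppressWarnings(rocAuc(scores, zThreshold)$auc)
  cf <- confusionStats(scores, zThreshold, pCutoff)
  bias <- suppressWarnings(biasMetrics(scores, zThreshold))
  new("BenchmarkResult", methodName = scores@methodName,
      n = length(scores@z), rp = rp, rs = rs, auc = auc,
      tp = cf$tp, fp = cf$fp, tn = cf$tn, fn = cf$fn, mcc = cf$mcc,
      fpr = cf$fpr, fnr = cf$fnr, tpr = cf$tpr, bias = bias,
      isBinary = scores@isBinary)
}

#' Rank predictors by absolute Pearson correlation
#'
#' Orders benchmark results from best to worst by |R_P| (descending),
#' breaking ties by AUC (descending, `NA` last) and then by method name.
#' Methods with undefined R_P sort last. The output is independent of the
#' input order.
#'
#' @param results list of [BenchmarkResult-class] objects.
#' @return the reordered list.
#' @export
rankMethods <- function(results) {
  if (is(results, "BenchmarkResult")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, is, TRUE, "BenchmarkResult")))
  absRp <- abs(vapply(results, function(r) r@rp, 0))
  auc <- vapply(results, function(r) r@auc, 0)
  nm <- vapply(results, methodName, "")
  ord <- order(is.na(absRp), -ifelse(is.na(absRp), Inf, absRp),
               is.na(auc), -ifelse(is.na(auc), Inf, auc), nm)
  results[ord]
}

#' Benchmark summary table
#'
#' Flattens a list of benchmark results into a data.frame, one row per
#' method, in the given order.
#'
#' @param results list of [BenchmarkResult-class] objects.
#' @return data.frame with the metric columns.
#' @export
benchmarkTable <- function(results) {
  if (is(results, "BenchmarkResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(method = r@methodName, n = r@n, R_P = r@rp, R_S = r@rs,
               AUC = r@auc, MCC = r@mcc, FPR = r@fpr, FNR = r@fnr,
               pZL = r@bias@pZL, pZH = r@bias@pZH, pZA = r@bias@pZA,
               pZD = r@bias@pZD, TP = r@tp, FP = r@fp, TN = r@tn,
               FN = r@fn, is_binary = r@isBinary,
               stringsAsFactors = FALSE)))
}

#' Optimal Z-score threshold for binary classification
#'
#' Scans a grid of candidate Z thresholds and returns the one maximising
#' the mean MCC across methods (each method at its configured probability
#' cutoff) -- the threshold giving the best binary order/disorder
#' agreement for all methods on average. Ties are broken toward 8.0,
#' then toward the smaller threshold.
#'
#' @param scoresList list of [PairedScores-class], one per method.
#' @param grid candidate thresholds (default 0 to 16 by 0.5).
#' @param pCutoffs scalar or per-method named vector of probability
#'   cutoffs (default 0.5).
#' @return list with `best` (scalar threshold) and `table` (data.frame
#'   `threshold`, `meanMCC`).
#' @export
optimalZThreshold <- function(scoresList, grid = seq(0, 16, by = 0.5),
                              pCutoffs = 0.5) {
  if (is(scoresList, "PairedScores")) scoresList <- list(scoresList)
  stopifnot(length(scoresList) >= 1L, length(grid) >= 1L,
            all(vapply(scoresList, is, TRUE, "PairedScores")))
  cutoffFor <- function(s) {
    if (length(pCutoffs) == 1L && is.null(names(pCutoffs)))
      return(unname(pCutoffs))
    if (s@methodName %in% names(pCutoffs))
      return(unname(pCutoffs[[s@methodName]]))
    0.5
  }
  meanMCC <- vapply(grid, function(th)
    mean(vapply(scoresList, function(s)
      confusionStats(s, zThreshold = th, pCutoff = cutoffFor(s))$mcc, 0)),
    0)
  if (all(is.na(meanMCC))) stop("objective undefined on the whole grid")
  best <- which(meanMCC == max(meanMCC, na.rm = TRUE))
  best <- best[order(abs(grid[best] - 8.0), grid[best])][1L]
  list(best = grid[best],
       table = data.frame(threshold = grid, meanMCC = meanMCC))
}
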