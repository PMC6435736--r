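## Benchmark report writer: a human-readable TSV (3 decimals, "n.a." for
## undefined fields) plus a machine-readable JSON twin at full precision.

.REPORT_COLUMNS <- c("Method", "R_P", "R_S", "AUC", "MCC", "pZL", "pZH",
                     "pZA", "pZD", "TP", "FP", "TN", "FN")

.resultRow <- function(r) {
  list(method = r@methodName, n = r@n, is_binary = r@isBinary,
       R_P = r@rp, R_S = r@rs, AUC = r@auc, MCC = r@mcc,
       FPR = r@fpr, FNR = r@fnr, TPR = r@tpr,
       pZL = r@bias@pZL, pZH = r@bias@pZH, pZA = r@bias@pZA,
       pZD = r@bias@pZD, nL = r@bias@nL, nH = r@bias@nH,
       TP = r@tp, FP = r@fp, TN = r@tn, FN = r@fn)
}

#' Write a benchmark report (TSV + JSON twin)
#'
#' Writes one row per method with columns Method, R_P, R_S, AUC, MCC,
#' pZL, pZH, pZA, pZD, TP, FP, TN, FN. Metrics are rounded to 3 decimals
#' in the TSV and undefined fields (Spearman correlation and AUC of
#' binary methods, or degenerate inputs) are written as `n.a.`. A JSON
#' twin holding every field at full precision (undefined as `null`) is
#' written alongside with extension `.json`.
#'
#' @param results list of [BenchmarkResult-class] objects (at least one).
#' @param path TSV output path; the JSON twin replaces its extension.
#' @return invisible character vector `c(tsv, json)` of the written paths.
#' @seealso [readBenchmarkReport()]
#' @export
writeBenchmarkReport <- function(results, path) {
  if (is(results, "BenchmarkResult")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, is, TRUE, "BenchmarkResult")))
  fmt <- function(x) ifelse(is.na(x), "n.a.", sprintf("%.3f", x))
  rows <- vapply(results, function(r) {
    paste(c(r@methodName, fmt(c(r@rp, r@rs, r@auc, r@mcc, r@bias@pZL,
                                r@bias@pZH, r@bias@pZA, r@bias@pZD)),
            r@tp, r@fp, r@tn, r@fn), collapse = "\t")
  }, "")
  writeLines(c(paste(.REPORT_COLUMNS, collapse = "\t"), rows), path)
  jsonPath <- paste0(sub("\\.[^.]*$", "", path), ".json")
  jsonlite::write_json(lapply(results, .resultRow), jsonPath,
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       na = "null", pretty = TRUE)
  invisible(c(path, jsonPath))
}

#' Read back the JSON twin of a benchmark report
#'
#' @param path the `.json` file written by [writeBenchmarkReport()].
#' @return list of per-method field lists (numeric `NA` for `null`).
#' @export
readBenchmarkReport <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(r)
    lapply(r, function(v) if (is.null(v)) NA_real_ else v))
}
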