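## Residue-level alignment of Z-score and prediction profiles.

#' Pair Z-scores with predicted probabilities
#'
#' Intersects a Z-score profile and a prediction on residue number,
#' preserving order. Residues present in only one profile are excluded
#' from all downstream metrics. An amino-acid type is not compared
#' (predictor servers may renumber or substitute); only the numbering is.
#'
#' @param z a [ZScoreProfile-class].
#' @param pred a [DisorderPrediction-class].
#' @return a [PairedScores-class].
#' @export
pairScores <- function(z, pred) {
  stopifnot(is(z, "ZScoreProfile"), is(pred, "DisorderPrediction"))
  if (!nResidues(z) || !nResidues(pred))
    stop("cannot pair empty profiles")
  common <- intersect(z@residues$resno, pred@residues$resno)
  if (!length(common))
    stop("no residues in common between '", entryId(z), "' and '",
         methodName(pred), "'")
  zi <- match(common, z@residues$resno)
  pi <- match(common, pred@residues$resno)
  new("PairedScores", entryId = entryId(z), methodName = methodName(pred),
      z = z@residues$z[zi], p = pred@residues$p[pi],
      isBinary = isBinary(pred))
}

#' Pool paired scores across proteins
#'
#' Concatenates per-protein [PairedScores-class] objects of the same
#' method into one pooled object (the default benchmarking mode: metrics
#' are computed over all residues pooled across the cohort).
#'
#' @param scoresList list of [PairedScores-class] for one method.
#' @return a pooled [PairedScores-class] with `entryId = "pooled"`.
#' @export
poolScores <- function(scoresList) {
  if (is(scoresList, "PairedScores")) scoresList <- list(scoresList)
  stopifnot(length(scoresList) >= 1L,
            all(vapply(scoresList, is, TRUE, "PairedScores")))
  nm <- unique(vapply(scoresList, methodName, ""))
  if (length(nm) != 1L)
    stop("cannot pool scores of different methods: ",
         paste(nm, collapse = ", "))
  new("PairedScores", entryId = "pooled", methodName = nm,
      z = unlist(lapply(scoresList, zScores)),
      p = unlist(lapply(scoresList, probabilities)),
      isBinary = all(vapply(scoresList, isBinary, TRUE)))
}
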