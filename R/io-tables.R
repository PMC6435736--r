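## Plain-text tables: per-residue Z-scores (1-letter code, residue number,
## Z) and predictor outputs (residue number + value columns).

#' Read a per-residue Z-score table
#'
#' Whitespace-separated lines `aa resno Z`; lines starting with `#` and
#' blank lines are ignored. Residue numbers must be strictly increasing
#' and unique.
#'
#' @param path text file.
#' @param entryId identifier; defaults to the file base name.
#' @return a [ZScoreProfile-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("M 1 2.1", "K 2 13.0"), f)
#' readZScores(f)
#' @export
readZScores <- function(path, entryId = NULL) {
  if (is.null(entryId))
    entryId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep))
    stop("empty Z-score file '", path, "'")
  tok <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(tok) < 3L)
  if (length(bad))
    stop("line ", keep[bad[1]], ": expected 'aa resno Z'")
  aa <- vapply(tok, `[`, "", 1L)
  resno <- suppressWarnings(as.integer(vapply(tok, `[`, "", 2L)))
  z <- suppressWarnings(as.numeric(vapply(tok, `[`, "", 3L)))
  if (anyNA(resno))
    stop("line ", keep[which(is.na(resno))[1]], ": non-integer residue number")
  if (anyNA(z))
    stop("line ", keep[which(is.na(z))[1]], ": non-numeric Z-score")
  if (anyDuplicated(resno))
    stop("duplicate residue number ", resno[duplicated(resno)][1])
  if (any(diff(resno) <= 0))
    stop("residue numbers must be strictly increasing")
  ZScoreProfile(entryId, data.frame(resno = resno, aa = aa, z = z,
                                    stringsAsFactors = FALSE))
}

#' Write a Z-score table
#'
#' @param x a [ZScoreProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeZScores <- function(x, path) {
  stopifnot(is(x, "ZScoreProfile"))
  r <- x@residues
  writeLines(sprintf("%s %d %.17g", r$aa, r$resno, r$z), path)
  invisible(path)
}

#' Read a predictor output table
#'
#' Whitespace-separated per-residue values with the residue number in the
#' first column. The value-column semantics are declared by the caller:
#' `"probability"` (one column, p in `[0, 1]`), `"s2d"` (three columns:
#' helix, sheet and coil populations, converted with [s2dToPdis()]), or
#' `"dynamine"` (one column, backbone order parameter S-squared, converted
#' with [dynamineToPdis()]). Sparse tables (a subset of residues) are
#' allowed.
#'
#' @param path text file.
#' @param methodName predictor name stored on the result.
#' @param kind value-column semantics, see above.
#' @return a [DisorderPrediction-class].
#' @export
readPredictions <- function(path, methodName,
                            kind = c("probability", "s2d", "dynamine")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("empty prediction file '", path, "'")
  tok <- strsplit(trimws(lines[keep]), "\\s+")
  ncol <- if (kind == "s2d") 4L else 2L
  bad <- which(lengths(tok) < ncol)
  if (length(bad))
    stop("line ", keep[bad[1]], ": expected ", ncol, " columns")
  resno <- suppressWarnings(as.integer(vapply(tok, `[`, "", 1L)))
  if (anyNA(resno))
    stop("line ", keep[which(is.na(resno))[1]], ": non-integer residue number")
  vals <- vapply(2:ncol, function(j)
    suppressWarnings(as.numeric(vapply(tok, `[`, "", j))), numeric(length(tok)))
  vals <- matrix(vals, nrow = length(tok))
  if (anyNA(vals))
    stop("line ", keep[which(rowSums(is.na(vals)) > 0)[1]],
         ": non-numeric value")
  if (any(diff(resno) <= 0))
    stop("residue numbers must be strictly increasing")
  p <- switch(kind,
    probability = {
      if (any(vals[, 1] < 0 | vals[, 1] > 1))
        stop("probability outside [0, 1] at residue ",
             resno[which(vals[, 1] < 0 | vals[, 1] > 1)[1]])
      vals[, 1]
    },
    s2d = s2dToPdis(vals[, 1], vals[, 2]),
    dynamine = dynamineToPdis(vals[, 1]))
  DisorderPrediction(methodName, data.frame(resno = resno, p = p))
}

#' Write a prediction table
#'
#' @param x a [DisorderPrediction-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(x, path) {
  stopifnot(is(x, "DisorderPrediction"))
  r <- x@residues
  writeLines(sprintf("%d %.17g", r$resno, r$p), path)
  invisible(path)
}
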