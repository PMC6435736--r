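## Coordinate route to the order parameter: inter-atomic (CA-CA) distance
## variance matrix -> rank-weighted residue coordinate variation t (A).
## Superposition-free by construction: internal distances are invariant
## under per-conformer rigid motion.

#' Inter-atomic variance matrix of an ensemble
#'
#' For every CA pair (i, j), the population variance (divisor N) of the
#' CA(i)-CA(j) distance over the N conformers,
#' \deqn{v_{ij} = \frac{1}{N}\sum_k (d_{ijk} - \bar d_{ij})^2,}
#' together with the mean-distance matrix.
#'
#' @param ensemble an [EnsembleStructure-class] with at least 2 conformers
#'   and 4 residues.
#' @return a [VarianceMatrix-class].
#' @export
buildIVM <- function(ensemble) {
  stopifnot(is(ensemble, "EnsembleStructure"))
  N <- nConformers(ensemble)
  L <- nResidues(ensemble)
  if (N < 2L) stop("variance matrix needs at least 2 conformers")
  if (L < 4L) stop("variance matrix needs at least 4 residues")
  ca <- atomCoordinates(ensemble, "CA")
  dists <- lapply(seq_len(N), function(k)
    as.matrix(stats::dist(ca[, , k])))
  dbar <- Reduce(`+`, dists) / N
  ## two-pass population variance: exactly zero for identical conformers
  v <- Reduce(`+`, lapply(dists, function(d) (d - dbar)^2)) / N
  v <- (v + t(v)) / 2
  diag(v) <- 0
  new("VarianceMatrix", resno = residueNumbers(ensemble), v = v, dbar = dbar)
}

#' Residue coordinate variation t from the variance matrix
#'
#' For each residue i the row of variances is taken excluding the
#' diagonal and the next-to-diagonal elements (|i-j| <= 1), sorted
#' ascending into lambda(i,1) <= ... <= lambda(i,n) with n the number of
#' retained elements of that row, and averaged with rank weights that
#' emphasise the most invariant distances:
#' \deqn{t(i) = \frac{\sum_j w_j \sqrt{\lambda_{ij}}}{\sum_j w_j},\quad
#'   w_j = e^{-\beta (j/n)^2}.}
#'
#' @param ivm a [VarianceMatrix-class].
#' @param beta rank-weight decay (default 10).
#' @return numeric vector t per residue in Angstrom.
#' @export
coordVariation <- function(ivm, beta = 10) {
  stopifnot(is(ivm, "VarianceMatrix"), beta > 0)
  L <- nrow(ivm@v)
  vapply(seq_len(L), function(i) {
    j <- which(abs(seq_len(L) - i) > 1L)
    if (!length(j)) return(NA_real_)
    lambda <- sort(ivm@v[i, j])
    n <- length(lambda)
    w <- exp(-beta * (seq_len(n) / n)^2)
    sum(w * sqrt(lambda)) / sum(w)
  }, 0)
}
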