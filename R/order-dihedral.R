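## Dihedral-angle route to the per-residue order parameter: phi/psi across
## the ensemble -> circular order parameter per angle -> residue-level
## concentration D -> angular standard deviation s (degrees).

#' Backbone dihedral angles of an ensemble
#'
#' Computes IUPAC phi (C'(i-1)-N(i)-CA(i)-C'(i)) and psi
#' (N(i)-CA(i)-C'(i)-N(i+1)) for every residue and conformer, in degrees
#' on (-180, 180]. Angles are undefined (`NA`) at the chain termini (phi
#' of the first residue, psi of the last), wherever a required backbone
#' atom is absent, and across chain breaks: if the CA(i)-CA(i+1) distance
#' exceeds `breakCutoff` in any conformer, the spanning dihedrals psi(i)
#' and phi(i+1) are undefined in all conformers.
#'
#' @param ensemble an [EnsembleStructure-class].
#' @param breakCutoff chain-break CA-CA distance cutoff in Angstrom
#'   (default 4.5, a generous bound on trans/cis peptide geometry).
#' @return a [DihedralSet-class].
#' @export
computeDihedrals <- function(ensemble, breakCutoff = 4.5) {
  stopifnot(is(ensemble, "EnsembleStructure"))
  L <- nResidues(ensemble); N <- nConformers(ensemble)
  co <- ensemble@coords
  phi <- matrix(NA_real_, L, N)
  psi <- matrix(NA_real_, L, N)
  if (L >= 2L) {
    ## chain breaks: any conformer with consecutive CA-CA > cutoff
    ca <- atomCoordinates(ensemble, "CA")
    gap <- sqrt(apply((ca[-1L, , , drop = FALSE] -
                       ca[-L, , , drop = FALSE])^2, c(1, 3), sum))
    broken <- apply(gap > breakCutoff, 1L, any)   # length L-1
    for (k in seq_len(N)) {
      for (i in seq_len(L)) {
        if (i > 1L && !broken[i - 1L]) {
          pts <- list(co[i - 1L, 3L, , k], co[i, 1L, , k],
                      co[i, 2L, , k], co[i, 3L, , k])
          if (!anyNA(unlist(pts)))
            phi[i, k] <- .torsion(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
        }
        if (i < L && !broken[i]) {
          pts <- list(co[i, 1L, , k], co[i, 2L, , k],
                      co[i, 3L, , k], co[i + 1L, 1L, , k])
          if (!anyNA(unlist(pts)))
            psi[i, k] <- .torsion(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
        }
      }
    }
  }
  ## an angle is defined in all conformers or in none
  phi[rowSums(is.na(phi)) > 0L, ] <- NA_real_
  psi[rowSums(is.na(psi)) > 0L, ] <- NA_real_
  new("DihedralSet", resno = residueNumbers(ensemble), phi = phi, psi = psi)
}

#' Circular order parameter of one dihedral angle
#'
#' The ensemble concentration statistic
#' \deqn{S_{HW}(\theta) = \frac{1}{N}\sqrt{\left(\sum_i \sin\theta_i\right)^2
#'   + \left(\sum_i \cos\theta_i\right)^2}}
#' i.e. the length of the mean unit vector on the circle: 1 when all N
#' angles coincide, 0 under symmetric cancellation.
#'
#' @param angles numeric vector of angles in degrees (N >= 1, no `NA`).
#' @return scalar in `[0, 1]`.
#' @examples
#' shw(c(42, 42, 42))   # 1
#' shw(c(0, 90, 180, 270))  # 0
#' @export
shw <- function(angles) {
  if (!length(angles) || anyNA(angles))
    stop("shw() needs at least one defined angle")
  rad <- angles * pi / 180
  sqrt(sum(sin(rad))^2 + sum(cos(rad))^2) / length(angles)
}

#' Residue-level dihedral order parameter D
#'
#' Averages the circular order parameters of the six dihedrals flanking
#' residue i (phi and psi of residues i-1, i, i+1); with all six defined
#' this is the printed six-term sum divided by 6. At termini and chain
#' breaks the average runs over the defined terms only (divisor = number
#' of defined terms), keeping D in `[0, 1]`; a residue with no defined
#' flanking angle gets `NA`.
#'
#' @param dihedrals a [DihedralSet-class].
#' @return numeric vector D per residue, `NA` where undefined.
#' @export
dihedralOrderProfile <- function(dihedrals) {
  stopifnot(is(dihedrals, "DihedralSet"))
  L <- length(dihedrals@resno)
  if (L < 3L) stop("need at least 3 residues")
  sPhi <- apply(dihedrals@phi, 1L, function(a)
    if (anyNA(a)) NA_real_ else shw(a))
  sPsi <- apply(dihedrals@psi, 1L, function(a)
    if (anyNA(a)) NA_real_ else shw(a))
  vapply(seq_len(L), function(i) {
    j <- intersect((i - 1L):(i + 1L), seq_len(L))
    terms <- c(sPhi[j], sPsi[j])
    terms <- terms[!is.na(terms)]
    if (!length(terms)) NA_real_ else mean(terms)
  }, 0)
}

#' Angular standard deviation from the order parameter D
#'
#' Inverts the circular concentration into an effective torsion-angle
#' standard deviation, \eqn{s = 2\arccos(1 + \ln(D)/2)}, reported in
#' degrees. The arccos argument is clamped to `[-1, 1]`; clamping engages
#' only for D below `exp(-4)`, where s saturates at 360 degrees.
#'
#' @param D numeric vector in `(0, 1]` (`NA` passed through).
#' @return s in degrees, same length as `D`.
#' @examples
#' angleStd(1)          # 0
#' angleStd(exp(-4))    # 360
#' @export
angleStd <- function(D) {
  if (any(D <= 0, na.rm = TRUE))
    stop("D must be strictly positive")
  arg <- pmin(1, pmax(-1, 1 + log(D) / 2))
  2 * acos(arg) * 180 / pi
}
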