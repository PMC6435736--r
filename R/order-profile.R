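## Composition of the two routes into the per-residue order parameters
## S (dihedral) and T (coordinate).

#' Map variation measures onto order parameters
#'
#' Lorentzian mapping of the angular standard deviation s (degrees) and
#' the coordinate variation t (Angstrom) onto `(0, 1]`:
#' \deqn{S = \frac{1}{1 + (s/s_0)^2}, \qquad T = \frac{1}{1 + (t/t_0)^2}}
#' with reference values s0 = 75 degrees and t0 = 1.5 Angstrom. Zero
#' variation maps to 1; variation equal to the reference maps to 0.5.
#'
#' @param s angular standard deviation(s) in degrees (>= 0, `NA` allowed).
#' @param t coordinate variation(s) in Angstrom (>= 0, `NA` allowed).
#' @param config an [OrderConfig-class].
#' @return list with components `S` and `T`.
#' @examples
#' orderParams(75, 1.5)       # both 0.5
#' orderParams(0, 3.0)$T      # 0.2
#' @export
orderParams <- function(s, t, config = orderConfig()) {
  stopifnot(is(config, "OrderConfig"))
  if (any(s < 0, na.rm = TRUE) || any(t < 0, na.rm = TRUE))
    stop("s and t must be non-negative")
  list(S = 1 / (1 + (s / config@s0)^2),
       T = 1 / (1 + (t / config@t0)^2))
}

#' Per-residue order-parameter profile of an ensemble
#'
#' Runs the full pipeline on a multi-conformer ensemble: backbone
#' dihedrals, circular order parameter D and angular standard deviation s
#' per residue; CA-CA variance matrix and rank-weighted coordinate
#' variation t; and the order parameters S and T. Undefined positions
#' (termini, chain breaks, missing atoms) are flagged `NA`, never
#' silently zero.
#'
#' @param ensemble an [EnsembleStructure-class] with N >= 2 conformers.
#' @param config an [OrderConfig-class].
#' @param breakCutoff chain-break cutoff passed to [computeDihedrals()].
#' @return an [OrderParameterProfile-class].
#' @examples
#' ens <- genEnsemble(generatorConfig(seed = 3, L = 30))$ensemble
#' prof <- ensembleOrderProfile(ens)
#' head(orderTable(prof))
#' @export
ensembleOrderProfile <- function(ensemble, config = orderConfig(),
                                 breakCutoff = 4.5) {
  stopifnot(is(ensemble, "EnsembleStructure"), is(config, "OrderConfig"))
  if (nConformers(ensemble) < 2L)
    stop("order parameters need at least 2 conformers")
  dih <- computeDihedrals(ensemble, breakCutoff = breakCutoff)
  D <- dihedralOrderProfile(dih)
  s <- angleStd(D)
  ivm <- buildIVM(ensemble)
  t <- coordVariation(ivm, beta = config@beta)
  st <- orderParams(s, t, config)
  prof <- data.frame(resno = residueNumbers(ensemble),
                     resname = ensemble@residues$resname,
                     D = D, s = s, S = st$S, t = t, T = st$T,
                     stringsAsFactors = FALSE)
  new("OrderParameterProfile", entryId = entryId(ensemble), profile = prof)
}

#' Write an order-parameter profile as TSV
#'
#' Columns: resno, resname, D, s_deg, S, t_A, T; undefined values are
#' written as `n.a.`.
#'
#' @param x an [OrderParameterProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeOrderProfile <- function(x, path) {
  stopifnot(is(x, "OrderParameterProfile"))
  p <- x@profile
  fmt <- function(v) ifelse(is.na(v), "n.a.", sprintf("%.6f", v))
  writeLines(c(paste(c("resno", "resname", "D", "s_deg", "S", "t_A", "T"),
                     collapse = "\t"),
               paste(p$resno, p$resname, fmt(p$D), fmt(p$s), fmt(p$S),
                     fmt(p$t), fmt(p$T), sep = "\t")), path)
  invisible(path)
}
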