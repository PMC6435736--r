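## Central S4 containers. Coordinates are stored in a dense 4-d array
## [residue, atom (N/CA/C), xyz, conformer] so that distance and dihedral
## kernels can vectorise over conformers without list traversal.

.BACKBONE_ATOMS <- c("N", "CA", "C")

#' Multi-conformer protein backbone ensemble
#'
#' Holds the N conformers of an NMR-style structure ensemble restricted to
#' the backbone atoms N, CA and C of a single chain. All conformers share
#' the same ordered residue set; every residue has a CA atom in every
#' conformer (residues violating this are dropped at read time). N and C
#' may be absent (`NA`) for individual residues, in which case the
#' dihedrals that depend on them are undefined downstream.
#'
#' @slot entryId character scalar, entry identifier.
#' @slot residues data.frame with columns `chain`, `resno`, `resname`, one
#'   row per residue, in file order.
#' @slot coords numeric array `[nResidues, 3 atoms (N, CA, C), 3 xyz,
#'   nConformers]`, coordinates in Angstrom.
#'
#' @seealso [readPdbEnsemble()], [genEnsemble()], [ensembleOrderProfile()]
#' @export
setClass("EnsembleStructure",
  representation(entryId = "character", residues = "data.frame",
                 coords = "array"))

setValidity("EnsembleStructure", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(object@entryId) != 1L)
    msg <- c(msg, "'entryId' must be a single string")
  if (length(d) != 4L || d[2] != 3L || d[3] != 3L)
    msg <- c(msg, "'coords' must be a [residues, 3, 3, conformers] array")
  else {
    if (d[4] < 1L) msg <- c(msg, "ensemble needs at least one conformer")
    if (d[1] != nrow(object@residues))
      msg <- c(msg, "coords/residues dimension mismatch")
    ca <- object@coords[, 2L, , , drop = FALSE]
    if (anyNA(ca) || any(!is.finite(ca)))
      msg <- c(msg, "every residue needs finite CA coordinates in every conformer")
    other <- object@coords[, c(1L, 3L), , , drop = FALSE]
    if (any(!is.finite(other[!is.na(other)])))
      msg <- c(msg, "non-finite backbone coordinates")
  }
  if (!all(c("chain", "resno", "resname") %in% names(object@residues)))
    msg <- c(msg, "'residues' needs chain/resno/resname columns")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnsembleStructure constructor.
#' @param entryId entry identifier.
#' @param residues residue table (`chain`, `resno`, `resname`).
#' @param coords coordinate array `[residue, atom, xyz, conformer]`.
#' @export
EnsembleStructure <- function(entryId, residues, coords) {
  dimnames(coords) <- list(NULL, .BACKBONE_ATOMS, c("x", "y", "z"), NULL)
  new("EnsembleStructure", entryId = as.character(entryId),
      residues = residues, coords = coords)
}

#' Per-residue chemical-shift Z-score profile
#'
#' Continuous per-residue measure of structural order derived from NMR
#' chemical shifts: high Z means ordered, low Z disordered; Z < 8 is the
#' conventional binary disorder criterion.
#'
#' @slot entryId character scalar.
#' @slot residues data.frame with columns `resno` (strictly increasing
#'   integers), `aa` (1-letter code, 20 amino acids plus `X`) and `z`
#'   (finite numeric).
#' @seealso [readZScores()], [genZScores()], [pairScores()]
#' @export
setClass("ZScoreProfile",
  representation(entryId = "character", residues = "data.frame"))

setValidity("ZScoreProfile", function(object) {
  r <- object@residues
  msg <- character()
  if (!all(c("resno", "aa", "z") %in% names(r)))
    msg <- c(msg, "'residues' needs resno/aa/z columns")
  else {
    if (nrow(r) && any(diff(r$resno) <= 0))
      msg <- c(msg, "residue numbers must be strictly increasing")
    if (any(!is.finite(r$z)))
      msg <- c(msg, "Z-scores must be finite")
    if (!all(r$aa %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")))
      msg <- c(msg, "amino-acid codes must be 1-letter (or 'X')")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ZScoreProfile constructor.
#' @param entryId entry identifier.
#' @param residues data.frame with `resno`, `aa`, `z`.
#' @export
ZScoreProfile <- function(entryId, residues) {
  residues$resno <- as.integer(residues$resno)
  rownames(residues) <- NULL
  new("ZScoreProfile", entryId = as.character(entryId), residues = residues)
}

#' Per-residue disorder prediction of one method
#'
#' Estimated probability of disorder p in `[0, 1]` per residue, possibly
#' sparse (a subset of the protein's residues). `isBinary` is `TRUE` iff
#' every p is exactly 0 or 1; binary methods are excluded from Spearman
#' correlation and AUC during benchmarking.
#'
#' @slot methodName predictor name.
#' @slot residues data.frame with `resno` (strictly increasing) and `p`.
#' @slot isBinary logical scalar.
#' @seealso [readPredictions()], [genPredictions()], [benchmarkMethod()]
#' @export
setClass("DisorderPrediction",
  representation(methodName = "character", residues = "data.frame",
                 isBinary = "logical"))

setValidity("DisorderPrediction", function(object) {
  r <- object@residues
  msg <- character()
  if (!all(c("resno", "p") %in% names(r)))
    msg <- c(msg, "'residues' needs resno/p columns")
  else {
    if (nrow(r) && any(diff(r$resno) <= 0))
      msg <- c(msg, "residue numbers must be strictly increasing")
    if (any(!is.finite(r$p)) || any(r$p < 0) || any(r$p > 1))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@isBinary != all(r$p %in% c(0, 1)))
      msg <- c(msg, "'isBinary' inconsistent with probabilities")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DisorderPrediction constructor; `isBinary` is detected from
#'   the probabilities.
#' @param methodName predictor name.
#' @param residues data.frame with `resno`, `p`.
#' @export
DisorderPrediction <- function(methodName, residues) {
  residues$resno <- as.integer(residues$resno)
  rownames(residues) <- NULL
  new("DisorderPrediction", methodName = as.character(methodName),
      residues = residues, isBinary = all(residues$p %in% c(0, 1)))
}

#' Observed/missing labels for an X-ray entry
#'
#' One label per SEQRES residue: `missing` if the residue is listed in
#' REMARK 465 or absent from the coordinate section, `observed` otherwise.
#' Missing density is the X-ray proxy for local disorder.
#'
#' @slot entryId character scalar.
#' @slot labels data.frame with `resno` and `status`
#'   (`"observed"`/`"missing"`), one row per SEQRES residue.
#' @seealso [readMissingResidues()], [genXrayLabels()]
#' @export
setClass("MissingResidueLabels",
  representation(entryId = "character", labels = "data.frame"))

setValidity("MissingResidueLabels", function(object) {
  l <- object@labels
  msg <- character()
  if (!all(c("resno", "status") %in% names(l)))
    msg <- c(msg, "'labels' needs resno/status columns")
  else if (!all(l$status %in% c("observed", "missing")))
    msg <- c(msg, "status must be 'observed' or 'missing'")
  if (length(msg)) msg else TRUE
})

#' @describeIn MissingResidueLabels constructor.
#' @param entryId entry identifier.
#' @param labels data.frame with `resno`, `status`.
#' @export
MissingResidueLabels <- function(entryId, labels) {
  labels$resno <- as.integer(labels$resno)
  rownames(labels) <- NULL
  new("MissingResidueLabels", entryId = as.character(entryId), labels = labels)
}

#' Backbone dihedral angles of an ensemble
#'
#' Per-residue, per-conformer phi/psi in degrees on (-180, 180]. `NA`
#' marks undefined angles: phi of the first residue, psi of the last, and
#' all angles spanning a chain break or a missing backbone atom. An angle
#' is undefined either in all conformers or in none.
#'
#' @slot resno integer residue numbers.
#' @slot phi,psi numeric matrices `[residue, conformer]` in degrees.
#' @seealso [computeDihedrals()]
#' @export
setClass("DihedralSet",
  representation(resno = "integer", phi = "matrix", psi = "matrix"))

setValidity("DihedralSet", function(object) {
  msg <- character()
  for (nm in c("phi", "psi")) {
    m <- slot(object, nm)
    if (nrow(m) != length(object@resno))
      msg <- c(msg, sprintf("'%s' row count != residue count", nm))
    bad <- rowSums(is.na(m))
    if (any(bad != 0L & bad != ncol(m)))
      msg <- c(msg, sprintf("'%s' rows must be defined in all conformers or none", nm))
    v <- m[!is.na(m)]
    if (any(!is.finite(v)) || any(v <= -180 | v > 180))
      msg <- c(msg, sprintf("'%s' angles must be finite and in (-180, 180]", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Inter-atomic (CA-CA) distance variance matrix
#'
#' Population variance over conformers of every CA(i)-CA(j) distance,
#' together with the companion mean-distance matrix. Superposition-free:
#' internal distances are invariant under per-conformer rigid motion.
#'
#' @slot resno integer residue numbers.
#' @slot v symmetric variance matrix (A^2), zero diagonal.
#' @slot dbar mean CA-CA distance matrix (A).
#' @seealso [buildIVM()], [coordVariation()]
#' @export
setClass("VarianceMatrix",
  representation(resno = "integer", v = "matrix", dbar = "matrix"))

setValidity("VarianceMatrix", function(object) {
  msg <- character()
  if (!isSymmetric(object@v, tol = 1e-8))
    msg <- c(msg, "'v' must be symmetric")
  if (any(object@v < -1e-12))
    msg <- c(msg, "variances must be non-negative")
  if (any(abs(diag(object@v)) > 1e-12))
    msg <- c(msg, "diagonal of 'v' must be zero")
  if (length(msg)) msg else TRUE
})

#' Per-residue structural order parameters
#'
#' The result of the ensemble order-parameter pipeline: the dihedral
#' concentration D in `[0, 1]`, its angular standard deviation s (degrees),
#' the coordinate variation t (Angstrom), and the order parameters
#' S = 1/(1 + (s/s0)^2) and T = 1/(1 + (t/t0)^2), both in (0, 1]. `NA`
#' flags positions where a quantity is undefined (never silently zero).
#'
#' @slot entryId character scalar.
#' @slot profile data.frame with columns `resno`, `resname`, `D`, `s`,
#'   `S`, `t`, `T`.
#' @seealso [ensembleOrderProfile()]
#' @export
setClass("OrderParameterProfile",
  representation(entryId = "character", profile = "data.frame"))

setValidity("OrderParameterProfile", function(object) {
  p <- object@profile
  need <- c("resno", "resname", "D", "s", "S", "t", "T")
  msg <- character()
  if (!all(need %in% names(p)))
    msg <- c(msg, "'profile' must have resno/resname/D/s/S/t/T columns")
  else {
    ok <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi))
    if (!ok(p$D, 0, 1)) msg <- c(msg, "D out of [0, 1]")
    if (!ok(p$S, 0, 1) || !ok(p$T, 0, 1)) msg <- c(msg, "S/T out of (0, 1]")
    if (!all(is.na(p$s) | p$s >= 0) || !all(is.na(p$t) | p$t >= 0))
      msg <- c(msg, "s/t must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Reference constants for the order parameters
#'
#' @slot s0 angular reference in degrees (default 75).
#' @slot t0 distance reference in Angstrom (default 1.5).
#' @slot beta rank-weight decay of the coordinate variation (default 10).
#' @export
setClass("OrderConfig",
  representation(s0 = "numeric", t0 = "numeric", beta = "numeric"))

setValidity("OrderConfig", function(object) {
  if (any(c(object@s0, object@t0, object@beta) <= 0))
    "s0, t0 and beta must be strictly positive" else TRUE
})

#' @describeIn OrderConfig constructor with the reference defaults
#'   s0 = 75 degrees, t0 = 1.5 Angstrom, beta = 10.
#' @param s0,t0,beta see slots.
#' @export
orderConfig <- function(s0 = 75, t0 = 1.5, beta = 10)
  new("OrderConfig", s0 = s0, t0 = t0, beta = beta)

#' Aligned (Z, p) pairs for one method
#'
#' Z-scores and predicted disorder probabilities matched on residue
#' number; residues present in only one profile are excluded. All
#' benchmarking metrics consume this container.
#'
#' @slot entryId provenance (entry, or `"pooled"`).
#' @slot methodName predictor name.
#' @slot z,p aligned numeric vectors.
#' @slot isBinary whether the prediction is binary.
#' @seealso [pairScores()], [benchmarkMethod()]
#' @export
setClass("PairedScores",
  representation(entryId = "character", methodName = "character",
                 z = "numeric", p = "numeric", isBinary = "logical"))

setValidity("PairedScores", function(object) {
  msg <- character()
  if (length(object@z) != length(object@p))
    msg <- c(msg, "z and p must have equal length")
  if (anyNA(object@z) || anyNA(object@p))
    msg <- c(msg, "undefined entries are not allowed (exclude before pairing)")
  if (length(msg)) msg else TRUE
})

#' Bias/discrimination decomposition of a predictor
#'
#' Mean predicted disorder probability over residues with low Z (pZL,
#' Z < threshold) and high Z (pZH, Z > threshold); their average
#' pZA = (pZL + pZH)/2 measures bias (0.5 = unbiased) and their
#' difference pZD = pZL - pZH measures discrimination.
#'
#' @slot pZL,pZH,pZA,pZD numeric scalars.
#' @slot nL,nH residue counts below/above the threshold.
#' @seealso [biasMetrics()], [classifyBias()]
#' @export
setClass("BiasMetrics",
  representation(pZL = "numeric", pZH = "numeric", pZA = "numeric",
                 pZD = "numeric", nL = "integer", nH = "integer"))

#' One predictor's full benchmark row
#'
#' Continuous agreement (Pearson R_P, Spearman R_S), ROC AUC, the
#' confusion counts at the probability cutoff with MCC/FPR/FNR/TPR, and
#' the bias metrics. For binary methods R_S and AUC are `NA` by policy.
#'
#' @slot methodName predictor name.
#' @slot n number of matched residues.
#' @slot rp,rs,auc,mcc,fpr,fnr,tpr numeric scalars (`NA` when undefined).
#' @slot tp,fp,tn,fn confusion counts.
#' @slot bias a [BiasMetrics-class] object.
#' @slot isBinary whether the method is binary.
#' @seealso [benchmarkMethod()], [rankMethods()], [writeBenchmarkReport()]
#' @export
setClass("BenchmarkResult",
  representation(methodName = "character", n = "integer",
                 rp = "numeric", rs = "numeric", auc = "numeric",
                 tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer", mcc = "numeric", fpr = "numeric",
                 fnr = "numeric", tpr = "numeric", bias = "BiasMetrics",
                 isBinary = "logical"))

#' Discrete probability distribution over Z-score bins
#'
#' Uniform-width bins with open outer bins (overflow mass is assigned to
#' the first/last bin). Pairwise operations (KL, JSD) require identical
#' binning.
#'
#' @slot edges numeric bin edges (length nbins + 1, strictly increasing).
#' @slot mass non-negative masses summing to 1.
#' @seealso [histogramZ()], [jsDivergence()]
#' @export
setClass("DiscreteDistribution",
  representation(edges = "numeric", mass = "numeric"))

setValidity("DiscreteDistribution", function(object) {
  msg <- character()
  if (length(object@mass) != length(object@edges) - 1L)
    msg <- c(msg, "need length(edges) == length(mass) + 1")
  if (any(diff(object@edges) <= 0))
    msg <- c(msg, "edges must be strictly increasing")
  if (any(object@mass < 0) || abs(sum(object@mass) - 1) > 1e-9)
    msg <- c(msg, "masses must be non-negative and sum to 1")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic-data generator
#'
#' Defines the study conditions every simulated input is drawn under. The
#' Z-score mixture defaults (disordered 3.0 +/- 2.0, ordered 12.0 +/- 2.0)
#' straddle the Z = 8 disorder criterion with modest overlap, emulating
#' the bimodal Z-score distributions of chemical-shift databases. The
#' planted predictor takes level b + d/2 on disordered and b - d/2 on
#' ordered residues plus Gaussian noise, so its expected bias pZA is b and
#' expected discrimination pZD is d. Ensembles are poly-alanine backbones
#' whose phi/psi are perturbed per conformer with a per-residue amplitude
#' (degrees): `coreAmplitude` on ordered, `tailAmplitude` on disordered
#' residues.
#'
#' @slot seed integer; every generator draw flows from it.
#' @slot L protein length (>= 5).
#' @slot segments optional data.frame (`start`, `end`, `state`) with
#'   state `"ordered"`/`"disordered"`; overrides `fractionDisordered`.
#' @slot fractionDisordered fraction of residues planted disordered (the
#'   trailing segment of the chain).
#' @slot zMeanDis,zSdDis,zMeanOrd,zSdOrd Z mixture parameters.
#' @slot bias,discrimination,noiseSd planted predictor parameters.
#' @slot nConformers ensemble size N.
#' @slot coreAmplitude,tailAmplitude dihedral perturbation s.d. in degrees.
#' @seealso [genZScores()], [genPredictions()], [genEnsemble()]
#' @export
setClass("GeneratorConfig",
  representation(seed = "integer", L = "integer", segments = "data.frame",
                 fractionDisordered = "numeric",
                 zMeanDis = "numeric", zSdDis = "numeric",
                 zMeanOrd = "numeric", zSdOrd = "numeric",
                 bias = "numeric", discrimination = "numeric",
                 noiseSd = "numeric", nConformers = "integer",
                 coreAmplitude = "numeric", tailAmplitude = "numeric"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@L < 5L) msg <- c(msg, "L must be >= 5")
  if (object@fractionDisordered < 0 || object@fractionDisordered > 1)
    msg <- c(msg, "fractionDisordered must be in [0, 1]")
  if (nrow(object@segments)) {
    s <- object@segments
    if (any(s$start < 1L) || any(s$end > object@L) || any(s$start > s$end))
      msg <- c(msg, "segment bounds must lie within [1, L]")
    if (!all(s$state %in% c("ordered", "disordered")))
      msg <- c(msg, "segment state must be 'ordered' or 'disordered'")
  }
  if (any(c(object@zSdDis, object@zSdOrd) <= 0))
    msg <- c(msg, "Z component standard deviations must be positive")
  if (object@bias < 0 || object@bias > 1 ||
      object@discrimination < 0 || object@discrimination > 1)
    msg <- c(msg, "bias and discrimination must be in [0, 1]")
  if (object@noiseSd < 0 || object@coreAmplitude < 0 ||
      object@tailAmplitude < 0)
    msg <- c(msg, "noise and perturbation amplitudes must be >= 0")
  if (object@nConformers < 1L) msg <- c(msg, "nConformers must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneratorConfig constructor with the default study
#'   conditions.
#' @param seed,L,segments,fractionDisordered,zMeanDis,zSdDis,zMeanOrd,zSdOrd
#'   see slots.
#' @param bias,discrimination,noiseSd,nConformers,coreAmplitude,tailAmplitude
#'   see slots.
#' @export
generatorConfig <- function(seed = 1L, L = 100L, segments = NULL,
                            fractionDisordered = 0.3,
                            zMeanDis = 3.0, zSdDis = 2.0,
                            zMeanOrd = 12.0, zSdOrd = 2.0,
                            bias = 0.5, discrimination = 0.8,
                            noiseSd = 0.05, nConformers = 10L,
                            coreAmplitude = 3, tailAmplitude = 60) {
  if (is.null(segments))
    segments <- data.frame(start = integer(), end = integer(),
                           state = character())
  new("GeneratorConfig", seed = as.integer(seed), L = as.integer(L),
      segments = segments, fractionDisordered = fractionDisordered,
      zMeanDis = zMeanDis, zSdDis = zSdDis, zMeanOrd = zMeanOrd,
      zSdOrd = zSdOrd, bias = bias, discrimination = discrimination,
      noiseSd = noiseSd, nConformers = as.integer(nConformers),
      coreAmplitude = coreAmplitude, tailAmplitude = tailAmplitude)
}

## ---- accessors -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("entryId", "EnsembleStructure", function(x) x@entryId)
#' @rdname accessors
#' @export
setMethod("entryId", "ZScoreProfile", function(x) x@entryId)
#' @rdname accessors
#' @export
setMethod("entryId", "MissingResidueLabels", function(x) x@entryId)
#' @rdname accessors
#' @export
setMethod("entryId", "OrderParameterProfile", function(x) x@entryId)
#' @rdname accessors
#' @export
setMethod("entryId", "PairedScores", function(x) x@entryId)

#' @rdname accessors
#' @export
setMethod("methodName", "DisorderPrediction", function(x) x@methodName)
#' @rdname accessors
#' @export
setMethod("methodName", "PairedScores", function(x) x@methodName)
#' @rdname accessors
#' @export
setMethod("methodName", "BenchmarkResult", function(x) x@methodName)

#' @rdname accessors
#' @export
setMethod("residueNumbers", "EnsembleStructure",
          function(x) as.integer(x@residues$resno))
#' @rdname accessors
#' @export
setMethod("residueNumbers", "ZScoreProfile",
          function(x) as.integer(x@residues$resno))
#' @rdname accessors
#' @export
setMethod("residueNumbers", "DisorderPrediction",
          function(x) as.integer(x@residues$resno))
#' @rdname accessors
#' @export
setMethod("residueNumbers", "OrderParameterProfile",
          function(x) as.integer(x@profile$resno))
#' @rdname accessors
#' @export
setMethod("residueNumbers", "MissingResidueLabels",
          function(x) as.integer(x@labels$resno))

#' @rdname accessors
#' @export
setMethod("zScores", "ZScoreProfile", function(x) x@residues$z)
#' @rdname accessors
#' @export
setMethod("zScores", "PairedScores", function(x) x@z)

#' @rdname accessors
#' @export
setMethod("probabilities", "DisorderPrediction", function(x) x@residues$p)
#' @rdname accessors
#' @export
setMethod("probabilities", "PairedScores", function(x) x@p)

#' @rdname accessors
#' @export
setMethod("isBinary", "DisorderPrediction", function(x) x@isBinary)
#' @rdname accessors
#' @export
setMethod("isBinary", "PairedScores", function(x) x@isBinary)
#' @rdname accessors
#' @export
setMethod("isBinary", "BenchmarkResult", function(x) x@isBinary)

#' @rdname accessors
#' @export
setMethod("nConformers", "EnsembleStructure", function(x) dim(x@coords)[4L])
#' @rdname accessors
#' @export
setMethod("nResidues", "EnsembleStructure", function(x) dim(x@coords)[1L])
#' @rdname accessors
#' @export
setMethod("nResidues", "ZScoreProfile", function(x) nrow(x@residues))
#' @rdname accessors
#' @export
setMethod("nResidues", "DisorderPrediction", function(x) nrow(x@residues))

#' Residue table of an ensemble
#'
#' @param x an [EnsembleStructure-class].
#' @return data.frame with `chain`, `resno`, `resname`.
#' @export
residueTable <- function(x) {
  stopifnot(is(x, "EnsembleStructure"))
  x@residues
}

#' Coordinates of one backbone atom across the ensemble
#'
#' @param x an [EnsembleStructure-class].
#' @param atom one of `"N"`, `"CA"`, `"C"`.
#' @return numeric array `[nResidues, 3 xyz, nConformers]`.
#' @export
atomCoordinates <- function(x, atom = "CA") {
  stopifnot(is(x, "EnsembleStructure"))
  i <- match(match.arg(atom, .BACKBONE_ATOMS), .BACKBONE_ATOMS)
  out <- x@coords[, i, , , drop = FALSE]
  dim(out) <- dim(x@coords)[c(1L, 3L, 4L)]
  out
}

#' Order-parameter profile as a data.frame
#'
#' @param x an [OrderParameterProfile-class].
#' @return data.frame with `resno`, `resname`, `D`, `s`, `S`, `t`, `T`.
#' @export
orderTable <- function(x) {
  stopifnot(is(x, "OrderParameterProfile"))
  x@profile
}

#' Missing/observed labels as a data.frame
#'
#' @param x a [MissingResidueLabels-class].
#' @return data.frame with `resno`, `status`.
#' @export
labelTable <- function(x) {
  stopifnot(is(x, "MissingResidueLabels"))
  x@labels
}

## ---- show methods --------------------------------------------------------

setMethod("show", "EnsembleStructure", function(object) {
  cat(sprintf("EnsembleStructure '%s': %d conformers x %d residues (%s)\n",
              object@entryId, nConformers(object), nResidues(object),
              paste0("chain ", object@residues$chain[1])))
})

setMethod("show", "ZScoreProfile", function(object) {
  z <- object@residues$z
  cat(sprintf("ZScoreProfile '%s': %d residues, Z in [%.2f, %.2f]\n",
              object@entryId, nrow(object@residues),
              if (length(z)) min(z) else NA, if (length(z)) max(z) else NA))
})

setMethod("show", "DisorderPrediction", function(object) {
  cat(sprintf("DisorderPrediction '%s': %d residues%s\n",
              object@methodName, nrow(object@residues),
              if (object@isBinary) " (binary)" else ""))
})

setMethod("show", "MissingResidueLabels", function(object) {
  cat(sprintf("MissingResidueLabels '%s': %d missing / %d observed\n",
              object@entryId, sum(object@labels$status == "missing"),
              sum(object@labels$status == "observed")))
})

setMethod("show", "OrderParameterProfile", function(object) {
  p <- object@profile
  cat(sprintf(
    "OrderParameterProfile '%s': %d residues, mean S = %.3f, mean T = %.3f\n",
    object@entryId, nrow(p), mean(p$S, na.rm = TRUE),
    mean(p$T, na.rm = TRUE)))
})

setMethod("show", "PairedScores", function(object) {
  cat(sprintf("PairedScores '%s' vs '%s': n = %d\n", object@methodName,
              object@entryId, length(object@z)))
})

setMethod("show", "BiasMetrics", function(object) {
  cat(sprintf("BiasMetrics: pZL = %.3f, pZH = %.3f, pZA = %.3f, pZD = %.3f (nL = %d, nH = %d)\n",
              object@pZL, object@pZH, object@pZA, object@pZD,
              object@nL, object@nH))
})

setMethod("show", "BenchmarkResult", function(object) {
  fmt <- function(x) ifelse(is.na(x), "n.a.", sprintf("%.3f", x))
  cat(sprintf(
    "BenchmarkResult '%s' (n = %d): R_P = %s, R_S = %s, AUC = %s, MCC = %s, pZA = %s, pZD = %s\n",
    object@methodName, object@n, fmt(object@rp), fmt(object@rs),
    fmt(object@auc), fmt(object@mcc), fmt(object@bias@pZA),
    fmt(object@bias@pZD)))
})

setMethod("show", "DiscreteDistribution", function(object) {
  cat(sprintf("DiscreteDistribution: %d bins on [%g, %g] (open outer bins)\n",
              length(object@mass), min(object@edges), max(object@edges)))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: seed %d, L = %d, %.0f%% disordered, b = %.2f, d = %.2f, N = %d\n",
    object@seed, object@L, 100 * object@fractionDisordered, object@bias,
    object@discrimination, object@nConformers))
})
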