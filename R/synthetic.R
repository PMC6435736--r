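## Seeded synthetic-data generators. They emulate the statistical
## structure the analysis assumes -- bimodal Z-scores over
## ordered/disordered segments, predictors with planted bias and
## discrimination, conformer ensembles with planted flexibility -- so
## every pipeline stage can be exercised, and planted parameters
## recovered, without any external database. All generators are pure
## functions of their configuration: the RNG is seeded from
## `config@seed` (with a fixed per-generator offset so the draws of the
## different generators are independent) and the caller's RNG state is
## restored afterwards.

.plantedMask <- function(config) {
  mask <- rep(FALSE, config@L)
  if (nrow(config@segments)) {
    s <- config@segments
    for (i in seq_len(nrow(s)))
      mask[s$start[i]:s$end[i]] <- s$state[i] == "disordered"
  } else if (config@fractionDisordered > 0) {
    nDis <- round(config@fractionDisordered * config@L)
    if (nDis > 0) mask[seq(config@L - nDis + 1L, config@L)] <- TRUE
  }
  mask
}

#' Simulate a per-residue Z-score profile
#'
#' Draws Z from a two-component Gaussian mixture: residues planted
#' disordered from `N(zMeanDis, zSdDis)` (default 3.0 +/- 2.0) and
#' ordered ones from `N(zMeanOrd, zSdOrd)` (default 12.0 +/- 2.0),
#' reproducing the bimodal Z-score distribution that drives the
#' four-quadrant structure of Z-vs-p scatter plots.
#'
#' @param config a [GeneratorConfig-class].
#' @param entryId identifier of the simulated protein.
#' @return list with `profile` (a [ZScoreProfile-class]) and `mask`
#'   (logical vector, `TRUE` = planted disordered) for recovery tests.
#' @examples
#' sim <- genZScores(generatorConfig(seed = 11, L = 50))
#' sim$profile
#' @export
genZScores <- function(config = generatorConfig(), entryId = "sim") {
  stopifnot(is(config, "GeneratorConfig"))
  mask <- .plantedMask(config)
  z <- .withSeed(config@seed, {
    mu <- ifelse(mask, config@zMeanDis, config@zMeanOrd)
    sd <- ifelse(mask, config@zSdDis, config@zSdOrd)
    aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], config@L,
                 replace = TRUE)
    list(z = stats::rnorm(config@L, mu, sd), aa = aa)
  })
  list(profile = ZScoreProfile(entryId,
         data.frame(resno = seq_len(config@L), aa = z$aa, z = z$z,
                    stringsAsFactors = FALSE)),
       mask = mask)
}

#' Simulate a predictor with planted bias and discrimination
#'
#' Two-level additive-noise predictor: on planted-disordered residues
#' `p = b + d/2 + eps`, on ordered ones `p = b - d/2 + eps`, with
#' `eps ~ N(0, noiseSd)` and the result clamped to `[0, 1]`. When
#' clamping is inactive the expected bias pZA is b and the expected
#' discrimination pZD is d, making the planted pair an analytically exact
#' recovery target. A warning is issued when `b +/- d/2` leaves `[0, 1]`
#' by more than twice the noise, since clamping then biases recovery.
#'
#' @param z a [ZScoreProfile-class] (fixes the residue numbering).
#' @param mask logical planted-disorder mask parallel to `z`.
#' @param config a [GeneratorConfig-class] (uses `bias`,
#'   `discrimination`, `noiseSd`, `seed`).
#' @param methodName name stored on the prediction.
#' @return a [DisorderPrediction-class].
#' @export
genPredictions <- function(z, mask, config = generatorConfig(),
                           methodName = "simulated") {
  stopifnot(is(z, "ZScoreProfile"), length(mask) == nResidues(z),
            is(config, "GeneratorConfig"))
  b <- config@bias; d <- config@discrimination
  if (b + d / 2 > 1 + 2 * config@noiseSd || b - d / 2 < -2 * config@noiseSd)
    warning("b +/- d/2 outside [0, 1]: clamping will bias recovery")
  p <- .withSeed(config@seed + 1L, {
    level <- ifelse(mask, b + d / 2, b - d / 2)
    pmin(1, pmax(0, level + stats::rnorm(length(mask), 0, config@noiseSd)))
  })
  DisorderPrediction(methodName,
                     data.frame(resno = residueNumbers(z), p = p))
}

#' Simulate a predictor with a logistic response in Z
#'
#' Convenience variant producing smoother, more realistic ROC shapes:
#' `p = plogis(-(Z - center)/scale)` plus clamped Gaussian noise. Its
#' bias/discrimination are not analytically planted; use
#' [genPredictions()] for recovery tests.
#'
#' @param z a [ZScoreProfile-class].
#' @param config a [GeneratorConfig-class] (uses `noiseSd`, `seed`).
#' @param center,scale logistic midpoint and width on the Z scale.
#' @param methodName name stored on the prediction.
#' @return a [DisorderPrediction-class].
#' @export
genLogisticPredictions <- function(z, config = generatorConfig(),
                                   center = 8, scale = 2,
                                   methodName = "simulated-logistic") {
  stopifnot(is(z, "ZScoreProfile"), is(config, "GeneratorConfig"))
  p <- .withSeed(config@seed + 2L, {
    raw <- stats::plogis(-(zScores(z) - center) / scale)
    pmin(1, pmax(0, raw + stats::rnorm(nResidues(z), 0, config@noiseSd)))
  })
  DisorderPrediction(methodName,
                     data.frame(resno = residueNumbers(z), p = p))
}

#' Simulate a backbone ensemble with planted disorder
#'
#' Builds an idealised poly-alanine backbone (standard peptide bond
#' lengths and angles, extended base conformation phi = -120, psi = 120
#' degrees) and produces N conformers by perturbing every phi/psi with
#' independent Gaussian noise whose per-residue standard deviation is
#' `coreAmplitude` (degrees) on planted-ordered residues and
#' `tailAmplitude` on planted-disordered ones. With both amplitudes zero
#' the ensemble is rigid and the order parameters are exactly 1 wherever
#' defined.
#'
#' @param config a [GeneratorConfig-class].
#' @param entryId identifier of the simulated entry.
#' @param basePhi,basePsi base conformation in degrees.
#' @return list with `ensemble` (an [EnsembleStructure-class]) and
#'   `mask` (planted disorder mask).
#' @export
genEnsemble <- function(config = generatorConfig(), entryId = "sim",
                        basePhi = -120, basePsi = 120) {
  stopifnot(is(config, "GeneratorConfig"), config@nConformers >= 2L)
  mask <- .plantedMask(config)
  L <- config@L; N <- config@nConformers
  amp <- ifelse(mask, config@tailAmplitude, config@coreAmplitude)
  coords <- .withSeed(config@seed + 3L, {
    out <- array(NA_real_, dim = c(L, 3L, 3L, N))
    for (k in seq_len(N)) {
      phi <- basePhi + stats::rnorm(L, 0, amp)
      psi <- basePsi + stats::rnorm(L, 0, amp)
      ## wrap into (-180, 180]
      phi <- phi - 360 * ceiling((phi - 180) / 360)
      psi <- psi - 360 * ceiling((psi - 180) / 360)
      out[, , , k] <- .buildBackbone(phi, psi)
    }
    out
  })
  res <- data.frame(chain = "A", resno = seq_len(L), resname = "ALA",
                    stringsAsFactors = FALSE)
  list(ensemble = EnsembleStructure(entryId, res, coords), mask = mask)
}

#' Simulate X-ray observed/missing labels
#'
#' Flags planted-disordered residues as missing density with probability
#' `missingRate`; ordered residues are never missing. Low rates combined
#' with a low disordered fraction reproduce the pronounced class
#' imbalance of crystallographic disorder labels.
#'
#' @param z a [ZScoreProfile-class] (fixes the residue numbering).
#' @param mask logical planted-disorder mask parallel to `z`.
#' @param missingRate probability a disordered residue is missing.
#' @param seed integer seed.
#' @return a [MissingResidueLabels-class].
#' @export
genXrayLabels <- function(z, mask, missingRate, seed = 1L) {
  stopifnot(is(z, "ZScoreProfile"), length(mask) == nResidues(z),
            missingRate >= 0, missingRate <= 1)
  miss <- .withSeed(as.integer(seed) + 4L,
                    mask & stats::runif(length(mask)) < missingRate)
  MissingResidueLabels(entryId(z),
    data.frame(resno = residueNumbers(z),
               status = ifelse(miss, "missing", "observed"),
               stringsAsFactors = FALSE))
}
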