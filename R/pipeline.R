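## End-to-end orchestration: assemble a cohort (simulated or from files),
## benchmark every method over the pooled residues, rank, classify bias,
## optionally optimize the Z threshold, and write the report.

#' Run configuration for the benchmarking pipeline
#'
#' @slot mode `"simulate"` or `"files"`.
#' @slot generator a [GeneratorConfig-class] (simulate mode).
#' @slot nProteins cohort size (simulate mode).
#' @slot methods data.frame with `name`, `bias`, `discrimination` and
#'   optionally `noiseSd` (simulate mode), one row per planted method.
#' @slot zDir,predDir directories of Z-score tables and per-method
#'   prediction subdirectories (files mode).
#' @slot zThreshold Z-score disorder criterion.
#' @slot pCutoffs scalar or named per-method probability cutoffs.
#' @slot optimizeGrid candidate thresholds for [optimalZThreshold()]
#'   (empty = skip optimization).
#' @slot outDir output directory (empty = no files written).
#' @export
setClass("RunConfig",
  representation(mode = "character", generator = "GeneratorConfig",
                 nProteins = "integer", methods = "data.frame",
                 zDir = "character", predDir = "character",
                 zThreshold = "numeric", pCutoffs = "numeric",
                 optimizeGrid = "numeric", outDir = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!object@mode %in% c("simulate", "files"))
    msg <- c(msg, "mode must be 'simulate' or 'files'")
  if (object@mode == "simulate") {
    if (object@nProteins < 1L) msg <- c(msg, "nProteins must be >= 1")
    if (!nrow(object@methods) ||
        !all(c("name", "bias", "discrimination") %in% names(object@methods)))
      msg <- c(msg, "methods needs name/bias/discrimination columns")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RunConfig constructor. Defaults mirror the analysis
#'   constants: Z threshold 8, probability cutoff 0.5.
#' @param mode,generator,nProteins,methods,zDir,predDir see slots.
#' @param zThreshold,pCutoffs,optimizeGrid,outDir see slots.
#' @export
runConfig <- function(mode = c("simulate", "files"),
                      generator = generatorConfig(), nProteins = 5L,
                      methods = data.frame(name = "simulated", bias = 0.5,
                                           discrimination = 0.8),
                      zDir = character(), predDir = character(),
                      zThreshold = 8.0, pCutoffs = 0.5,
                      optimizeGrid = numeric(), outDir = character()) {
  new("RunConfig", mode = match.arg(mode), generator = generator,
      nProteins = as.integer(nProteins), methods = methods, zDir = zDir,
      predDir = predDir, zThreshold = zThreshold, pCutoffs = pCutoffs,
      optimizeGrid = optimizeGrid, outDir = outDir)
}

## Per-protein generator configs derive distinct sub-seeds from the master
## seed; kept small so every derived seed stays a valid 32-bit integer.
.proteinConfig <- function(gen, i) {
  g <- gen
  g@seed <- gen@seed + 1009L * i
  g
}

#' Simulate a benchmarking cohort
#'
#' Generates `nProteins` Z-score profiles under the generator
#' configuration and, for every row of `methods`, planted predictions on
#' each protein. All randomness derives from the generator seed.
#'
#' @param config a [RunConfig-class] in simulate mode.
#' @return list with `zscores` (list of [ZScoreProfile-class]), `masks`
#'   (list of logical vectors) and `predictions` (list per method of
#'   lists per protein).
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "RunConfig"), config@mode == "simulate")
  zs <- vector("list", config@nProteins)
  masks <- vector("list", config@nProteins)
  for (i in seq_len(config@nProteins)) {
    g <- .proteinConfig(config@generator, i)
    sim <- genZScores(g, entryId = sprintf("sim%03d", i))
    zs[[i]] <- sim$profile; masks[[i]] <- sim$mask
  }
  preds <- lapply(seq_len(nrow(config@methods)), function(j) {
    m <- config@methods[j, ]
    lapply(seq_len(config@nProteins), function(i) {
      g <- .proteinConfig(config@generator, i)
      g@seed <- g@seed + 31L * j
      g@bias <- m$bias
      g@discrimination <- m$discrimination
      if ("noiseSd" %in% names(m)) g@noiseSd <- m$noiseSd
      genPredictions(zs[[i]], masks[[i]], g, methodName = m$name)
    })
  })
  names(preds) <- config@methods$name
  list(zscores = zs, masks = masks, predictions = preds)
}

.loadCohort <- function(config) {
  zFiles <- list.files(config@zDir, full.names = TRUE)
  if (!length(zFiles)) stop("no Z-score files in '", config@zDir, "'")
  zs <- lapply(zFiles, readZScores)
  ids <- vapply(zs, entryId, "")
  methodDirs <- list.dirs(config@predDir, recursive = FALSE)
  if (!length(methodDirs)) stop("no method directories in '", config@predDir, "'")
  preds <- lapply(methodDirs, function(d) {
    lapply(ids, function(id) {
      f <- file.path(d, paste0(id, ".txt"))
      if (file.exists(f)) readPredictions(f, basename(d)) else NULL
    })
  })
  names(preds) <- basename(methodDirs)
  list(zscores = zs, masks = NULL, predictions = preds)
}

#' Run the full benchmarking pipeline
#'
#' Assembles the cohort (simulated or read from files), pairs every
#' method's predictions with the Z-scores, pools residues across
#' proteins, computes the full benchmark row per method, ranks methods by
#' |R_P|, classifies their bias, and optionally scans a Z-threshold grid.
#' Methods with zero matched residues are excluded with a warning rather
#' than failing the run. With `outDir` set, the TSV + JSON report is
#' written; the run is deterministic given the configuration, so a rerun
#' produces byte-identical reports.
#'
#' @param config a [RunConfig-class].
#' @return list with `results` (ranked [BenchmarkResult-class] list),
#'   `table` (data.frame summary in ranked order), `biasCategories`
#'   (named character), `pooled` (named list of pooled
#'   [PairedScores-class]), `threshold` (result of [optimalZThreshold()]
#'   or `NULL`) and `reportPaths`.
#' @examples
#' cfg <- runConfig(nProteins = 2,
#'                  generator = generatorConfig(seed = 5, L = 60),
#'                  methods = data.frame(name = c("good", "weak"),
#'                                       bias = 0.5,
#'                                       discrimination = c(0.8, 0.2)))
#' res <- runBenchmark(cfg)
#' res$table[, c("method", "R_P", "AUC", "pZA", "pZD")]
#' @export
runBenchmark <- function(config) {
  stopifnot(is(config, "RunConfig"))
  cohort <- if (config@mode == "simulate") simulateCohort(config)
            else .loadCohort(config)
  cutoffFor <- function(nm) {
    pc <- config@pCutoffs
    if (length(pc) == 1L && is.null(names(pc))) return(unname(pc))
    if (nm %in% names(pc)) unname(pc[[nm]]) else 0.5
  }
  pooled <- list()
  for (nm in names(cohort$predictions)) {
    perProt <- list()
    for (i in seq_along(cohort$zscores)) {
      pr <- cohort$predictions[[nm]][[i]]
      if (is.null(pr)) next
      ps <- tryCatch(pairScores(cohort$zscores[[i]], pr),
                     error = function(e) NULL)
      if (!is.null(ps)) perProt[[length(perProt) + 1L]] <- ps
    }
    if (!length(perProt)) {
      warning("method '", nm, "' has no matched residues; excluded")
      next
    }
    pooled[[nm]] <- poolScores(perProt)
  }
  if (!length(pooled)) stop("no method has any matched residues")
  results <- lapply(names(pooled), function(nm)
    benchmarkMethod(pooled[[nm]], zThreshold = config@zThreshold,
                    pCutoff = cutoffFor(nm)))
  results <- rankMethods(results)
  biasCat <- vapply(results, function(r)
    if (is.na(r@bias@pZA)) NA_character_ else classifyBias(r@bias), "")
  names(biasCat) <- vapply(results, methodName, "")
  thr <- NULL
  if (length(config@optimizeGrid))
    thr <- optimalZThreshold(pooled, grid = config@optimizeGrid,
                             pCutoffs = config@pCutoffs)
  paths <- NULL
  if (length(config@outDir)) {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- writeBenchmarkReport(results,
                                  file.path(config@outDir, "benchmark.tsv"))
  }
  list(results = results, table = benchmarkTable(results),
       biasCategories = biasCat, pooled = pooled, threshold = thr,
       reportPaths = paths)
}

#' Order-parameter analysis of an ensemble cohort
#'
#' Computes the per-residue S/T order-parameter profile of every
#' ensemble, ranks the proteins by their fraction of residues with
#' Z-scores below `zSelect` (most disordered first, ties broken by entry
#' name), optionally keeps the top `topK`, and measures how much the
#' structural classifications tell about the Z-scores: the
#' Jensen-Shannon divergence between Z distributions of residues with S
#' above/below 0.5 (equivalently s below/above the angular reference)
#' and likewise for T.
#'
#' @param ensembles list of [EnsembleStructure-class].
#' @param zscores list of matching [ZScoreProfile-class] (same order;
#'   matched on entry id when named). Proteins lacking either input are
#'   skipped with a warning.
#' @param config an [OrderConfig-class].
#' @param zSelect Z threshold of the selection rule (default 5).
#' @param topK number of proteins kept after ranking (default: all).
#' @param edges Z histogram edges for the JSD.
#' @return list with `profiles` (per selected protein), `selection`
#'   (data.frame `entry`, `fractionBelow`, ranked), `jsdS`, `jsdT`
#'   (scalars) and `paired` (data.frame `z`, `S`, `T` pooled over the
#'   selection).
#' @export
runOrderAnalysis <- function(ensembles, zscores, config = orderConfig(),
                             zSelect = 5.0, topK = NULL,
                             edges = seq(-5, 20, by = 1)) {
  stopifnot(length(ensembles) >= 1L, length(zscores) >= 1L)
  zIds <- vapply(zscores, entryId, "")
  keep <- list()
  for (ens in ensembles) {
    i <- match(entryId(ens), zIds)
    if (is.na(i)) {
      warning("no Z-score profile for '", entryId(ens), "'; skipped")
      next
    }
    keep[[length(keep) + 1L]] <- list(ens = ens, z = zscores[[i]])
  }
  if (!length(keep)) stop("no protein has both an ensemble and Z-scores")
  frac <- vapply(keep, function(k) mean(zScores(k$z) < zSelect), 0)
  nm <- vapply(keep, function(k) entryId(k$ens), "")
  ord <- order(-frac, nm)
  keep <- keep[ord]
  selection <- data.frame(entry = nm[ord], fractionBelow = frac[ord],
                          stringsAsFactors = FALSE)
  if (!is.null(topK)) {
    topK <- min(topK, length(keep))
    keep <- keep[seq_len(topK)]
    selection <- selection[seq_len(topK), ]
  }
  profiles <- lapply(keep, function(k)
    ensembleOrderProfile(k$ens, config = config))
  paired <- do.call(rbind, lapply(seq_along(keep), function(i) {
    pr <- profiles[[i]]@profile
    zr <- keep[[i]]$z@residues
    j <- match(pr$resno, zr$resno)
    ok <- !is.na(j)
    data.frame(z = zr$z[j[ok]], S = pr$S[ok], T = pr$T[ok])
  }))
  okS <- !is.na(paired$S); okT <- !is.na(paired$T)
  safeJsd <- function(z, lab, what) {
    tryCatch(jsdByClassification(z, lab, edges = edges),
             error = function(e) {
               warning("JSD of the ", what,
                       " split undefined: ", conditionMessage(e))
               NA_real_
             })
  }
  jsdS <- safeJsd(paired$z[okS], paired$S[okS] >= 0.5, "S")
  jsdT <- safeJsd(paired$z[okT], paired$T[okT] >= 0.5, "T")
  list(profiles = profiles, selection = selection, jsdS = jsdS,
       jsdT = jsdT, paired = paired)
}
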