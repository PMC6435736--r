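pairedFrom <- function(z, p, method = "m", binary = FALSE) {
  new("PairedScores", entryId = "t", methodName = method, z = z, p = p,
      isBinary = binary)
}

test_that("profiles pair on residue number with order preserved", {
  zp <- ZScoreProfile("e", data.frame(resno = 1:30, aa = "A",
                                      z = seq(0, 14.5, by = 0.5)))
  pr <- DisorderPrediction("m", data.frame(resno = 10:20,
                                           p = seq(0, 1, length.out = 11)))
  ps <- pairScores(zp, pr)
  expect_identical(length(zScores(ps)), 11L)
  expect_equal(zScores(ps), zp@residues$z[10:20])

  full <- DisorderPrediction("m", data.frame(resno = 1:30, p = 0.5))
  expect_identical(length(zScores(pairScores(zp, full))), 30L)

  disjoint <- DisorderPrediction("m", data.frame(resno = 31:40, p = 0.5))
  expect_error(pairScores(zp, disjoint), "no residues in common")
})

test_that("Pearson correlation matches the textbook formula", {
  # exact linear dependence p = 1 - Z/16 gives R_P = -1
  z <- c(1, 3.5, 8, 12, 15.2)
  ps <- pairedFrom(z, 1 - z / 16)
  expect_equal(pearsonR(ps), -1, tolerance = 1e-12)

  # hand-listed pairs against the brute-force formula
  z5 <- c(2.2, 7.9, 8.1, 11.0, 14.3)
  p5 <- c(0.9, 0.7, 0.35, 0.2, 0.12)
  expect_equal(pearsonR(pairedFrom(z5, p5)), brutePearson(p5, z5),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:10) {
    z <- rnorm(50); p <- runif(50)
    expect_equal(pearsonR(pairedFrom(z, p)), brutePearson(p, z),
                 tolerance = 1e-12)
  }

  # permuted (independent) predictions: correlation concentrates near 0
  set.seed(7)
  rps <- vapply(1:10, function(i) {
    z <- c(rnorm(500, 3, 2), rnorm(500, 12, 2))
    p <- sample(stats::plogis(-(z - 8) / 2))
    pearsonR(pairedFrom(z, p))
  }, 0)
  expect_lt(mean(abs(rps)), 0.1)

  expect_warning(rp <- pearsonR(pairedFrom(c(1, 2, 3), c(0.5, 0.5, 0.5))),
                 "constant")
  expect_true(is.na(rp))
})

test_that("Spearman correlation ranks with average ties", {
  # strictly monotone nonlinear: R_S = -1 while R_P > -1
  z <- c(0.5, 2, 4, 7, 9, 12, 15)
  ps <- pairedFrom(z, exp(-z))
  expect_equal(spearmanR(ps), -1, tolerance = 1e-12)
  expect_gt(pearsonR(ps), -1)

  # one tie, against hand-assigned average ranks
  z6 <- c(1, 2, 3, 4, 5, 6)
  p6 <- c(0.9, 0.8, 0.5, 0.5, 0.2, 0.1)
  expect_equal(spearmanR(pairedFrom(z6, p6)),
               brutePearson(c(6, 5, 3.5, 3.5, 2, 1), 1:6),
               tolerance = 1e-12)
  expect_equal(spearmanR(pairedFrom(z6, p6)),
               cor(p6, z6, method = "spearman"), tolerance = 1e-12)

  expect_warning(rs <- spearmanR(pairedFrom(z6, rep(0.4, 6))), "tied")
  expect_true(is.na(rs))
  # binary methods: n.a. by policy
  expect_true(is.na(spearmanR(pairedFrom(z6, c(1, 1, 0, 0, 0, 1),
                                         binary = TRUE))))
})

test_that("Z binarization is strict at the threshold", {
  expect_true(binarizeZ(7.999))
  expect_false(binarizeZ(8.0))
  expect_identical(sum(binarizeZ(rep(12, 5))), 0L)
  set.seed(9)
  z <- runif(200, 0, 16)
  expect_identical(sum(binarizeZ(z)), sum(vapply(z, function(x) x < 8, NA)))
})

test_that("trapezoidal AUC equals the exhaustive pairwise statistic", {
  # degenerate anchors
  z <- c(1, 2, 3, 11, 12, 13)
  expect_equal(rocAuc(pairedFrom(z, c(0.9, 0.8, 0.7, 0.2, 0.1, 0.0)))$auc, 1.0)
  expect_equal(rocAuc(pairedFrom(z, rep(0.4, 6)))$auc, 0.5)

  # 12-point toy set with heavy ties
  p12 <- c(0.8, 0.8, 0.6, 0.6, 0.6, 0.4, 0.8, 0.4, 0.4, 0.2, 0.2, 0.6)
  z12 <- c(2, 3, 4, 5, 6, 7, 9, 10, 11, 12, 13, 14)
  expect_equal(rocAuc(pairedFrom(z12, p12))$auc, bruteAUC(z12, p12),
               tolerance = 1e-12)

  # property: random instances with heavy ties, exact agreement
  set.seed(10)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    z <- runif(n, 0, 16)
    p <- round(runif(n), sample(c(0, 1, 2), 1))  # heavy ties at 0/1 decimals
    got <- rocAuc(pairedFrom(z, p))$auc
    if (is.na(got)) next
    expect_equal(got, bruteAUC(z, p), tolerance = 1e-12)
  }

  # independent library cross-check on one instance
  set.seed(12)
  z <- runif(150, 0, 16); p <- round(runif(150), 1)
  expect_equal(rocAuc(pairedFrom(z, p))$auc,
               as.numeric(pROC::auc(pROC::roc(z < 8, p, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)

  # single class: undefined with a warning
  expect_warning(a <- rocAuc(pairedFrom(c(10, 11, 12), c(0.1, 0.2, 0.3)))$auc)
  expect_true(is.na(a))
  # ROC curve starts at (0,0) and ends at (1,1)
  roc <- rocAuc(pairedFrom(z, p))$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("confusion statistics follow the MCC conventions", {
  # perfect predictions
  z <- c(1, 2, 3, 11, 12, 13)
  cf <- confusionStats(pairedFrom(z, c(1, 1, 1, 0, 0, 0)))
  expect_equal(cf$mcc, 1)
  expect_equal(cf$fpr, 0); expect_equal(cf$fnr, 0)

  # all-positive predictions on a mixed set: zero marginal, MCC = 0
  cf <- confusionStats(pairedFrom(z, rep(1, 6)))
  expect_equal(cf$mcc, 0)
  expect_equal(cf$fpr, 1)

  # hand-built counts TP=3 FP=1 FN=2 TN=4
  z <- c(rep(4, 3), rep(4, 2), rep(12, 1), rep(12, 4))
  p <- c(rep(1, 3), rep(0, 2), rep(1, 1), rep(0, 4))
  cf <- confusionStats(pairedFrom(z, p))
  expect_identical(c(cf$tp, cf$fp, cf$tn, cf$fn), c(3L, 1L, 4L, 2L))
  expect_equal(cf$mcc, bruteMCC(3, 1, 4, 2), tolerance = 1e-12)
  expect_equal(cf$mcc, (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6),
               tolerance = 1e-12)

  # MCC invariant under simultaneous label/prediction swap
  set.seed(14)
  z <- runif(100, 0, 16); p <- runif(100)
  mcc1 <- confusionStats(pairedFrom(z, p))$mcc
  mcc2 <- confusionStats(pairedFrom(16 - z, 1 - p),
                         zThreshold = 8, pCutoff = 0.5)$mcc
  expect_equal(mcc1, mcc2, tolerance = 1e-9)
})

test_that("monotone transforms preserve rank metrics but not Pearson", {
  set.seed(15)
  z <- c(rnorm(80, 3, 2), rnorm(80, 12, 2))
  p <- stats::plogis(-(z - 8) / 3) + rnorm(160, 0, 0.02)
  p <- pmin(1, pmax(0, p))
  f <- function(x) x^3                     # strictly increasing on [0,1]
  a <- pairedFrom(z, p); b <- pairedFrom(z, f(p))
  expect_equal(spearmanR(a), spearmanR(b), tolerance = 1e-12)
  expect_equal(rocAuc(a)$auc, rocAuc(b)$auc, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pearsonR(a), pearsonR(b), tolerance = 1e-6)))
})

test_that("bias metrics satisfy their defining identities", {
  # ideal step predictor
  z <- c(2, 4, 6, 10, 12, 14)
  bm <- biasMetrics(pairedFrom(z, c(1, 1, 1, 0, 0, 0)))
  expect_equal(bm@pZL, 1); expect_equal(bm@pZH, 0)
  expect_equal(bm@pZA, 0.5); expect_equal(bm@pZD, 1)

  # constant predictor: pZA = c, pZD = 0
  bm <- biasMetrics(pairedFrom(z, rep(0.37, 6)))
  expect_equal(bm@pZA, 0.37); expect_equal(bm@pZD, 0)

  # Z exactly at the threshold enters neither mean
  bm <- biasMetrics(pairedFrom(c(2, 8, 14), c(0.9, 0.123, 0.1)))
  expect_identical(bm@nL + bm@nH, 2L)
  expect_equal(bm@pZL, 0.9); expect_equal(bm@pZH, 0.1)

  # identities hold exactly on random instances
  set.seed(16)
  for (i in 1:20) {
    z <- runif(60, 0, 16); p <- runif(60)
    bm <- biasMetrics(pairedFrom(z, p))
    expect_equal(bm@pZA, (bm@pZL + bm@pZH) / 2, tolerance = 1e-12)
    expect_equal(bm@pZD, bm@pZL - bm@pZH, tolerance = 1e-12)
  }

  expect_warning(bm <- biasMetrics(pairedFrom(c(10, 12), c(0.1, 0.2))))
  expect_true(is.na(bm@pZA))
})

test_that("the step predictor is simultaneously perfect on all axes", {
  z <- c(runif(40, 0, 7.5), runif(40, 8.5, 16))
  p <- as.numeric(z < 8)
  ps <- pairedFrom(z, p)          # treated as continuous here
  expect_equal(rocAuc(ps)$auc, 1)
  expect_equal(confusionStats(ps)$mcc, 1)
  expect_equal(biasMetrics(ps)@pZD, 1)
})

test_that("bias classification applies the pZA rules", {
  expect_identical(classifyBias(0.12), "under-predicts-disorder")
  expect_identical(classifyBias(0.5), "unbiased-range")
  expect_identical(classifyBias(0.71), "over-predicts-disorder")
  expect_identical(classifyBias(0.3), "unbiased-range")
  bm <- biasMetrics(pairedFrom(c(2, 12), c(0.1, 0.1)))
  expect_identical(classifyBias(bm), "under-predicts-disorder")
})

test_that("threshold optimization respects its tie-breaking contract", {
  # singleton grid
  sim <- genZScores(generatorConfig(seed = 18, L = 500,
                                    fractionDisordered = 0.5))
  pred <- genPredictions(sim$profile, sim$mask,
                         generatorConfig(seed = 18, L = 500))
  ps <- pairScores(sim$profile, pred)
  expect_equal(optimalZThreshold(list(ps), grid = 8.0)$best, 8.0)

  # perfect method: every threshold between the Z clusters is optimal;
  # the tie-break returns the grid point nearest 8
  z <- c(runif(30, 0, 4), runif(30, 12, 16))
  perfect <- pairedFrom(z, as.numeric(z < 8))
  opt <- optimalZThreshold(list(perfect), grid = seq(0, 16, by = 0.5))
  expect_equal(opt$best, 8.0)
  expect_identical(nrow(opt$table), 33L)
  # ties away from 8 break toward the smaller threshold
  opt2 <- optimalZThreshold(list(perfect), grid = c(5, 6, 10, 11))
  expect_equal(opt2$best, 6)
})

test_that("methods rank by |R_P| with AUC and name tie-breaks", {
  mk <- function(nm, rp, auc) {
    rp <- as.numeric(rp); auc <- as.numeric(auc)
    bm <- new("BiasMetrics", pZL = 0.5, pZH = 0.5, pZA = 0.5, pZD = 0,
              nL = 1L, nH = 1L)
    new("BenchmarkResult", methodName = nm, n = 10L, rp = rp,
        rs = NA_real_, auc = auc, tp = 1L, fp = 1L, tn = 1L, fn = 1L,
        mcc = 0, fpr = 0.5, fnr = 0.5, tpr = 0.5, bias = bm,
        isBinary = FALSE)
  }
  r <- list(mk("c", 0.1, 0.5), mk("a", -0.7, 0.9), mk("b", -0.3, 0.6))
  expect_identical(vapply(rankMethods(r), methodName, ""), c("a", "b", "c"))
  # equal |R_P|: higher AUC first
  r <- list(mk("x", -0.5, 0.8), mk("y", 0.5, 0.9))
  expect_identical(vapply(rankMethods(r), methodName, ""), c("y", "x"))
  # undefined R_P sorts last; output independent of input order
  r <- list(mk("na", NA, 0.9), mk("ok", -0.2, 0.5))
  expect_identical(vapply(rankMethods(r), methodName, ""), c("ok", "na"))
  shuf <- list(mk("m1", -0.6, 0.8), mk("m2", -0.6, 0.7), mk("m3", 0.9, 0.5))
  expect_identical(vapply(rankMethods(shuf), methodName, ""),
                   vapply(rankMethods(rev(shuf)), methodName, ""))
})
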