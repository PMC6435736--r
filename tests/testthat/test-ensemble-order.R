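rigidEnsemble <- function(L = 12, N = 4, seed = 1) {
  genEnsemble(generatorConfig(seed = seed, L = L, nConformers = N,
                              coreAmplitude = 0, tailAmplitude = 0,
                              fractionDisordered = 0))$ensemble
}

test_that("shw matches its defining circular statistic", {
  expect_equal(shw(rep(42, 7)), 1)
  expect_equal(shw(c(0, 90, 180, 270)), 0, tolerance = 1e-12)
  expect_equal(shw(c(0, 90)), sqrt(2) / 2)
  expect_error(shw(numeric()), "at least one")

  set.seed(4)
  for (i in 1:25) {
    a <- runif(sample(1:12, 1), -180, 180)
    expect_equal(shw(a), bruteShw(a), tolerance = 1e-12)
    expect_gte(shw(a), 0); expect_lte(shw(a), 1 + 1e-12)
    # rotation of the circle leaves the concentration unchanged
    expect_equal(shw(a), shw(a + runif(1, -720, 720)), tolerance = 1e-9)
  }
  # equals 1 iff all angles equal modulo 360
  expect_equal(shw(c(10, 370, -350)), 1, tolerance = 1e-9)
  expect_lt(shw(c(10, 11)), 1)
})

test_that("computed dihedrals reproduce the angles a chain was built from", {
  set.seed(11)
  L <- 8
  for (rep in 1:3) {
    phi <- c(180, runif(L - 1, -179, 179))
    psi <- c(runif(L - 1, -179, 179), 180)
    bb <- DisorderBench:::.buildBackbone(phi, psi)
    coords <- array(bb, dim = c(L, 3, 3, 1))
    coords <- array(rep(coords, 2), dim = c(L, 3, 3, 2))  # 2 identical
    ens <- EnsembleStructure("built",
      data.frame(chain = "A", resno = 1:L, resname = "ALA"), coords)
    dih <- computeDihedrals(ens)
    expect_equal(dih@phi[2:L, 1], phi[2:L], tolerance = 1e-6)
    expect_equal(dih@psi[1:(L - 1), 1], psi[1:(L - 1)], tolerance = 1e-6)
    # identical conformers give identical dihedral sets
    expect_identical(dih@phi[, 1], dih@phi[, 2])
    # termini are undefined
    expect_true(all(is.na(dih@phi[1, ])))
    expect_true(all(is.na(dih@psi[L, ])))
  }

  # extended chain built at phi = psi = 180 recomputes to 180 everywhere
  bb <- DisorderBench:::.buildBackbone(rep(180, 4), rep(180, 4))
  ens <- EnsembleStructure("ext",
    data.frame(chain = "A", resno = 1:4, resname = "ALA"),
    array(bb, dim = c(4, 3, 3, 1)))
  dih <- computeDihedrals(ens)
  expect_equal(abs(dih@phi[2:4, 1]), rep(180, 3), tolerance = 1e-6)
  expect_equal(abs(dih@psi[1:3, 1]), rep(180, 3), tolerance = 1e-6)
})

test_that("dihedrals agree with the bio3d torsion oracle", {
  set.seed(21)
  L <- 6
  phi <- c(180, runif(L - 1, -170, 170))
  psi <- c(runif(L - 1, -170, 170), 180)
  bb <- DisorderBench:::.buildBackbone(phi, psi)
  # flatten residue-major, atom-major: N1 CA1 C1 N2 ...
  flat <- c(t(matrix(aperm(bb, c(2, 1, 3)), ncol = 3)))
  tor <- bio3d::torsion.xyz(flat, atm.inc = 1)
  # consecutive windows: psi(i) at 1 + 3*(i-1), phi(i+1) at 3*i
  ens <- EnsembleStructure("b3d",
    data.frame(chain = "A", resno = 1:L, resname = "ALA"),
    array(bb, dim = c(L, 3, 3, 1)))
  dih <- computeDihedrals(ens)
  # torsion.xyz emits a leading NA, then the consecutive 4-atom windows:
  # psi(i), omega(i), phi(i+1), ...
  for (i in 1:(L - 1)) {
    expect_equal(dih@psi[i, 1], tor[2 + 3 * (i - 1)], tolerance = 1e-6)
    expect_equal(dih@phi[i + 1, 1], tor[1 + 3 * i], tolerance = 1e-6)
  }
})

test_that("chain breaks make the spanning dihedrals undefined", {
  ens <- rigidEnsemble(L = 10, N = 3)
  co <- ens@coords
  co[7:10, , 1, ] <- co[7:10, , 1, ] + 30   # translate tail along x
  broken <- EnsembleStructure("brk", ens@residues, co)
  dih <- computeDihedrals(broken)
  expect_true(all(is.na(dih@psi[6, ])))
  expect_true(all(is.na(dih@phi[7, ])))
  expect_false(anyNA(dih@phi[2:6, ]))
})

test_that("D averages the six flanking circular order parameters", {
  # rigid ensemble: every defined angle has S_HW = 1, interior D = 1
  D <- dihedralOrderProfile(computeDihedrals(rigidEnsemble()))
  expect_equal(D[3:10], rep(1, 8), tolerance = 1e-12)

  # hand-built 5-residue, 3-conformer dihedral set with known S_HW values
  set.seed(8)
  phi <- matrix(runif(15, -180, 180), 5, 3)
  psi <- matrix(runif(15, -180, 180), 5, 3)
  phi[1, ] <- NA; psi[5, ] <- NA
  dset <- new("DihedralSet", resno = 1:5, phi = phi, psi = psi)
  D <- dihedralOrderProfile(dset)
  sphi <- c(NA, vapply(2:5, function(i) bruteShw(phi[i, ]), 0))
  spsi <- c(vapply(1:4, function(i) bruteShw(psi[i, ]), 0), NA)
  # interior residue 3: all six terms defined, divisor 6
  expect_equal(D[3], sum(sphi[2:4], spsi[2:4]) / 6, tolerance = 1e-12)
  # terminus residue 1: defined terms only, divisor = their count
  expect_equal(D[1], mean(c(sphi[2], spsi[1], spsi[2])), tolerance = 1e-12)
  expect_true(all(D >= 0 & D <= 1, na.rm = TRUE))
})

test_that("angleStd inverts the concentration into degrees", {
  expect_equal(angleStd(1), 0)
  expect_equal(angleStd(exp(-4)), 360, tolerance = 1e-9)
  # numerically invert at s = 75 degrees: ln D = 2 (cos(s/2) - 1)
  D75 <- exp(2 * (cos(75 / 2 * pi / 180) - 1))
  expect_equal(angleStd(D75), 75, tolerance = 1e-9)
  expect_error(angleStd(0), "positive")
  expect_error(angleStd(-0.5), "positive")
  # continuous, strictly monotone on [e^-4, 1], onto [0, 360]
  grid <- seq(exp(-4), 1, length.out = 400)
  s <- angleStd(grid)
  expect_true(all(diff(s) < 0))
  expect_equal(range(s), c(0, 360), tolerance = 1e-6)
  # below e^-4 the arccos argument is clamped and s saturates
  expect_equal(angleStd(1e-4), 360)
})

test_that("the variance matrix matches hand evaluation and is rigid-invariant", {
  ens <- rigidEnsemble(L = 8, N = 5)
  ivm <- buildIVM(ens)
  expect_lt(max(ivm@v), 1e-20)

  # 2 conformers, one CA pair at d and d + delta: v = delta^2 / 4
  delta <- 0.8
  co <- ens@coords[, , , 1:2]
  dir18 <- DisorderBench:::.unit(co[8, 2, , 2] - co[1, 2, , 2])
  co[8, 2, , 2] <- co[8, 2, , 2] + delta * dir18
  two <- EnsembleStructure("two", ens@residues, co)
  v <- buildIVM(two)@v
  expect_equal(v[1, 8], delta^2 / 4, tolerance = 1e-9)
  expect_equal(v, t(v), tolerance = 1e-12)

  # per-conformer rigid motion leaves the matrix unchanged
  wob <- genEnsemble(generatorConfig(seed = 5, L = 15, nConformers = 6))$ensemble
  set.seed(99)
  moved <- rigidlyPerturb(wob)
  expect_equal(buildIVM(moved)@v, buildIVM(wob)@v, tolerance = 1e-9)

  one <- EnsembleStructure("one", ens@residues,
                           ens@coords[, , , 1, drop = FALSE])
  expect_error(buildIVM(one), "2 conformers")
})

test_that("coordVariation performs the rank-weighted average", {
  ens <- rigidEnsemble(L = 8, N = 3)
  expect_equal(coordVariation(buildIVM(ens)), rep(0, 8))

  # constant retained variances: t = sqrt(c) regardless of beta
  L <- 7; cc <- 0.49
  v <- matrix(cc, L, L); diag(v) <- 0
  for (i in 1:(L - 1)) v[i, i + 1] <- v[i + 1, i] <- cc
  ivm <- new("VarianceMatrix", resno = 1:L, v = v, dbar = matrix(1, L, L))
  expect_equal(coordVariation(ivm, beta = 10), rep(sqrt(cc), L))
  expect_equal(coordVariation(ivm, beta = 0.3), rep(sqrt(cc), L))

  # 6-residue toy matrix against an independent brute-force evaluation
  set.seed(13)
  m <- matrix(runif(36, 0, 4), 6, 6)
  v <- (m + t(m)) / 2; diag(v) <- 0
  ivm <- new("VarianceMatrix", resno = 1:6, v = v, dbar = matrix(1, 6, 6))
  beta <- 10
  got <- coordVariation(ivm, beta = beta)
  for (i in 1:6) {
    lam <- sort(v[i, setdiff(1:6, c(i - 1, i, i + 1))])
    n <- length(lam)
    w <- num <- 0
    for (j in seq_len(n)) {
      wj <- exp(-beta * (j / n)^2)
      w <- w + wj; num <- num + wj * sqrt(lam[j])
    }
    expect_equal(got[i], num / w, tolerance = 1e-12)
  }
})

test_that("orderParams applies the Lorentzian mapping", {
  expect_equal(orderParams(0, 0), list(S = 1, T = 1))
  st <- orderParams(75, 1.5)
  expect_equal(st$S, 0.5); expect_equal(st$T, 0.5)
  expect_equal(orderParams(0, 3.0)$T, 0.2)
  expect_error(orderParams(-1, 0), "non-negative")
  # strictly decreasing in each argument, range (0, 1]
  s <- seq(0, 720, by = 5)
  expect_true(all(diff(orderParams(s, 0)$S) < 0))
  t <- seq(0, 30, by = 0.25)
  expect_true(all(diff(orderParams(0, t)$T) < 0))
  expect_true(all(orderParams(s, t[seq_along(s) %% length(t) + 1])$S > 0))
})

test_that("full profiles distinguish planted order from disorder", {
  prof <- ensembleOrderProfile(rigidEnsemble(L = 14, N = 5))
  tab <- orderTable(prof)
  expect_equal(tab$S[!is.na(tab$S)],
               rep(1, sum(!is.na(tab$S))), tolerance = 1e-9)
  expect_equal(tab$T[!is.na(tab$T)],
               rep(1, sum(!is.na(tab$T))), tolerance = 1e-9)

  sim <- genEnsemble(generatorConfig(seed = 41, L = 40, nConformers = 10))
  tab <- orderTable(ensembleOrderProfile(sim$ensemble))
  expect_lt(mean(tab$S[sim$mask], na.rm = TRUE),
            mean(tab$S[!sim$mask], na.rm = TRUE))
  expect_lt(mean(tab$T[sim$mask], na.rm = TRUE),
            mean(tab$T[!sim$mask], na.rm = TRUE))

  # T is invariant under per-conformer rigid motion
  set.seed(77)
  moved <- rigidlyPerturb(sim$ensemble)
  expect_equal(orderTable(ensembleOrderProfile(moved))$T, tab$T,
               tolerance = 1e-9)
})

test_that("coordinate disorder tracks the planted amplitude profile", {
  # planted per-residue amplitude vs 1 - T: strong rank agreement at
  # >= 5x amplitude contrast
  # balanced mask: with a two-level amplitude the attainable Spearman is
  # bounded by sqrt(3ab/((n-1)(n+1))), which only clears 0.8 for a ~ b
  rhos <- vapply(1:10, function(seed) {
    sim <- genEnsemble(generatorConfig(seed = seed, L = 60,
                                       nConformers = 10,
                                       fractionDisordered = 0.5,
                                       coreAmplitude = 3,
                                       tailAmplitude = 30))
    tab <- orderTable(ensembleOrderProfile(sim$ensemble))
    amp <- ifelse(sim$mask, 30, 3)
    ok <- !is.na(tab$T)
    cor(amp[ok], 1 - tab$T[ok], method = "spearman")
  }, 0)
  expect_gt(mean(rhos), 0.8)
  expect_true(all(rhos > 0))
})
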