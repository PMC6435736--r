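## Internal 3-d geometry kernels: torsion angles from coordinates and the
## inverse (sequential atom placement from internal coordinates), used by
## the dihedral module and the synthetic backbone builder.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v * v))

## IUPAC torsion of the four points p1-p2-p3-p4, degrees in (-180, 180].
.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(.unit(b2), n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

## Place atom D given A-B-C, bond length |C-D|, angle B-C-D (deg) and
## torsion A-B-C-D (deg). Inverse of .torsion (NeRF construction).
.placeAtom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

## Standard peptide internal-coordinate constants (lengths in Angstrom,
## angles in degrees) for the idealised poly-alanine backbone.
.PEPTIDE_GEOMETRY <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
  omega = 180)

## Build an L-residue backbone (N, CA, C per residue) from phi[2..L] and
## psi[1..L-1] in degrees; phi[1] and psi[L] are ignored. Returns an
## [L, 3 atoms, 3 xyz] array.
.buildBackbone <- function(phi, psi, geom = .PEPTIDE_GEOMETRY) {
  L <- length(phi)
  stopifnot(length(psi) == L, L >= 2L)
  out <- array(NA_real_, dim = c(L, 3L, 3L))
  ## first residue in the xy-plane
  out[1, 1, ] <- c(0, 0, 0)
  out[1, 2, ] <- c(geom$b_N_CA, 0, 0)
  ang <- geom$a_N_CA_C * pi / 180
  out[1, 3, ] <- out[1, 2, ] +
    geom$b_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq(2L, L)) {
    out[i, 1, ] <- .placeAtom(out[i - 1, 1, ], out[i - 1, 2, ],
                              out[i - 1, 3, ], geom$b_C_N, geom$a_CA_C_N,
                              psi[i - 1])
    out[i, 2, ] <- .placeAtom(out[i - 1, 2, ], out[i - 1, 3, ], out[i, 1, ],
                              geom$b_N_CA, geom$a_C_N_CA, geom$omega)
    out[i, 3, ] <- .placeAtom(out[i - 1, 3, ], out[i, 1, ], out[i, 2, ],
                              geom$b_CA_C, geom$a_N_CA_C, phi[i])
  }
  out
}

## Uniformly random rotation matrix (via QR of a Gaussian matrix, sign-fixed).
.randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Evaluate thunk with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards so generators behave as pure functions.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}
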