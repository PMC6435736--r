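# Independent brute-force oracles and hand-built fixtures. These stay
# deliberately naive (explicit loops, textbook formulas) so they share no
# code path with the implementation they check.

bruteShw <- function(angles) {
  rad <- angles * pi / 180
  s <- 0; c <- 0
  for (a in rad) { s <- s + sin(a); c <- c + cos(a) }
  sqrt(s^2 + c^2) / length(angles)
}

# Tie-corrected pairwise Mann-Whitney AUC: over every (disordered,
# ordered) pair, count concordant pairs (disordered residue scored
# strictly higher) plus half of the tied ones.
bruteAUC <- function(z, p, threshold = 8) {
  dis <- which(z < threshold); ord <- which(!(z < threshold))
  if (!length(dis) || !length(ord)) return(NA_real_)
  num <- 0
  for (i in dis) for (j in ord) {
    if (p[i] > p[j]) num <- num + 1
    else if (p[i] == p[j]) num <- num + 0.5
  }
  num / (length(dis) * length(ord))
}

brutePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bruteKL <- function(pm, mm) {
  out <- 0
  for (i in seq_along(pm))
    if (pm[i] > 0) out <- out + pm[i] * log(pm[i] / mm[i])
  out
}

bruteMCC <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# Apply an independent random rigid-body motion to each conformer.
rigidlyPerturb <- function(ensemble) {
  co <- ensemble@coords
  for (k in seq_len(dim(co)[4])) {
    rot <- DisorderBench:::.randomRotation()
    shift <- stats::rnorm(3, sd = 20)
    for (ai in 1:3) {
      xyz <- co[, ai, , k]
      nas <- is.na(xyz[, 1])
      xyz[!nas, ] <- sweep(xyz[!nas, , drop = FALSE] %*% t(rot), 2,
                           -shift)
    co[, ai, , k] <- xyz
    }
  }
  EnsembleStructure(entryId(ensemble), ensemble@residues, co)
}

# ---- hand-written PDB fixture builders -----------------------------------

pdbAtomLine <- function(serial, name, resname, chain, resno, xyz,
                        altloc = " ", icode = " ") {
  sprintf("ATOM  %5d  %-3s%1s%3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name, altloc, resname, chain, resno, icode,
          xyz[1], xyz[2], xyz[3])
}

# A compact multi-model PDB text: `models` is a list; each model a list of
# residues, each residue a list(resno, resname, atoms = named list of xyz).
pdbText <- function(models, chain = "A", endmdl = TRUE) {
  out <- character()
  for (m in seq_along(models)) {
    out <- c(out, sprintf("MODEL     %4d", m))
    serial <- 0
    for (r in models[[m]]) {
      for (nm in names(r$atoms)) {
        serial <- serial + 1
        out <- c(out, pdbAtomLine(serial, nm, r$resname, chain, r$resno,
                                  r$atoms[[nm]],
                                  altloc = if (is.null(r$altloc)) " " else r$altloc,
                                  icode = if (is.null(r$icode)) " " else r$icode))
      }
    }
    if (endmdl) out <- c(out, "ENDMDL")
  }
  c(out, "END")
}

# Plausible backbone-ish residue with all three atoms near a base point.
fixtureResidue <- function(resno, base = c(resno * 3.8, 0, 0),
                           resname = "ALA") {
  list(resno = resno, resname = resname,
       atoms = list(N = base + c(-1.2, 0.3, 0), CA = base,
                    C = base + c(1.2, 0.4, 0)))
}

writeTempPdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}
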