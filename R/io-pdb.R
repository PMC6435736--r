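## Fixed-column PDB parsing for multi-model backbone ensembles and for
## SEQRES / REMARK 465 missing-residue labelling. Only the records the
## analysis needs are interpreted (ATOM, MODEL/ENDMDL, SEQRES, REMARK 465);
## hetero-atoms and nucleic acids are ignored.

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.parseAtomRecords <- function(lines) {
  data.frame(
    name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = as.integer(substr(lines, 23, 26)),
    icode = substr(lines, 27, 27),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    stringsAsFactors = FALSE)
}

## Split the file into per-model blocks of ATOM lines. A file without
## MODEL records is a single implicit model.
.splitModels <- function(lines) {
  lines <- sub("[ \t\r]+$", "", lines)
  rec <- substr(lines, 1, 6)
  modelStarts <- which(trimws(rec) == "MODEL")
  atomIdx <- which(rec == "ATOM  ")
  if (!length(modelStarts)) return(list(lines[atomIdx]))
  ends <- which(trimws(rec) %in% c("ENDMDL", "END"))
  lapply(seq_along(modelStarts), function(m) {
    from <- modelStarts[m]
    to <- c(modelStarts, length(lines) + 1L)[m + 1L] - 1L
    stop_at <- ends[ends >= from & ends <= to]
    if (length(stop_at)) to <- min(stop_at)
    idx <- atomIdx[atomIdx > from & atomIdx < to + 1L]
    lines[idx]
  })
}

#' Read a multi-model PDB file as a backbone ensemble
#'
#' Splits the file on MODEL/ENDMDL records (a file without MODEL records
#' is a single-conformer ensemble), keeps the backbone atoms N, CA, C of
#' one chain, and reconciles the conformers: residues that lack a CA atom
#' in any conformer are dropped from all conformers; alternate locations
#' other than `' '`/`'A'` are ignored; insertion codes are rejected.
#' Residue order follows the first conformer.
#'
#' @param path PDB file.
#' @param chain chain identifier; default is the first chain seen.
#' @param entryId identifier stored on the result; defaults to the file
#'   base name.
#' @return an [EnsembleStructure-class].
#' @examples
#' cfg <- generatorConfig(seed = 7, L = 12, nConformers = 3)
#' ens <- genEnsemble(cfg)$ensemble
#' f <- tempfile(fileext = ".pdb")
#' writePdbEnsemble(ens, f)
#' readPdbEnsemble(f)
#' @export
readPdbEnsemble <- function(path, chain = NULL, entryId = NULL) {
  if (is.null(entryId))
    entryId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  blocks <- .splitModels(lines)
  blocks <- Filter(length, blocks)
  if (!length(blocks))
    stop("no ATOM records found in '", path, "'")
  models <- lapply(blocks, .parseAtomRecords)
  models <- lapply(models, function(a) {
    a <- a[a$name %in% .BACKBONE_ATOMS & a$altloc %in% c(" ", "A"), ]
    if (any(a$icode != " "))
      stop("insertion codes are not supported (residue ",
           a$resno[a$icode != " "][1], ")")
    a
  })
  if (is.null(chain)) chain <- models[[1]]$chain[1]
  models <- lapply(models, function(a) a[a$chain == chain, ])
  if (!any(vapply(models, nrow, 0L) > 0L))
    stop("no ATOM records for chain '", chain, "'")

  key <- function(a) paste(a$chain, a$resno, a$resname)
  ## residues with a CA present in every conformer
  caKeys <- lapply(models, function(a) unique(key(a[a$name == "CA", ])))
  keep <- Reduce(intersect, caKeys)
  if (!length(keep))
    stop("no residue has a CA atom in every conformer")
  ## identical (chain, resno) must name the same residue in every conformer
  allCA <- do.call(rbind, lapply(models, function(a) a[a$name == "CA", ]))
  byNo <- unique(allCA[, c("chain", "resno", "resname")])
  dupNo <- byNo$resno[duplicated(paste(byNo$chain, byNo$resno))]
  if (length(dupNo))
    stop("inconsistent residue identities across conformers at residue(s) ",
         paste(unique(dupNo), collapse = ", "))
  ## order by first conformer
  ord <- caKeys[[1]][caKeys[[1]] %in% keep]
  first <- models[[1]][models[[1]]$name == "CA", ]
  first <- first[key(first) %in% ord, ]
  first <- first[match(ord, key(first)), ]
  res <- data.frame(chain = first$chain, resno = first$resno,
                    resname = first$resname, stringsAsFactors = FALSE)
  L <- nrow(res); N <- length(models)
  coords <- array(NA_real_, dim = c(L, 3L, 3L, N))
  for (m in seq_len(N)) {
    a <- models[[m]]
    for (ai in seq_along(.BACKBONE_ATOMS)) {
      sel <- a[a$name == .BACKBONE_ATOMS[ai], ]
      idx <- match(ord, key(sel))
      hit <- which(!is.na(idx))
      coords[hit, ai, , m] <- as.matrix(sel[idx[hit], c("x", "y", "z")])
    }
  }
  EnsembleStructure(entryId, res, coords)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Serialises backbone coordinates with one MODEL/ENDMDL block per
#' conformer. Residues with absent N or C atoms omit those records.
#'
#' @param x an [EnsembleStructure-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePdbEnsemble <- function(x, path) {
  stopifnot(is(x, "EnsembleStructure"))
  res <- x@residues
  con <- file(path, "w")
  on.exit(close(con))
  elem <- c(N = "N", CA = "C", C = "C")
  for (m in seq_len(nConformers(x))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (i in seq_len(nrow(res))) {
      for (ai in seq_along(.BACKBONE_ATOMS)) {
        xyz <- x@coords[i, ai, , m]
        if (anyNA(xyz)) next
        serial <- serial + 1L
        nm <- .BACKBONE_ATOMS[ai]
        writeLines(sprintf(
          "ATOM  %5d  %-3s%4s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, nm, res$resname[i], res$chain[i], res$resno[i],
          xyz[1], xyz[2], xyz[3], elem[[nm]]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Label SEQRES residues as observed or missing
#'
#' Reads SEQRES and REMARK 465 records of an X-ray PDB file and labels
#' every SEQRES residue: `missing` if listed in REMARK 465 or absent from
#' the ATOM records, `observed` otherwise. SEQRES positions carry no
#' residue numbers in the PDB format, so the SEQRES sequence is anchored
#' at the smallest residue number seen in ATOM or REMARK 465 records
#' (falling back to 1) and numbered consecutively.
#'
#' @param path PDB file with SEQRES records.
#' @param chain chain identifier; default is the first SEQRES chain.
#' @param entryId identifier; defaults to the file base name.
#' @return a [MissingResidueLabels-class].
#' @export
readMissingResidues <- function(path, chain = NULL, entryId = NULL) {
  if (is.null(entryId))
    entryId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  seqres <- lines[rec == "SEQRES"]
  if (!length(seqres))
    stop("no SEQRES records in '", path, "' (sequence source required)")
  schain <- substr(seqres, 12, 12)
  if (is.null(chain)) chain <- schain[1]
  seqres <- seqres[schain == chain]
  if (!length(seqres)) stop("no SEQRES records for chain '", chain, "'")
  nres <- unique(as.integer(substr(seqres, 14, 17)))
  seq3 <- unlist(strsplit(trimws(substr(seqres, 20, 70)), "[ ]+"))
  if (length(seq3) != nres)
    stop("SEQRES residue count mismatch (", length(seq3), " vs ", nres, ")")

  ## REMARK 465 data lines: RES CHAIN SSSEQ (skip the header lines)
  r465 <- lines[rec == "REMARK" & substr(lines, 8, 10) == "465"]
  missingNo <- integer()
  for (ln in r465) {
    tok <- strsplit(trimws(substr(ln, 11, nchar(ln))), "[ ]+")[[1]]
    if (length(tok) == 4L && tok[1] %in% c("1", as.character(1:99)))
      tok <- tok[-1]                      # optional model number column
    if (length(tok) == 3L && tok[1] %in% names(.AA3) &&
        grepl("^-?[0-9]+$", tok[3]) && tok[2] == chain)
      missingNo <- c(missingNo, as.integer(tok[3]))
  }
  atom <- lines[rec == "ATOM  "]
  atom <- atom[substr(atom, 22, 22) == chain]
  observedNo <- unique(as.integer(substr(atom, 23, 26)))

  start <- if (length(observedNo) || length(missingNo))
    min(c(observedNo, missingNo)) else 1L
  resno <- seq(start, length.out = length(seq3))
  status <- ifelse(resno %in% missingNo | !(resno %in% observedNo),
                   "missing", "observed")
  MissingResidueLabels(entryId,
                       data.frame(resno = resno, status = status,
                                  stringsAsFactors = FALSE))
}
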