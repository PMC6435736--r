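#' @import methods
NULL

#' Accessor generics
#'
#' Small family of accessors shared by the DisorderBench S4 containers.
#' `entryId` returns the database/file identifier of a structure- or
#' profile-level object; `methodName` the predictor name; `residueNumbers`
#' the ordered residue numbering; `zScores` and `probabilities` the numeric
#' payloads; `isBinary` whether a prediction takes only values 0/1;
#' `nConformers` and `nResidues` the ensemble dimensions.
#'
#' @param x an object of one of the DisorderBench classes.
#' @return `entryId` and `methodName` return a character scalar;
#'   `residueNumbers` an integer vector; `zScores` and `probabilities`
#'   numeric vectors; `isBinary` a logical scalar; `nConformers` and
#'   `nResidues` integer scalars.
#' @name accessors
#' @aliases entryId methodName residueNumbers zScores probabilities
#'   isBinary nConformers nResidues
#' @examples
#' zp <- ZScoreProfile("demo", data.frame(resno = 1:2, aa = c("M", "K"),
#'                                        z = c(2.1, 13.0)))
#' entryId(zp)
#' zScores(zp)
NULL

#' @rdname accessors
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))

#' @rdname accessors
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' @rdname accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname accessors
#' @export
setGeneric("isBinary", function(x) standardGeneric("isBinary"))

#' @rdname accessors
#' @export
setGeneric("nConformers", function(x) standardGeneric("nConformers"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
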