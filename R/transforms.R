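## Calibration of NMR-trained predictor outputs into pseudo-probabilities
## of disorder.

#' Disorder probability from secondary-structure populations
#'
#' Interprets the sum of the predicted alpha-helix and beta-sheet
#' populations as the probability of order, so
#' `p = 1 - (pHelix + pSheet)`, clamped to `[0, 1]`. Populations may
#' exceed validity bounds by up to `tol` (text outputs of prediction
#' servers are low-precision).
#'
#' @param pHelix,pSheet numeric vectors of populations in `[0, 1]`.
#' @param tol tolerance on range violations (default 1e-6).
#' @return numeric vector of disorder probabilities.
#' @examples
#' s2dToPdis(0.3, 0.2)   # 0.5
#' @export
s2dToPdis <- function(pHelix, pSheet, tol = 1e-6) {
  stopifnot(length(pHelix) == length(pSheet))
  if (any(pHelix < -tol | pHelix > 1 + tol) ||
      any(pSheet < -tol | pSheet > 1 + tol))
    stop("secondary-structure populations outside [0, 1]")
  if (any(pHelix + pSheet > 1 + tol))
    stop("helix + sheet population exceeds 1")
  pmin(1, pmax(0, 1 - (pHelix + pSheet)))
}

#' Disorder probability from a backbone order parameter
#'
#' The bijective transformation `p = sqrt(1 - S2)` mapping a predicted
#' generalized order parameter S-squared in `[0, 1]` onto a
#' pseudo-probability of disorder in `[0, 1]` (inverse:
#' `S2 = 1 - p^2`).
#'
#' @param s2 numeric vector of order parameters in `[0, 1]`.
#' @return numeric vector of disorder probabilities.
#' @examples
#' dynamineToPdis(0.75)  # 0.5
#' @export
dynamineToPdis <- function(s2) {
  if (any(s2 < 0 | s2 > 1))
    stop("order parameter S2 outside [0, 1]")
  sqrt(1 - s2)
}
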