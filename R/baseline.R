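#' Zero a PMF profile on its long-distance baseline
#'
#' Subtracts from the whole profile the unweighted mean of F over the bins
#' whose centres lie inside the closed `range`. This anchors the PMF to
#' zero at large separation, absorbing the constant hydration free energy
#' of the isolated solutes; after the call the mean of F over the baseline
#' bins is exactly zero.
#'
#' @param pmf a \linkS4class{PMFProfile}
#' @param range numeric(2) closed distance range, Angstrom (e.g. 12--13.5
#'   for the hexane-like preset, 14--15.4 for the adamantane-like one)
#' @return the baseline-subtracted \linkS4class{PMFProfile} with
#'   `baselineRange` recorded
#' @export
subtractBaseline <- function(pmf, range) {
  stopifnot(is(pmf, "PMFProfile"), length(range) == 2L, range[1] < range[2])
  inRange <- pmf@binCenters >= range[1] & pmf@binCenters <= range[2] &
    !is.na(pmf@F)
  if (sum(inRange) < 2L)
    stop("subtractBaseline: baseline range [", range[1], ", ", range[2],
         "] covers fewer than two defined bins")
  shift <- mean(pmf@F[inRange])
  pmf@F <- pmf@F - shift
  if (length(pmf@Ferr)) pmf@Ferr <- pmf@Ferr # errors unchanged by a shift
  pmf@baselineRange <- as.numeric(range)
  pmf
}
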