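## centred moving average with shrinking windows at the ends; w is forced odd
.movingAverage <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

## indices of interior local minima/maxima of a sequence; plateaus resolve
## to their first (smallest-xi) point
.localExtrema <- function(y) {
  n <- length(y)
  mins <- maxs <- integer(0)
  if (n >= 3L) for (i in 2:(n - 1L)) {
    if (y[i] <= y[i - 1L] && y[i] <= y[i + 1L] &&
        (y[i] < y[i - 1L] || y[i] < y[i + 1L]) &&
        !(i > 2L && y[i] == y[i - 1L]))
      mins <- c(mins, i)
    if (y[i] >= y[i - 1L] && y[i] >= y[i + 1L] &&
        (y[i] > y[i - 1L] || y[i] > y[i + 1L]) &&
        !(i > 2L && y[i] == y[i - 1L]))
      maxs <- c(maxs, i)
  }
  list(mins = mins, maxs = maxs)
}

## prominence of a minimum at index i: how far it dips below the lower of
## the highest levels reached on each side
.minProminenceAt <- function(y, i) {
  left <- max(y[seq_len(i - 1L)])
  right <- max(y[(i + 1L):length(y)])
  min(left, right) - y[i]
}

#' Locate the CM, DM and SSM of a PMF profile
#'
#' Identifies the contact minimum (CM), desolvation maximum (DM) and
#' solvent-separated minimum (SSM) of a baseline-subtracted PMF. Extremum
#' positions are located on a lightly smoothed copy of the profile
#' (centred moving average over `smoothWindow` bins); the reported depths
#' and heights are read from the unsmoothed profile at the located bins.
#'
#' The CM is the global minimum (smallest distance among ties) and must be
#' an interior minimum with prominence at least `minProminence`, else an
#' error is raised. The SSM is the first subsequent minimum with that
#' prominence; the DM is the highest maximum between CM and SSM. Profiles
#' that rise monotonically from the CM to the baseline (hexane-like) get
#' `hasDM = hasSSM = FALSE`; absent features are never fabricated.
#'
#' @param pmf a baseline-subtracted \linkS4class{PMFProfile} with at least
#'   5 defined bins
#' @param smoothWindow moving-average width in bins (default 3; 1 disables
#'   smoothing)
#' @param minProminence minimum prominence, kcal/mol (default 0.05),
#'   suppressing bootstrap-level wiggles
#' @return a \linkS4class{PMFFeatures}
#' @export
findExtrema <- function(pmf, smoothWindow = 3L, minProminence = 0.05) {
  stopifnot(is(pmf, "PMFProfile"))
  defined <- which(!is.na(pmf@F))
  if (length(defined) < 5L)
    stop("findExtrema: fewer than 5 defined bins")
  x <- pmf@binCenters[defined]
  Fraw <- pmf@F[defined]
  Fs <- .movingAverage(Fraw, smoothWindow)

  ext <- .localExtrema(Fs)
  prom <- vapply(ext$mins, function(i) .minProminenceAt(Fs, i), numeric(1))
  ok <- ext$mins[prom >= minProminence]
  if (!length(ok))
    stop("findExtrema: no contact minimum (no interior minimum with ",
         "prominence >= ", minProminence, " kcal/mol)")
  cmIdx <- ok[which.min(Fs[ok])] # which.min takes the first = smallest xi

  ## SSM = first minimum beyond the CM whose separating barrier (the DM)
  ## rises at least minProminence above it; DM = the highest maximum in
  ## between. Bootstrap-level wiggles in the tail fail the prominence test
  ## and leave both flags unset.
  dmIdx <- ssmIdx <- NA_integer_
  for (cand in ext$mins[ext$mins > cmIdx]) {
    between <- ext$maxs[ext$maxs > cmIdx & ext$maxs < cand]
    if (!length(between)) next
    top <- between[which.max(Fs[between])]
    if (Fs[top] - Fs[cand] >= minProminence) {
      dmIdx <- top
      ssmIdx <- cand
      break
    }
  }

  new("PMFFeatures",
      cmPos = x[cmIdx], cmDepth = Fraw[cmIdx],
      dmPos = if (is.na(dmIdx)) NA_real_ else x[dmIdx],
      dmHeight = if (is.na(dmIdx)) NA_real_ else Fraw[dmIdx],
      ssmPos = if (is.na(ssmIdx)) NA_real_ else x[ssmIdx],
      ssmDepth = if (is.na(ssmIdx)) NA_real_ else Fraw[ssmIdx],
      hasDM = !is.na(dmIdx), hasSSM = !is.na(ssmIdx))
}
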