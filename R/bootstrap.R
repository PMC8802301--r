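#' Moving-block bootstrap uncertainty for a WHAM PMF
#'
#' Resamples each window's time series in contiguous blocks of `blockLen`
#' samples (respecting serial correlation within blocks), re-runs WHAM on
#' every resample (warm-started from the full-data solution) and attaches
#' the per-bin standard deviation of the resampled, optionally
#' baseline-subtracted, profiles as `Ferr`. Deterministic in `seed`.
#'
#' @param series list of \linkS4class{ReactionCoordinateSeries} (one
#'   condition), as for [buildHistograms()]
#' @param binWidth,range histogram grid, see [buildHistograms()]
#' @param nBoot number of bootstrap replicates (>= 2)
#' @param blockLen block length in samples; must be shorter than every
#'   series. Choose it at least as long as the chain's correlation time.
#' @param seed integer seed
#' @param baselineRange closed baseline range, or `NULL` to skip baseline
#'   subtraction of the replicates
#' @param tol,maxIter,biasConvention passed to [whamSolve()]
#' @return the full-data \linkS4class{PMFProfile} (baseline-subtracted when
#'   `baselineRange` is given) with `Ferr` filled; bins defined in fewer
#'   than two replicates get `NA` error
#' @export
bootstrapPMF <- function(series, binWidth = 0.1, range = NULL,
                         nBoot = 20L, blockLen = 100L, seed,
                         baselineRange = NULL, tol = 1e-7,
                         maxIter = 100000L,
                         biasConvention = c("k_sq", "half_k_sq")) {
  biasConvention <- match.arg(biasConvention)
  nBoot <- as.integer(nBoot)
  blockLen <- as.integer(blockLen)
  if (nBoot < 2L) stop("bootstrapPMF: 'nBoot' must be >= 2")
  if (blockLen < 1L) stop("bootstrapPMF: 'blockLen' must be >= 1")
  lens <- vapply(series, function(s) length(s@xi), integer(1))
  if (any(blockLen >= lens))
    stop("bootstrapPMF: 'blockLen' must be shorter than every series")

  hist0 <- buildHistograms(series, binWidth = binWidth, range = range)
  pmf0 <- whamSolve(hist0, tol = tol, maxIter = maxIter,
                    biasConvention = biasConvention)
  if (!is.null(baselineRange)) pmf0 <- subtractBaseline(pmf0, baselineRange)

  edges <- hist0@binEdges
  nb <- length(edges) - 1L
  Fboot <- .withSeed(seed, {
    out <- matrix(NA_real_, nrow = nBoot, ncol = nb)
    for (b in seq_len(nBoot)) {
      counts <- matrix(0L, nrow = length(series), ncol = nb)
      dropped <- integer(length(series))
      for (i in seq_along(series)) {
        n <- lens[i]
        nblocks <- ceiling(n / blockLen)
        starts <- sample.int(n - blockLen + 1L, nblocks, replace = TRUE)
        idx <- (rep(starts, each = blockLen) +
                  rep.int(0:(blockLen - 1L), nblocks))[seq_len(n)]
        bin <- findInterval(series[[i]]@xi[idx], edges)
        inside <- bin >= 1L & bin <= nb
        counts[i, ] <- tabulate(bin[inside], nbins = nb)
        dropped[i] <- sum(!inside)
      }
      h <- new("HistogramSet", binEdges = edges, counts = counts,
               nTotal = as.integer(rowSums(counts)), dropped = dropped,
               windows = hist0@windows, condition = hist0@condition)
      pb <- suppressWarnings(
        whamSolve(h, tol = tol, maxIter = maxIter,
                  biasConvention = biasConvention,
                  fInit = pmf0@windowShifts))
      Fb <- pb@F
      if (!is.null(baselineRange)) {
        inR <- pb@binCenters >= baselineRange[1] &
          pb@binCenters <= baselineRange[2] & !is.na(Fb)
        if (sum(inR) >= 1L) Fb <- Fb - mean(Fb[inR])
      }
      out[b, ] <- Fb
    }
    out
  })

  nOk <- colSums(!is.na(Fboot))
  Ferr <- rep(NA_real_, nb)
  Ferr[nOk >= 2L] <- apply(Fboot[, nOk >= 2L, drop = FALSE], 2L,
                           stats::sd, na.rm = TRUE)
  pmf0@Ferr <- Ferr
  pmf0
}
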