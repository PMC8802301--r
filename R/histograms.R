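#' Bin window series onto a common histogram grid
#'
#' Bins the reaction-coordinate samples of every window of one condition
#' onto a shared grid of half-open bins `[edge_j, edge_{j+1})`. Samples
#' outside the grid are dropped and counted, so for every window
#' `retained + dropped` equals the series length.
#'
#' @param series list of \linkS4class{ReactionCoordinateSeries}, all sharing
#'   one condition
#' @param binWidth bin width, Angstrom (default 0.1)
#' @param range numeric(2) grid limits; default `min(d0) - 1` to
#'   `max(d0) + 2` over the windows present
#' @return a \linkS4class{HistogramSet}
#' @examples
#' s <- ReactionCoordinateSeries(WindowSpec(4, 0), Condition(298),
#'                               xi = c(4.05, 4.24, 4.26))
#' binCounts(buildHistograms(list(s), binWidth = 0.2, range = c(4, 4.4)))
#' @export
buildHistograms <- function(series, binWidth = 0.1, range = NULL) {
  if (length(series) == 0L)
    stop("buildHistograms: empty series list")
  stopifnot(all(vapply(series, is, logical(1), "ReactionCoordinateSeries")))
  if (binWidth <= 0) stop("buildHistograms: 'binWidth' must be positive")

  conds <- vapply(series, function(s)
    sprintf("%.10g|%.10g", s@condition@temperature,
            s@condition@ionicStrength), character(1))
  if (length(unique(conds)) != 1L)
    stop("buildHistograms: series mix different (T, IS) conditions")

  d0s <- vapply(series, function(s) s@window@d0, numeric(1))
  if (is.null(range)) range <- c(min(d0s) - 1, max(d0s) + 2)
  nb <- as.integer(ceiling((range[2] - range[1]) / binWidth - 1e-9))
  if (nb < 1L) stop("buildHistograms: 'range' narrower than one bin")
  edges <- range[1] + (0:nb) * binWidth

  counts <- matrix(0L, nrow = length(series), ncol = nb)
  dropped <- integer(length(series))
  for (i in seq_along(series)) {
    idx <- findInterval(series[[i]]@xi, edges) # [edge_j, edge_{j+1})
    inside <- idx >= 1L & idx <= nb
    counts[i, ] <- tabulate(idx[inside], nbins = nb)
    dropped[i] <- sum(!inside)
  }
  new("HistogramSet", binEdges = edges, counts = counts,
      nTotal = as.integer(rowSums(counts)), dropped = dropped,
      windows = lapply(series, function(s) s@window),
      condition = series[[1]]@condition)
}
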