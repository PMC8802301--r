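.lse <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

## column-wise log-sum-exp of a small-row matrix, shifted for stability
.colLse <- function(B) {
  m <- nrow(B)
  mx <- B[1L, ]
  if (m > 1L) for (i in 2:m) mx <- pmax(mx, B[i, ])
  ok <- is.finite(mx)
  out <- mx
  if (any(ok)) {
    S <- exp(B[, ok, drop = FALSE] -
               matrix(mx[ok], m, sum(ok), byrow = TRUE))
    out[ok] <- mx[ok] + log(.colSums(S, m, sum(ok)))
  }
  out
}

#' Self-consistent WHAM solution of a histogram set
#'
#' Iterates the two coupled WHAM equations for the unbiased bin
#' probabilities and the per-window free-energy shifts,
#' \deqn{p_j \propto \frac{\sum_i n_{ij}}{\sum_i N_i e^{-(w_i(\xi_j) - f_i)/k_BT}},\qquad
#'       f_i = -k_BT \ln \sum_j p_j e^{-w_i(\xi_j)/k_BT},}
#' with the bias \eqn{w_i} evaluated at bin centres, until the largest
#' change of any \eqn{f_i} falls below `tol`. The gauge is fixed by
#' \eqn{f_1 = 0}. All exponentials are evaluated in shifted (log-sum-exp)
#' form, so stiff far-window biases neither overflow nor destabilise the
#' iteration. The PMF is \eqn{F_j = -k_BT \ln p_j}, defined only for bins
#' with at least one count (`NA` elsewhere); its additive offset is
#' meaningless until [subtractBaseline()] is applied.
#'
#' @param hist a \linkS4class{HistogramSet}
#' @param tol convergence tolerance on the shifts, kcal/mol (default 1e-7)
#' @param maxIter iteration cap (default 1e5); if exceeded the profile is
#'   returned with `converged = FALSE` and a warning
#' @param biasConvention see [biasEnergy()]
#' @param fInit optional warm-start shifts, kcal/mol (e.g. from a previous
#'   solution during bootstrap resampling)
#' @param biasOffsets optional per-window constants added to the bias
#'   energies, kcal/mol (restraint reference offsets); they are absorbed
#'   into the window shifts and leave the PMF invariant
#' @return a \linkS4class{PMFProfile} (no baseline applied, no errors)
#' @references Kumar et al. (1992) J Comput Chem 13:1011; Roux (1995)
#'   Comput Phys Commun 91:275.
#' @export
whamSolve <- function(hist, tol = 1e-7, maxIter = 100000L,
                      biasConvention = c("k_sq", "half_k_sq"),
                      fInit = NULL, biasOffsets = NULL) {
  stopifnot(is(hist, "HistogramSet"))
  biasConvention <- match.arg(biasConvention)
  if (length(hist@windows) < 1L) stop("whamSolve: no windows")
  ntotj <- colSums(hist@counts)
  if (all(ntotj == 0)) stop("whamSolve: all histogram bins are empty")

  kBT <- kB * hist@condition@temperature
  centers <- (hist@binEdges[-1] + hist@binEdges[-length(hist@binEdges)]) / 2
  m <- length(hist@windows)
  ## A[i, j] = -w_i(xi_j)/kBT, the log Boltzmann factor of window i's bias
  if (is.null(biasOffsets)) biasOffsets <- numeric(m)
  stopifnot(length(biasOffsets) == m)
  A <- t(vapply(seq_len(m), function(i)
    -(biasEnergy(hist@windows[[i]], centers, biasConvention) +
        biasOffsets[i]) / kBT, numeric(length(centers))))
  A <- matrix(A, nrow = m)

  logN <- ifelse(hist@nTotal > 0, log(hist@nTotal), -Inf)
  lognum <- ifelse(ntotj > 0, log(ntotj), -Inf)
  defined <- ntotj > 0

  g <- if (is.null(fInit)) numeric(m) else fInit / kBT
  g <- g - g[1L]
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    D <- .colLse(A + (logN + g))      # recycles down columns: rows = windows
    lp <- lognum - D
    lp <- lp - .lse(lp[defined])
    gnew <- -apply(A + rep(lp, each = m), 1L, .lse)
    gnew <- gnew - gnew[1L]
    delta <- max(abs(gnew - g)) * kBT
    g <- gnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("whamSolve: not converged after ", iter,
            " iterations (last change ", format(delta), " kcal/mol)")

  D <- .colLse(A + (logN + g))
  lp <- lognum - D
  lp <- lp - .lse(lp[defined])
  F <- ifelse(defined, -kBT * lp, NA_real_)

  new("PMFProfile", binCenters = centers, F = F, Ferr = numeric(0),
      counts = as.numeric(ntotj), windowShifts = kBT * g,
      condition = hist@condition, converged = converged,
      iterations = iter)
}
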