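# Independent oracles used to cross-check the package implementations.
# These are deliberately written in plain arithmetic, sharing no code with
# the package internals.

# Naive WHAM fixed-point iteration: direct exponentials, no log-sum-exp,
# no gauge tricks beyond f[1] = 0. Suitable only for small toy instances.
oracleWham <- function(counts, N, W, kBT, tol = 1e-13, maxIter = 500000L) {
  m <- nrow(counts)
  B <- exp(-W / kBT)               # m x nb Boltzmann bias factors
  ntot <- colSums(counts)
  f <- rep(0, m)
  for (it in seq_len(maxIter)) {
    denom <- colSums(N * exp(f / kBT) * B)
    p <- ifelse(ntot > 0, ntot / denom, 0)
    p <- p / sum(p)
    fnew <- -kBT * log(as.numeric(B %*% p))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) {
      f <- fnew
      break
    }
    f <- fnew
  }
  denom <- colSums(N * exp(f / kBT) * B)
  p <- ifelse(ntot > 0, ntot / denom, 0)
  list(p = p / sum(p), f = f)
}

# Normalized probabilities implied by a PMFProfile (defined bins only).
profileToProbs <- function(pmf) {
  kBT <- hydrotherm::kB * temperature(pmf)
  F <- pmfValues(pmf)
  p <- ifelse(is.na(F), 0, exp(-(F - min(F, na.rm = TRUE)) / kBT))
  p / sum(p)
}

# Biased target CDF by trapezoidal quadrature of
# exp(-(U_model + k (x - d0)^2) / kBT) on (wallPos, xMax].
quadratureBiasedCdf <- function(model, window, condition, xMax,
                                dx = 0.002) {
  lo <- model@wallPos + 0.02
  x <- seq(lo, xMax, by = dx)
  u <- modelPMF(model, x, condition) + biasEnergy(window, x)
  kBT <- hydrotherm::kB * temperature(condition)
  dens <- exp(-(u - min(u)) / kBT)
  w <- rep(dx, length(x)); w[1] <- w[length(x)] <- dx / 2
  cum <- cumsum(dens * w)
  list(x = x, cdf = cum / cum[length(cum)])
}

# Kolmogorov-Smirnov distance between samples and a tabulated CDF.
ksDistance <- function(samples, grid, cdf) {
  n <- length(samples)
  Fq <- approx(grid, cdf, xout = sort(samples), rule = 2)$y
  max(abs(Fq - (seq_len(n) - 1) / n), abs(Fq - seq_len(n) / n))
}

# Effective sample size from the initial positive autocorrelations.
effectiveSampleSize <- function(x) {
  n <- length(x)
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 1L, 200L),
                               plot = FALSE)$acf)[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
  n / (1 + 2 * sum(rho))
}

# Brute-force local extrema of a vector (no smoothing, no prominence).
bruteExtrema <- function(y) {
  n <- length(y)
  mins <- maxs <- integer(0)
  for (i in 2:(n - 1L)) {
    if (y[i] < y[i - 1L] && y[i] < y[i + 1L]) mins <- c(mins, i)
    if (y[i] > y[i - 1L] && y[i] > y[i + 1L]) maxs <- c(maxs, i)
  }
  list(mins = mins, maxs = maxs)
}
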