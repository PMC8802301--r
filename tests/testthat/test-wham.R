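## Exact Gaussian window samples over a flat underlying potential:
## the biased density of window (d0, k) is N(d0, kBT/(2k)).
gaussianWindowSeries <- function(d0s, k, n, temperature = 298, seed = 1) {
  set.seed(seed)
  sd <- sqrt(kB * temperature / (2 * k))
  lapply(d0s, function(d)
    seriesFromXi(rnorm(n, d, sd), d0 = d, k = k,
                 temperature = temperature))
}

test_that("zero-bias single window reduces to Boltzmann inversion", {
  set.seed(7)
  xi <- 5 + abs(rnorm(5000, 0, 0.8))
  s <- seriesFromXi(xi, d0 = 6, k = 0)
  h <- buildHistograms(list(s), binWidth = 0.2, range = c(4.5, 9))
  pmf <- whamSolve(h, tol = 1e-12)
  kBT <- kB * 298
  counts <- binCounts(pmf)
  direct <- -kBT * log(counts / sum(counts))
  def <- !is.na(pmfValues(pmf))
  diffs <- pmfValues(pmf)[def] - direct[def]
  expect_lt(max(diffs) - min(diffs), 1e-8) # equal up to an additive constant
})

test_that("flat underlying potential is recovered flat", {
  ser <- gaussianWindowSeries(5:10, k = 2, n = 20000, seed = 2)
  h <- buildHistograms(ser, binWidth = 0.1)
  pmf <- whamSolve(h)
  sel <- !is.na(pmfValues(pmf)) & binCounts(pmf) >= 500
  F <- pmfValues(pmf)[sel]
  expect_gt(sum(sel), 30)
  expect_lt(max(abs(F - mean(F))), 0.05) # statistical noise only
})

test_that("toy instances agree with the brute-force fixed-point oracle", {
  kBT <- kB * 298
  ## 5-bin, 2-window instance with hand-enumerable counts
  counts <- rbind(c(40, 30, 20, 8, 2),
                  c(2, 10, 28, 30, 30))
  wins <- list(WindowSpec(4.1, 1), WindowSpec(4.9, 1))
  h <- new("HistogramSet", binEdges = seq(4.0, 5.0, 0.2),
           counts = counts, nTotal = as.integer(rowSums(counts)),
           dropped = c(0L, 0L), windows = wins,
           condition = Condition(298, 0))
  pmf <- whamSolve(h, tol = 1e-12)
  centers <- seq(4.1, 4.9, 0.2)
  W <- rbind(biasEnergy(wins[[1]], centers), biasEnergy(wins[[2]], centers))
  oracle <- oracleWham(counts, rowSums(counts), W, kBT, tol = 1e-13)
  expect_lt(max(abs(profileToProbs(pmf) - oracle$p)), 1e-8)
  expect_lt(max(abs(windowShifts(pmf) - oracle$f)), 1e-7)
})

test_that("adding a constant to every bias leaves the PMF invariant", {
  ser <- gaussianWindowSeries(c(5, 6, 7), k = 2, n = 5000, seed = 3)
  h <- buildHistograms(ser, binWidth = 0.1)
  base <- subtractBaseline(whamSolve(h, tol = 1e-10), c(6.5, 7.5))
  shifted <- subtractBaseline(
    whamSolve(h, tol = 1e-10, biasOffsets = rep(3.7, 3)), c(6.5, 7.5))
  def <- !is.na(pmfValues(base))
  expect_lt(max(abs(pmfValues(base)[def] - pmfValues(shifted)[def])), 1e-8)
})

test_that("the converged solution is a fixed point of one iteration", {
  ser <- gaussianWindowSeries(c(5, 6, 7), k = 2, n = 3000, seed = 4)
  h <- buildHistograms(ser, binWidth = 0.1)
  pmf <- whamSolve(h, tol = 1e-9)
  expect_true(isConverged(pmf))
  again <- whamSolve(h, tol = 1e-9, fInit = windowShifts(pmf))
  expect_true(isConverged(again))
  expect_identical(again@iterations, 1L)
})

test_that("iteration cap yields an unconverged profile with a warning", {
  ser <- gaussianWindowSeries(c(5, 6, 7, 8), k = 2, n = 3000, seed = 5)
  h <- buildHistograms(ser, binWidth = 0.1)
  expect_warning(pmf <- whamSolve(h, tol = 1e-12, maxIter = 3L),
                 "not converged")
  expect_false(isConverged(pmf))
})

test_that("an all-empty histogram is an error", {
  s <- seriesFromXi(c(20, 21), d0 = 8, k = 2) # outside the grid
  h <- buildHistograms(list(s), binWidth = 0.1, range = c(5, 10))
  expect_error(whamSolve(h), "empty")
})
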