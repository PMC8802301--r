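## analytic three-feature profile: minima at 6.2 (-1.8) and 9.8 (-0.4),
## barrier at 8.0 (+0.6), rising wall on the left, zero tail
threeFeatureF <- function(x)
  5 * exp(-(x - 4) / 0.3) - 1.8 * exp(-(x - 6.2)^2 / 0.18) +
  0.6 * exp(-(x - 8.0)^2 / 0.18) - 0.4 * exp(-(x - 9.8)^2 / 0.18)

test_that("constructed CM/DM/SSM profile yields exactly those features", {
  pmf <- profileFromFunction(threeFeatureF, 4, 14, by = 0.1)
  f <- findExtrema(pmf, smoothWindow = 1, minProminence = 0.05)
  expect_lt(abs(cmPosition(f) - 6.2), 0.06)
  expect_lt(abs(cmDepth(f) - (-1.8)), 0.05)
  expect_true(hasDM(f))
  expect_lt(abs(dmPosition(f) - 8.0), 0.06)
  expect_lt(abs(dmHeight(f) - 0.6), 0.05)
  expect_true(hasSSM(f))
  expect_lt(abs(ssmPosition(f) - 9.8), 0.06)
  expect_lt(abs(ssmDepth(f) - (-0.4)), 0.05)
})

test_that("a monotonic rise from a single minimum has no DM or SSM", {
  f1 <- function(x) 5 * exp(-(x - 4)) - 1.5 * exp(-(x - 6)^2 / 0.5)
  f <- findExtrema(profileFromFunction(f1, 4, 14))
  expect_false(hasDM(f))
  expect_false(hasSSM(f))
  expect_true(is.na(dmPosition(f)) && is.na(ssmPosition(f)))
})

test_that("noiseless model PMF locates the CM within one bin", {
  for (preset in list(hexanePreset(), adamantanePreset())) {
    m <- preset$model
    cond <- Condition(298, 0)
    pmf <- profileFromFunction(function(x) modelPMF(m, x, cond),
                               m@wallPos + 0.4, max(preset$ladder) + 2)
    f <- findExtrema(pmf)
    ## brute-force argmin oracle on the same grid
    oracle <- binCenters(pmf)[which.min(pmfValues(pmf))]
    expect_equal(cmPosition(f), oracle, tolerance = 1e-12)
    expect_lt(abs(cmPosition(f) - m@cmPos), 0.1 + 1e-9)
  }
})

test_that("adding a constant moves no positions and shifts all values", {
  pmf <- profileFromFunction(threeFeatureF, 4, 14)
  f0 <- findExtrema(pmf)
  pmf2 <- pmf
  pmf2@F <- pmf2@F + 2.5
  f1 <- findExtrema(pmf2)
  expect_identical(cmPosition(f1), cmPosition(f0))
  expect_identical(dmPosition(f1), dmPosition(f0))
  expect_identical(ssmPosition(f1), ssmPosition(f0))
  expect_equal(cmDepth(f1) - cmDepth(f0), 2.5, tolerance = 1e-12)
  expect_equal(dmHeight(f1) - dmHeight(f0), 2.5, tolerance = 1e-12)
})

test_that("halving the bin width moves positions by at most one coarse bin", {
  coarse <- findExtrema(profileFromFunction(threeFeatureF, 4, 14, by = 0.1))
  fine <- findExtrema(profileFromFunction(threeFeatureF, 4, 14, by = 0.05))
  expect_lt(abs(cmPosition(fine) - cmPosition(coarse)), 0.1 + 1e-9)
  expect_lt(abs(dmPosition(fine) - dmPosition(coarse)), 0.1 + 1e-9)
  expect_lt(abs(ssmPosition(fine) - ssmPosition(coarse)), 0.1 + 1e-9)
})

test_that("zero prominence without smoothing reduces to the brute scan", {
  set.seed(21)
  for (rep in 1:5) {
    x <- seq(4, 10, by = 0.25)
    y <- 3 * exp(-(x - 4)) - exp(-(x - 6)^2) + cumsum(rnorm(length(x), 0,
                                                            0.05))
    pmf <- new("PMFProfile", binCenters = x, F = y, Ferr = numeric(0),
               counts = rep(100, length(x)), windowShifts = 0,
               condition = Condition(298, 0), converged = TRUE,
               iterations = 1L)
    br <- bruteExtrema(y)
    if (!length(br$mins)) next
    f <- findExtrema(pmf, smoothWindow = 1, minProminence = 0)
    expect_equal(cmDepth(f), min(y[br$mins]), tolerance = 1e-12)
    expect_equal(cmPosition(f), x[br$mins[which.min(y[br$mins])]],
                 tolerance = 1e-12)
  }
})

test_that("profiles without an interior minimum raise a clear error", {
  rising <- profileFromFunction(function(x) 3 * exp(-(x - 4)), 4, 14)
  expect_error(findExtrema(rising), "no contact minimum")
  tiny <- profileFromFunction(function(x) -exp(-(x - 6)^2), 5.8, 6.2)
  expect_error(findExtrema(tiny), "5 defined bins")
})
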