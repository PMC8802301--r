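test_that("identical seed and inputs give bitwise-identical series", {
  m <- hexanePreset()$model
  w <- WindowSpec(6, 2)
  cond <- Condition(298, 0.4)
  s1 <- sampleWindow(m, w, cond, nSamples = 2000, seed = 77)
  s2 <- sampleWindow(m, w, cond, nSamples = 2000, seed = 77)
  expect_identical(xiValues(s1), xiValues(s2))
  expect_identical(sampleTimes(s1), sampleTimes(s2))
  s3 <- sampleWindow(m, w, cond, nSamples = 2000, seed = 78)
  expect_false(identical(xiValues(s1), xiValues(s3)))
})

test_that("sampling leaves the caller's RNG stream untouched", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(sampleWindow(flatModel(), WindowSpec(8, 50), Condition(298, 0),
                         nSamples = 100, seed = 5))
  expect_identical(runif(1), r1)
})

test_that("stiff harmonic window reproduces the Gaussian closed form", {
  ## flat model, k = 50: target density ~ exp(-k (xi-d0)^2 / kBT), so
  ## mean = d0 and var = kBT / (2 k)
  s <- sampleWindow(flatModel(), WindowSpec(8, 50), Condition(298, 0),
                    nSamples = 50000, seed = 42)
  expect_lt(abs(mean(xiValues(s)) - 8), 0.02)
  target <- kB * 298 / (2 * 50)
  expect_lt(abs(var(xiValues(s)) / target - 1), 0.05)
})

test_that("biased sampling matches the quadrature CDF (KS test)", {
  p <- hexanePreset()
  w <- WindowSpec(6, 2)
  cond <- Condition(298, 0)
  s <- sampleWindow(p$model, w, cond, nSamples = 50000, seed = 11)
  q <- quadratureBiasedCdf(p$model, w, cond, xMax = max(w@d0 + 6,
                                                        p$model@cmPos + 6))
  D <- ksDistance(xiValues(s), q$x, q$cdf)
  ess <- effectiveSampleSize(xiValues(s))
  expect_gt(ess, 1000)
  expect_lt(D, 1.628 / sqrt(ess)) # 1% critical value
})

test_that("chains converge to the target distribution as they grow", {
  ## stationarity: KS distance to the quadrature CDF decreases with length
  m <- flatModel()
  w <- WindowSpec(7, 2)
  cond <- Condition(298, 0)
  q <- quadratureBiasedCdf(m, w, cond, xMax = 13)
  ks <- vapply(c(500, 50000), function(n) {
    s <- sampleWindow(m, w, cond, nSamples = n, seed = 9)
    ksDistance(xiValues(s), q$x, q$cdf)
  }, numeric(1))
  expect_lt(ks[2], ks[1])
})

test_that("sampler rejects non-positive sample counts", {
  expect_error(sampleWindow(flatModel(), WindowSpec(8, 2),
                            Condition(298, 0), nSamples = 0, seed = 1),
               "nSamples")
  expect_error(sampleWindow(flatModel(), WindowSpec(8, 2),
                            Condition(298, 0), nSamples = -5, seed = 1),
               "nSamples")
})

test_that("sampled series respect the synthetic time stride and domain", {
  s <- sampleWindow(flatModel(), WindowSpec(8, 2), Condition(298, 0),
                    nSamples = 500, seed = 3)
  expect_equal(sampleTimes(s), (1:500) * 0.2)
  expect_true(all(xiValues(s) > 0))
})
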