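test_that("bootstrap errors are deterministic in the seed", {
  set.seed(11)
  ser <- lapply(c(5, 6), function(d)
    seriesFromXi(rnorm(800, d, 0.4), d0 = d, k = 2))
  a <- bootstrapPMF(ser, binWidth = 0.2, nBoot = 5, blockLen = 20,
                    seed = 31)
  b <- bootstrapPMF(ser, binWidth = 0.2, nBoot = 5, blockLen = 20,
                    seed = 31)
  expect_identical(pmfErrors(a), pmfErrors(b))
  c <- bootstrapPMF(ser, binWidth = 0.2, nBoot = 5, blockLen = 20,
                    seed = 32)
  expect_false(identical(pmfErrors(a), pmfErrors(c)))
})

test_that("constant series give a single defined bin with zero error", {
  s <- seriesFromXi(rep(6.05, 100), d0 = 6, k = 2)
  pmf <- bootstrapPMF(list(s), binWidth = 0.1, range = c(5, 7),
                      nBoot = 4, blockLen = 10, seed = 1)
  def <- which(!is.na(pmfValues(pmf)))
  expect_length(def, 1L)
  expect_identical(pmfErrors(pmf)[def], 0)
  expect_true(all(is.na(pmfErrors(pmf)[-def])))
})

test_that("bootstrap scale matches across-replicate variability", {
  ## flat potential; compare mean bootstrap error with the empirical sd of
  ## F across independently regenerated studies (factor-2 agreement)
  kBT <- kB * 298
  gen <- function(seed) {
    set.seed(seed)
    lapply(c(5, 6, 7), function(d)
      seriesFromXi(rnorm(3000, d, sqrt(kBT / 4)), d0 = d, k = 2))
  }
  boot <- bootstrapPMF(gen(100), binWidth = 0.1, nBoot = 30, blockLen = 10,
                       seed = 9, baselineRange = c(6.5, 7.5))
  sel <- !is.na(pmfValues(boot)) & binCounts(boot) >= 200
  Fmat <- vapply(1:20, function(r) {
    h <- buildHistograms(gen(200 + r), binWidth = 0.1,
                         range = range(binCenters(boot)) + c(-0.05, 0.05))
    pmfValues(subtractBaseline(whamSolve(h), c(6.5, 7.5)))
  }, numeric(length(binCenters(boot))))
  empir <- apply(Fmat[sel, ], 1, sd, na.rm = TRUE)
  ratio <- mean(pmfErrors(boot)[sel]) / mean(empir)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("bootstrap input contracts are enforced", {
  s <- seriesFromXi(rnorm(50, 6, 0.3), d0 = 6, k = 2)
  expect_error(bootstrapPMF(list(s), nBoot = 1, blockLen = 5, seed = 1),
               "nBoot")
  expect_error(bootstrapPMF(list(s), nBoot = 3, blockLen = 50, seed = 1),
               "blockLen")
  expect_error(bootstrapPMF(list(s), nBoot = 3, blockLen = 0, seed = 1),
               "blockLen")
})
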