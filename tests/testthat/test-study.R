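test_that("preset ladders match the emulated protocol", {
  expect_equal(hexanePreset()$ladder, seq(4, 14, by = 1))
  expect_equal(adamantanePreset()$ladder,
               c(4.0, 5.0, 6.0, 6.5, 7.0, 7.5, 8.0, 8.5, 9.0, 9.5, 10.0,
                 10.5, 11.0, 11.5, 12.0, 12.5, 13.0, 13.5, 14.0, 14.5,
                 15.0, 16.0, 17.0, 18.0))
  expect_equal(hexanePreset()$temperatures, paperTemperatures)
  expect_equal(hexanePreset()$ionicStrengths, paperIonicStrengths)
  expect_identical(hexanePreset()$nSamples, 50000L)
  expect_identical(adamantanePreset()$nSamples, 50000L)
  expect_equal(hexanePreset()$k, 2)
  expect_equal(hexanePreset()$baselineRange, c(12, 13.5))
  expect_equal(adamantanePreset()$baselineRange, c(14, 15.4))
})

test_that("study grids are complete: 495 hexane-like, 1080 adamantane-like", {
  hx <- generateStudy(hexanePreset(nSamples = 5), seed = 1)
  expect_identical(length(hx), 9L * 5L * 11L) # 495
  ad <- generateStudy(adamantanePreset(nSamples = 5), seed = 1)
  expect_identical(length(ad), 9L * 5L * 24L) # 1080
  ## every (window, condition) cell appears exactly once
  keys <- vapply(seriesList(hx), function(s)
    sprintf("%s|%g|%g", s@window@label, temperature(s), ionicStrength(s)),
    character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(vapply(seriesList(hx), length, integer(1)) == 5L))
})

test_that("a study is a pure function of (protocol, seed)", {
  p <- hexanePreset(temperatures = c(298, 323), ionicStrengths = c(0, 1),
                    nSamples = 50)
  a <- generateStudy(p, seed = 4)
  b <- generateStudy(p, seed = 4)
  expect_identical(lapply(seriesList(a), xiValues),
                   lapply(seriesList(b), xiValues))
  c <- generateStudy(p, seed = 5)
  expect_false(identical(lapply(seriesList(a), xiValues),
                         lapply(seriesList(c), xiValues)))
})

test_that("duplicate windows or conditions are rejected", {
  p <- hexanePreset(nSamples = 5)
  p$ladder <- c(4, 5, 5, 6)
  expect_error(generateStudy(p, 1), "duplicate")
  p2 <- hexanePreset(temperatures = c(298, 298), nSamples = 5)
  expect_error(generateStudy(p2, 1), "duplicate")
})
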