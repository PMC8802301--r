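test_that("an exact quadratic is recovered to machine precision", {
  Ts <- paperTemperatures
  dF <- 2.0 - 0.02 * Ts - 3e-5 * Ts^2
  fit <- fitFreeEnergyVsTemperature(Ts, dF)
  expect_lt(max(abs(coef(fit) - c(2.0, -0.02, -3e-5))), 1e-10)
  ## three collinear points: curvature is zero
  lin <- fitFreeEnergyVsTemperature(c(280, 300, 320), 1 - 0.005 *
                                      c(280, 300, 320))
  expect_lt(abs(coef(lin)[["c"]]), 1e-12)
})

test_that("the thermodynamic state follows the decided closed forms", {
  Ts <- paperTemperatures
  fit <- fitFreeEnergyVsTemperature(Ts, 2.0 - 0.02 * Ts - 3e-5 * Ts^2)
  st <- thermoState(fit, 298)
  expect_equal(st@dF, -6.62412, tolerance = 1e-9)
  expect_equal(st@dS, 0.03788, tolerance = 1e-9)
  expect_equal(st@dU, 4.66412, tolerance = 1e-9)
  expect_equal(st@dCv, 17.880, tolerance = 1e-9)
  ## c = 0: no heat capacity, dU independent of T
  lin <- fitFreeEnergyVsTemperature(Ts, 1 - 0.005 * Ts)
  expect_lt(abs(thermoState(lin, 298)@dCv), 1e-8)
  expect_lt(abs(thermoState(lin, 273)@dU - thermoState(lin, 373)@dU), 1e-8)
})

test_that("dF = dU - T dS holds for arbitrary fits and temperatures", {
  set.seed(31)
  Ts <- paperTemperatures
  for (rep in 1:20) {
    dF <- rnorm(1, 0, 2) + rnorm(1, 0, 0.02) * Ts +
      rnorm(1, 0, 1e-4) * Ts^2 + rnorm(9, 0, 0.05)
    fit <- fitFreeEnergyVsTemperature(Ts, dF)
    for (Tq in c(273, 298.15, 350)) {
      st <- thermoState(fit, Tq)
      expect_lt(abs(st@dF - (st@dU - Tq * st@dS)), 1e-10)
    }
  }
})

test_that("95% CI for the curvature has calibrated coverage", {
  Ts <- paperTemperatures
  truth <- c(a = 2.0, b = -0.02, c = -3e-5)
  mu <- truth[1] + truth[2] * Ts + truth[3] * Ts^2
  sigma <- 0.05
  set.seed(2024)
  hits <- 0L
  nrep <- 1000L
  for (r in seq_len(nrep)) {
    fit <- fitFreeEnergyVsTemperature(Ts, mu + rnorm(9, 0, sigma),
                                      sigma = rep(sigma, 9))
    se <- sqrt(vcov(fit)[3, 3])
    ci <- coef(fit)[["c"]] + c(-1, 1) * qnorm(0.975) * se
    if (truth[3] >= ci[1] && truth[3] <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.93)
  expect_lte(hits / nrep, 0.97)
})

test_that("weighted and unweighted covariances behave as documented", {
  Ts <- paperTemperatures
  set.seed(5)
  y <- 1 - 0.01 * Ts + rnorm(9, 0, 0.05)
  wfit <- fitFreeEnergyVsTemperature(Ts, y, sigma = rep(0.05, 9))
  ufit <- fitFreeEnergyVsTemperature(Ts, y)
  expect_true(wfit@weighted)
  expect_false(ufit@weighted)
  ## unweighted covariance cross-check against stats::lm
  lmfit <- lm(y ~ Ts + I(Ts^2))
  expect_equal(unname(coef(ufit)), unname(coef(lmfit)), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(vcov(ufit)))),
               unname(sqrt(diag(vcov(lmfit)))), tolerance = 1e-6)
  ## exact 3-point fit: zero residual covariance
  efit <- fitFreeEnergyVsTemperature(c(280, 300, 320), 1 - 0.005 *
                                       c(280, 300, 320))
  expect_lt(max(abs(vcov(efit))), 1e-15)
})

test_that("fit preconditions are enforced", {
  expect_error(fitFreeEnergyVsTemperature(c(298, 298, 298), c(1, 2, 3)),
               "distinct")
  expect_error(fitFreeEnergyVsTemperature(c(298, 310), c(1, 2)), "distinct")
  expect_error(fitFreeEnergyVsIonicStrength(c(1, 1), c(0.1, 0.2)),
               "distinct")
})

test_that("an exact line over the ionic-strength grid is recovered", {
  IS <- paperIonicStrengths
  fit <- fitFreeEnergyVsIonicStrength(IS, -1.2 - 0.15 * IS,
                                      temperature = 298)
  expect_lt(abs(fit@slope - (-0.15)), 1e-12)
  expect_lt(abs(fit@intercept - (-1.2)), 1e-12)
  expect_false(fit@saturated)
})

test_that("two-point ionic fits interpolate exactly but are flagged", {
  fit <- fitFreeEnergyVsIonicStrength(c(0, 2), c(-1.0, -1.4),
                                      temperature = 298)
  expect_equal(fit@intercept, -1.0, tolerance = 1e-12)
  expect_equal(fit@slope, -0.2, tolerance = 1e-12)
  expect_true(fit@saturated)
  expect_true(all(is.na(vcov(fit))))
})
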