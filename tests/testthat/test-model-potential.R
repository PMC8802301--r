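test_that("CM depth is pinned exactly by the temperature/ionic-strength law", {
  m <- ModelPotential(cmPos = 6, depthTQuad = c(2, -0.02, 2e-5),
                      depthISSlope = -0.1, wallPos = 3, wallScale = 1.2)
  for (Tv in c(273, 298, 373)) for (isv in c(0, 0.4, 2)) {
    want <- 2 - 0.02 * Tv + 2e-5 * Tv^2 - 0.1 * isv
    expect_equal(cmDepth(m, Tv, isv), want, tolerance = 1e-12)
    expect_equal(modelPMF(m, 6, Condition(Tv, isv)), want,
                 tolerance = 1e-12)
  }
  ## pinning works with DM/SSM features overlapping the CM region too
  m2 <- adamantanePreset()$model
  expect_equal(modelPMF(m2, m2@cmPos, Condition(298, 0)),
               cmDepth(m2, 298, 0), tolerance = 1e-12)
})

test_that("model PMF vanishes at large separation and diverges at the wall", {
  for (m in list(hexanePreset()$model, adamantanePreset()$model)) {
    cond <- Condition(298, 0.4)
    expect_lt(abs(modelPMF(m, 50, cond)), 1e-6)
    expect_gt(modelPMF(m, m@wallPos + 1e-3, cond), 1e10)
    expect_error(modelPMF(m, m@wallPos - 0.1, cond), "wall")
    expect_error(modelPMF(m, c(5, m@wallPos), cond), "wall")
  }
})

test_that("temperature difference of the CM depth follows the quadratic", {
  ## choose the quadratic so depth(373) - depth(273) = -0.8 exactly:
  ## b*(373-273) + c*(373^2-273^2) = -0.8 with c = 0 -> b = -0.008
  m <- ModelPotential(cmPos = 5.5, depthTQuad = c(1, -0.008, 0),
                      wallPos = 3, wallScale = 1.2)
  d <- modelPMF(m, 5.5, Condition(373, 0)) - modelPMF(m, 5.5,
                                                      Condition(273, 0))
  expect_equal(d, -0.8, tolerance = 1e-12)
  ## and with curvature: b = -0.01, c covers the rest
  cc <- (-0.8 + 0.01 * 100) / (373^2 - 273^2)
  m2 <- ModelPotential(cmPos = 5.5, depthTQuad = c(1, -0.01, cc),
                       wallPos = 3, wallScale = 1.2)
  d2 <- modelPMF(m2, 5.5, Condition(373, 0)) - modelPMF(m2, 5.5,
                                                        Condition(273, 0))
  expect_equal(d2, -0.8, tolerance = 1e-12)
})

test_that("model PMF is smooth on the sampled domain", {
  m <- adamantanePreset()$model
  cond <- Condition(310, 1)
  x <- seq(m@wallPos + 0.5, 16, by = 1e-3)
  u <- modelPMF(m, x, cond)
  d2 <- diff(u, differences = 2) / 1e-6 # second difference ~ curvature
  expect_true(all(is.finite(d2)))
  ## curvature changes slowly between adjacent points (C2 continuity)
  expect_lt(max(abs(diff(d2))) / max(abs(d2)), 0.05)
})

test_that("bias energy follows the k(xi - d0)^2 convention", {
  w <- WindowSpec(d0 = 4, k = 2)
  expect_identical(biasEnergy(w, 4), 0)
  expect_equal(biasEnergy(w, 5), 2)
  expect_equal(biasEnergy(w, 3), 2) # symmetry about d0
  expect_equal(biasEnergy(w, 5, convention = "half_k_sq"), 1)
  expect_equal(biasEnergy(w, c(3, 4, 5)), c(2, 0, 2))
})

test_that("constructor invariants reject unphysical inputs", {
  expect_error(WindowSpec(d0 = -1, k = 2), "d0")
  expect_error(WindowSpec(d0 = 4, k = -2), "k")
  expect_error(Condition(-10, 0), "temperature")
  expect_error(Condition(298, -1), "ionicStrength")
  expect_error(ModelPotential(cmPos = 2, depthTQuad = c(0, 0, 0),
                              wallPos = 3, wallScale = 1), "wall")
})
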