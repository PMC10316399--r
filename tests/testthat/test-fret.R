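# Forward FRET engine: snapshot decay, ensemble averaging and the
# analytic uniform-plane limit.

test_that("a donor without acceptors decays mono-exponentially", {
  params <- testParams()
  pr <- probesAt(c(10, 10), matrix(numeric(), 0, 2))
  d <- donorDecaySnapshot(pr, params)
  expect_equal(d@intensity[1], 1)
  tauIdx <- which.min(abs(d@time - params@donorLifetime))
  expect_equal(d@intensity[tauIdx], exp(-1), tolerance = 1e-6)
})

test_that("one acceptor at the Forster radius doubles the decay rate", {
  params <- testParams()
  pr <- probesAt(c(10, 10), c(10 + params@forsterRadius, 10))
  d <- donorDecaySnapshot(pr, params)
  expect_equal(d@intensity,
               exp(-2 * d@time / params@donorLifetime), tolerance = 1e-10)
  e <- fretEfficiency(d, params@donorLifetime)
  expect_equal(as.numeric(e), 0.5, tolerance = 1e-4)
})

test_that("snapshot decay equals the term-by-term brute-force oracle", {
  params <- testParams()
  set.seed(11)
  pr <- probesAt(runif(6) * 40 + 30, runif(10) * 40 + 30,
                 donorLeaflet = c(0, 1, 0), acceptorLeaflet = c(0, 0, 1, 1, 0),
                 boxLength = 100, bilayerSep = 5)
  tg <- defaultTimeGrid(params, 128L)
  d <- donorDecaySnapshot(pr, params, tg)
  expect_equal(d@intensity, bruteForceDecay(pr, params, tg),
               tolerance = 1e-12)
})

test_that("pairs closer than the excluded distance are rejected", {
  params <- testParams(rMin = 1.0)
  pr <- probesAt(c(10, 10), c(10.5, 10))
  expect_error(donorDecaySnapshot(pr, params), "rMin")
})

test_that("plane decay reduces to the closed form and is linear in density", {
  params0 <- FretParameters(5.7, 1, rMin = 0)
  x <- seq(0.25, 4, by = 0.25)
  num <- -log(uniformPlaneDecay(0.005, params0, timeGrid = x)@intensity) - x
  cf <- planeQuenchExponent(0.005, 5.7, x)
  expect_lt(max(abs(num / cf - 1)), 1e-6)

  # sigma = 0 is the unquenched donor
  d0 <- uniformPlaneDecay(0, testParams(), bilayerSep = 5)
  expect_equal(d0@intensity, exp(-d0@time / 5.8), tolerance = 1e-12)

  # Poisson independence: quench exponent scales linearly with density
  params <- testParams()
  tg <- defaultTimeGrid(params, 256L)
  f1 <- uniformPlaneDecay(0.004, params, tg, bilayerSep = 5)@intensity
  f2 <- uniformPlaneDecay(0.008, params, tg, bilayerSep = 5)@intensity
  base <- exp(-tg / params@donorLifetime)
  expect_equal(log(f2 / base)[-1], 2 * log(f1 / base)[-1],
               tolerance = 1e-6)
})

test_that("ensemble decay with A = 0 matches the Poisson-plane oracle", {
  params <- testParams()
  dm <- DomainModel(1, 0, 150)
  ed <- ensembleDecay(dm, params, nRealizations = 60, seed = 31)
  sigma <- (ed@metadata$nAcceptors / 2) / 150^2
  up <- uniformPlaneDecay(sigma, params, bilayerSep = 5)
  dev <- abs(ed@intensity - up@intensity)[-1] / pmax(ed@se[-1], 1e-12)
  expect_lt(max(dev), 3)
})

test_that("ensemble decays are normalized, monotone and deterministic", {
  params <- testParams()
  dm <- DomainModel(8, 0.4, 120)
  a <- ensembleDecay(dm, params, nRealizations = 5, seed = 17)
  b <- ensembleDecay(dm, params, nRealizations = 5, seed = 17)
  expect_identical(a@intensity, b@intensity)
  expect_equal(a@intensity[1], 1)
  expect_true(all(diff(a@intensity) <= 1e-12))
})

test_that("Monte-Carlo standard error shrinks as 1/sqrt(n)", {
  params <- testParams()
  dm <- DomainModel(8, 0.4, 120)
  mid <- 100:400  # channels with appreciable signal
  # the batch-means SE estimator has ~9 df, so average the 25-vs-100
  # realization ratio over independent replicates; ideal value 0.5
  rs <- vapply(1:4, function(k) {
    e25 <- ensembleDecay(dm, params, nRealizations = 25, seed = 300 + k)
    e100 <- ensembleDecay(dm, params, nRealizations = 100, seed = 400 + k)
    mean(e100@se[mid]) / mean(e25@se[mid])
  }, numeric(1))
  gm <- exp(mean(log(rs)))
  expect_gt(gm, 0.28)
  expect_lt(gm, 0.75)
})

test_that("efficiency is zero unquenched and monotone in acceptor density", {
  params <- testParams()
  d0 <- uniformPlaneDecay(0, params, bilayerSep = 5)
  expect_equal(as.numeric(fretEfficiency(d0, params@donorLifetime)), 0,
               tolerance = 1e-4)
  es <- sapply(c(0.002, 0.004, 0.008, 0.016), function(s)
    as.numeric(fretEfficiency(uniformPlaneDecay(s, params, bilayerSep = 5),
                              params@donorLifetime)))
  expect_true(all(diff(es) > 0))
  expect_true(all(es >= 0 & es <= 1))
})

test_that("a short time grid triggers the tail-correction warning", {
  params <- testParams()
  tg <- seq(0, 3 * params@donorLifetime, length.out = 64L)
  d <- DecayCurve(tg, intensity = exp(-tg / params@donorLifetime))
  expect_warning(e <- fretEfficiency(d, params@donorLifetime), "tail")
  expect_true(attr(e, "truncated"))
  expect_equal(as.numeric(e), 0, tolerance = 1e-3)
})

test_that("doubling the box leaves the decay within Monte-Carlo error", {
  params <- testParams()
  e1 <- ensembleDecay(DomainModel(6, 0.4, 120), params,
                      nRealizations = 40, seed = 5)
  e2 <- ensembleDecay(DomainModel(6, 0.4, 240), params,
                      nRealizations = 10, seed = 6)
  se <- sqrt(e1@se^2 + e2@se^2)
  mid <- 2:512
  frac <- mean(abs(e1@intensity - e2@intensity)[mid] <= 3 * se[mid])
  expect_gt(frac, 0.99)
})

test_that("IRF convolution shifts and broadens the model decay", {
  params <- testParams()
  d <- uniformPlaneDecay(0.004, params, bilayerSep = 5)
  # delta IRF leaves the shape unchanged
  same <- convolveIRF(d, c(1))
  expect_equal(same@intensity, d@intensity / max(d@intensity),
               tolerance = 1e-12)
  # a shifted delta delays the peak by its offset
  shifted <- convolveIRF(d, c(0, 0, 0, 1))
  expect_equal(which.max(shifted@intensity), 4L)
  expect_equal(shifted@intensity[4:10], d@intensity[1:7] / max(d@intensity),
               tolerance = 1e-9)
})
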