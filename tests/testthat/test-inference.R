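# The MC-FRET inverse problem on small grids (the full-grid recovery
# experiment lives in test-acceptance.R).

# compact grid + fast fit settings shared by the tests below
tinyGrid <- function() {
  rbind(data.frame(radius_nm = 5, area = 0),
        expand.grid(radius_nm = c(5, 15, 45), area = c(0.35, 0.55)))
}
fastFit <- function(measured, seed = 77, refine = FALSE, lib = NULL,
                    grid = tinyGrid()) {
  fitGUV(measured, grid, testParams(), seed = seed, library = lib,
         refine = refine, minDonorSamples = 1e5, stage2Samples = 2e5)
}
tinyLibrary <- function(seed = 77, grid = tinyGrid()) {
  simulateDecayLibrary(grid, testParams(), defaultTimeGrid(testParams()),
                       seed = seed, minDonorSamples = 1e5)
}

makeMeasured <- function(radius, area, counts = 1e6, seed = 5,
                         samples = 4e5) {
  params <- testParams()
  L <- if (area > 0) defaultBoxLength(radius, params@forsterRadius)
       else 40 * params@forsterRadius
  model <- DomainModel(max(radius, 1), area, L)
  np <- probeCount(L)
  dec <- ensembleDecay(model, params, max(8, ceiling(samples / np)),
                       nDonors = np, nAcceptors = np, seed = seed)
  makeTCSPC(dec, counts, backgroundFraction = 0.01, seed = seed + 1)
}

lib77 <- tinyLibrary()

test_that("a decay generated at a grid node is recovered exactly", {
  measured <- makeMeasured(15, 0.55)
  fit <- fastFit(measured, lib = lib77)
  expect_equal(radiusHat(fit), 15)
  expect_equal(areaHat(fit), 0.55)
  expect_true(all(chiSurface(fit)$chisq[chiSurface(fit)$valid] >=
                    chiSquare(fit) - fit@tieTolerance - 1e-9))
})

test_that("a uniform (no-domain) decay is assigned A = 0", {
  measured <- makeMeasured(10, 0, counts = 1e6)
  fit <- fastFit(measured, lib = lib77)
  expect_lte(areaHat(fit), 0.05)
})

test_that("fits are bit-identical for identical inputs and seed", {
  measured <- makeMeasured(15, 0.55, counts = 2e5)
  a <- fastFit(measured)
  b <- fastFit(measured)
  expect_identical(chiSurface(a), chiSurface(b))
  expect_identical(radiusHat(a), radiusHat(b))
  expect_identical(chiSquare(a), chiSquare(b))
})

test_that("all-zero counts are rejected", {
  d <- DecayCurve(defaultTimeGrid(testParams()),
                  counts = rep(0, 1024))
  expect_error(fastFit(d), "all-zero")
})

test_that("the chi-square at the generating node beats the others in expectation", {
  params <- testParams()
  chis <- replicate(4, {
    measured <- makeMeasured(15, 0.55, counts = 2e5,
                             seed = sample.int(1e6, 1))
    fit <- fastFit(measured, lib = lib77)
    s <- chiSurface(fit)
    s$chisq[order(s$radius_nm, s$area)]
  })
  avg <- rowMeans(chis)
  s0 <- chiSurface(fastFit(makeMeasured(15, 0.55, counts = 2e5),
                           lib = lib77))
  node <- which(s0$radius_nm[order(s0$radius_nm, s0$area)] == 15 &
                  s0$area[order(s0$radius_nm, s0$area)] == 0.55)
  expect_equal(which.min(avg), node)
})

test_that("the chi-square surface exposes flat directions", {
  # with no domains, R is unidentifiable: the A = 0 node must not be
  # distinguishable from itself at other radii -- check the surface is
  # stored with every evaluated node so such diagnostics are possible
  measured <- makeMeasured(10, 0, counts = 2e5)
  fit <- fastFit(measured)
  s <- chiSurface(fit)
  expect_true(all(c("radius_nm", "area", "chisq", "amplitude",
                    "background", "valid") %in% names(s)))
  expect_gte(nrow(s), nrow(tinyGrid()))
})

test_that("cohort aggregation computes means and histograms", {
  mk <- function(id, r, a) new("FitResult", guvId = id, radiusHat = r,
                               areaHat = a, chiSquare = 1,
                               surface = data.frame(), seed = 1L,
                               tieTolerance = 0)
  one <- aggregateGUVs(list(mk("g1", 91, 0.45)))
  expect_equal(one@meanRadius, 91)
  expect_equal(one@meanArea, 0.45)

  two <- aggregateGUVs(list(mk("g1", 10, 0.4), mk("g2", 20, 0.5)))
  expect_equal(two@meanRadius, 15)
  expect_equal(sum(two@histRadius$count), 2)
  expect_equal(sum(two@histArea$count), 2)

  expect_error(aggregateGUVs(list()), "no fit results")
})

test_that("cohort fitting shares one library and returns one fit per decay", {
  sc <- guvScenario("tiny", 15, 0.55, relSdR = 0, sdA = 0, nGuvs = 2L,
                    counts = 2e5, seed = 9)
  coh <- makeGUVCohort(sc, testParams(), minDonorSamples = 2e5)
  fits <- fitCohort(coh$decays, tinyGrid(), testParams(), seed = 77,
                    refine = FALSE, minDonorSamples = 1e5)
  expect_length(fits, 2L)
  expect_identical(names(fits), coh$manifest$guv)
  expect_true(all(vapply(fits, function(f) areaHat(f) > 0, logical(1))))
})
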