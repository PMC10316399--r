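# Nanodomain patch geometry: disc placement, probe partitioning and the
# periodic pair metric.

test_that("zero area fraction gives an empty configuration", {
  cfg <- placeDomains(DomainModel(10, 0, 120), seed = 1)
  expect_identical(nDomains(cfg), 0L)
  expect_equal(coverageEstimate(cfg), 0)
})

test_that("disc count follows round(A L^2 / (pi R^2)) and coverage matches", {
  cfg <- placeDomains(DomainModel(100, 0.5, 2000), seed = 3)
  expect_identical(nDomains(cfg), 64L)  # round(0.5 * 2000^2 / (pi * 100^2))
  expect_lt(abs(coverageEstimate(cfg, 512) - 0.5), 0.02)
})

test_that("realized coverage tracks the requested area fraction", {
  for (A in c(0.1, 0.3, 0.45, 0.55, 0.61)) {
    cfg <- placeDomains(DomainModel(8, A, 230), seed = 7)
    expect_lt(abs(coverageEstimate(cfg, 512) - A), 0.02)
  }
})

test_that("discs never overlap under the torus metric", {
  for (seed in 1:4) {
    cfg <- placeDomains(DomainModel(5, 0.61, 120), seed = seed)
    expect_gte(nanoFRET:::minPairDistTorus(cfg@centers, 120), 10 - 1e-9)
  }
})

test_that("placement is deterministic given the seed", {
  a <- placeDomains(DomainModel(12, 0.4, 150), seed = 42)
  b <- placeDomains(DomainModel(12, 0.4, 150), seed = 42)
  expect_identical(a@centers, b@centers)
  c <- placeDomains(DomainModel(12, 0.4, 150), seed = 43)
  expect_false(identical(a@centers, c@centers))
})

test_that("model validity rejects unsupported states", {
  expect_error(DomainModel(10, 0.7, 200), "areaFraction")
  expect_error(DomainModel(10, 0.4, 50), "10 x radius")
  expect_error(DomainModel(-1, 0.4, 200), "radius")
})

test_that("probe partitioning follows K A / (K A + 1 - A)", {
  cfg <- placeDomains(DomainModel(10, 0.3, 230), seed = 5)
  Areal <- nDomains(cfg) * pi * 100 / 230^2
  for (K in c(0.1, 1, 5, 100)) {
    pr <- placeProbes(cfg, 12000, 12000, K, K, seed = K * 7 + 1)
    pExp <- partitionProbability(K, Areal)
    seBin <- sqrt(pExp * (1 - pExp) / 12000)
    expect_lt(abs(mean(pr@donorInDomain) - pExp), max(3 * seBin, 1e-12))
    expect_lt(abs(mean(pr@acceptorInDomain) - pExp), max(3 * seBin, 1e-12))
  }
})

test_that("an extreme partition coefficient puts every probe in a domain", {
  cfg <- placeDomains(DomainModel(10, 0.3, 230), seed = 5)
  pr <- placeProbes(cfg, 500, 500, 1e6, 1e6, seed = 1)
  expect_true(all(pr@donorInDomain))
  expect_true(all(pr@acceptorInDomain))
})

test_that("in-domain flags agree with the torus distance to disc centers", {
  cfg <- placeDomains(DomainModel(10, 0.3, 230), seed = 9)
  pr <- placeProbes(cfg, 400, 400, 5, 5, seed = 2)
  inDisc <- function(xy) {
    d2 <- sapply(seq_len(nDomains(cfg)), function(k) {
      dx <- abs(xy[, 1] - cfg@centers[k, 1]); dx <- pmin(dx, 230 - dx)
      dy <- abs(xy[, 2] - cfg@centers[k, 2]); dy <- pmin(dy, 230 - dy)
      dx^2 + dy^2
    })
    apply(d2, 1L, min) <= 100
  }
  expect_identical(unname(inDisc(pr@donorXY)), unname(pr@donorInDomain))
  expect_true(all(pr@donorXY >= 0 & pr@donorXY < 230))
  expect_true(all(pr@acceptorXY >= 0 & pr@acceptorXY < 230))
})

test_that("probe placement enforces the donor-acceptor excluded distance", {
  cfg <- placeDomains(DomainModel(10, 0.2, 230), seed = 3)
  pr <- placeProbes(cfg, 300, 300, 1, 1, seed = 4, rMin = 1.0)
  sameLeaf <- outer(pr@donorLeaflet, pr@acceptorLeaflet, "==")
  dx <- abs(outer(pr@donorXY[, 1], pr@acceptorXY[, 1], "-"))
  dy <- abs(outer(pr@donorXY[, 2], pr@acceptorXY[, 2], "-"))
  dx <- pmin(dx, 230 - dx); dy <- pmin(dy, 230 - dy)
  dlat <- sqrt(dx^2 + dy^2)
  expect_gte(min(dlat[sameLeaf]), 1.0)
})

test_that("pair distance uses minimum image and cross-leaflet quadrature", {
  expect_equal(pairDistance(c(5, 5), c(5, 5), 0, 0, 100), 0)
  expect_equal(pairDistance(c(0, 0), c(99, 0), 0, 0, 100), 1)
  expect_equal(pairDistance(c(7, 3), c(7, 3), 0, 1, 100, bilayerSep = 5), 5)
  expect_equal(pairDistance(c(0, 0), c(96, 0), 0, 1, 100, bilayerSep = 3),
               5)  # 3-4-5 triangle
})
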