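# Synthetic-data generators: TCSPC Poissonization and cohort/fixture
# bookkeeping.

test_that("TCSPC counts are deterministic and follow the model shape", {
  params <- testParams()
  model <- uniformPlaneDecay(0.005, params, bilayerSep = 5)
  a <- makeTCSPC(model, 1e5, seed = 4)
  b <- makeTCSPC(model, 1e5, seed = 4)
  expect_identical(a@counts, b@counts)
  c <- makeTCSPC(model, 1e5, seed = 5)
  expect_false(identical(a@counts, c@counts))

  # law of large numbers: at huge counts the histogram converges to the
  # normalized model shape (3 sigma per channel)
  big <- makeTCSPC(model, 1e8, backgroundFraction = 0, seed = 6)
  lambda <- 1e8 * model@intensity / sum(model@intensity)
  dev <- abs(big@counts - lambda) / sqrt(pmax(lambda, 1))
  expect_lt(mean(dev > 3), 0.005)
})

test_that("per-channel counts are Poisson (variance tracks the mean)", {
  params <- testParams()
  model <- uniformPlaneDecay(0.005, params, bilayerSep = 5)
  draws <- sapply(1:60, function(i) makeTCSPC(model, 2e4, seed = i)@counts)
  ch <- which(rowMeans(draws) > 5)[1:50]
  m <- rowMeans(draws[ch, ])
  v <- apply(draws[ch, ], 1L, var)
  # variance/mean ratio ~ 1 with sampling spread ~ sqrt(2/(n-1))
  ratio <- v / m
  expect_lt(abs(mean(ratio) - 1), 3 * sqrt(2 / 59) / sqrt(50) * 3 + 0.1)
})

test_that("negative background is rejected", {
  params <- testParams()
  model <- uniformPlaneDecay(0.005, params, bilayerSep = 5)
  expect_error(makeTCSPC(model, 1e4, backgroundFraction = -0.1), ">= 0")
})

test_that("cohort manifests record the generating truth", {
  sc <- guvScenario("DOPC/Chol/GSL 75/25/5", 15, 0.55, relSdR = 0,
                    sdA = 0, nGuvs = 3L, counts = 1e4, seed = 2)
  coh <- makeGUVCohort(sc, testParams(), minDonorSamples = 5e4)
  expect_identical(nrow(coh$manifest), 3L)
  expect_true(all(coh$manifest$radius_nm == 15))
  expect_true(all(coh$manifest$area == 0.55))
  expect_length(coh$decays, 3L)
  expect_true(all(vapply(coh$decays, function(d) sum(d@counts) > 0,
                         logical(1))))

  # with variability the truths spread around the scenario values
  scv <- guvScenario("v", 15, 0.55, relSdR = 0.1, sdA = 0.05, nGuvs = 6L,
                     counts = 1e4, seed = 3)
  cohv <- makeGUVCohort(scv, testParams(), minDonorSamples = 5e4)
  expect_gt(sd(cohv$manifest$radius_nm), 0)
  expect_true(all(cohv$manifest$area >= 0 & cohv$manifest$area <= 0.65))
})

test_that("cohort generation is a pure function of scenario and seed", {
  sc <- guvScenario("x", 12, 0.4, nGuvs = 2L, counts = 1e4, seed = 8)
  a <- makeGUVCohort(sc, testParams(), minDonorSamples = 5e4)
  b <- makeGUVCohort(sc, testParams(), minDonorSamples = 5e4)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$decays[[1]]@counts, b$decays[[1]]@counts)
})

test_that("membrane fixtures plant exactly the requested bonds", {
  pb <- data.frame(moietyA = "Sia3", moietyB = "Sia3", count = 4L)
  fx <- makeMembraneFixture(nGsl = 2, species = "GM1", plantedBonds = pb,
                            nWater = 5, nDecoys = 2, seed = 3)
  bonds <- detectHBonds(fx$coords, fx$topology, fx$box)
  at <- atomTable(fx$topology)
  sp <- at$species[match(bonds$donor, at$atom)]
  spa <- at$species[match(bonds$acceptor, at$atom)]
  expect_identical(sum(sp == "GM1" & spa == "GM1"), 4L)
  expect_identical(nrow(fx$truth$bonds), 4L)

  # planted bond list matches detection exactly
  key <- function(b) sort(sprintf("%d_%d", b$donor, b$acceptor))
  gg <- bonds[sp == "GM1" & spa == "GM1", ]
  expect_identical(key(gg), key(fx$truth$bonds))
})

test_that("an all-decoy fixture contains no bonds", {
  fx <- makeMembraneFixture(nGsl = 3, species = "asialoGM1", nWater = 0,
                            nDecoys = 6, seed = 4)
  expect_identical(nrow(detectHBonds(fx$coords, fx$topology, fx$box)), 0L)
})

test_that("species constrain the available moieties", {
  expect_identical(speciesMoieties("GM3"), c("Glc1", "Gal2", "Sia3"))
  expect_false("Sia3" %in% speciesMoieties("asialoGM1"))
  expect_error(speciesMoieties("GM99"), "unknown")
  expect_error(
    makeMembraneFixture(nGsl = 2, species = "asialoGM1",
                        plantedBonds = data.frame(
                          moietyA = "Sia3", moietyB = "Sia3", count = 1L),
                        seed = 1),
    "Sia3")
})

test_that("infeasible planting requests fail loudly", {
  expect_error(
    makeMembraneFixture(nGsl = 2, species = "GM3",
                        plantedBonds = data.frame(
                          moietyA = "Sia3", moietyB = "Sia3", count = 9L),
                        seed = 1),
    "infeasible")
  expect_error(
    makeMembraneFixture(nGsl = 2, species = "GM1", nWater = 1,
                        waterContacts = data.frame(moiety = "Sia3",
                                                   count = 5L),
                        seed = 1),
    "not enough waters")
})

test_that("fixture topologies are chemically consistent", {
  fx <- makeMembraneFixture(nGsl = 3, species = "GD1a", nWater = 12,
                            nDecoys = 2, seed = 5)
  at <- atomTable(fx$topology)
  qs <- tapply(at$charge, at$mol, sum)
  expect_true(all(abs(qs - round(qs)) < 1e-6))
  mm <- moietyOf(fx$moietyMap)
  expect_identical(sort(unique(unname(mm[as.character(
    at$atom[at$species == "GD1a"])]))),
    sort(c("Cer", speciesMoieties("GD1a"))))
  expect_true(validObject(fx$topology))
})
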