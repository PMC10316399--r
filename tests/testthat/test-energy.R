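# Pairwise nonbonded energies, the per-partner summary table and the
# density profile.

test_that("two opposite unit charges at 1 nm give the Coulomb constant", {
  atoms <- data.frame(atom = 1:2, element = c("N", "N"),
                      charge = c(1, -1), sigma = 0, epsilon = 0,
                      mol = 1:2, species = "other")
  topo <- Topology(atoms)
  co <- rbind(c(1, 1, 1), c(2, 1, 1))
  e <- pairInteractionEnergy(co, topo, c(10, 10, 10), 1, 2)
  expect_equal(e, -138.935458, tolerance = 1e-9)
})

test_that("group energies are symmetric and match the all-pairs oracle", {
  fx <- randomMolecularFixture(160, box = c(3.5, 3.5, 3.5), seed = 8)
  at <- atomTable(fx$topology)
  for (seed in 1:5) {
    set.seed(seed + 100)
    mols <- sample(unique(at$mol))
    ga <- at$atom[at$mol %in% mols[1:40]]
    gb <- at$atom[at$mol %in% mols[41:90]]
    eAB <- pairInteractionEnergy(fx$coords, fx$topology, fx$box, ga, gb)
    eBA <- pairInteractionEnergy(fx$coords, fx$topology, fx$box, gb, ga)
    expect_equal(eAB, eBA, tolerance = 1e-12)
    want <- bruteForceEnergy(fx$coords, fx$topology, fx$box, ga, gb)
    expect_equal(eAB, want, tolerance = 1e-10)
  }
})

test_that("overlapping atoms are rejected", {
  atoms <- data.frame(atom = 1:2, element = c("N", "N"),
                      charge = c(1, -1), sigma = 0, epsilon = 0,
                      mol = 1:2, species = "other")
  topo <- Topology(atoms)
  co <- rbind(c(1, 1, 1), c(1, 1, 1 + 1e-4))
  expect_error(pairInteractionEnergy(co, topo, c(10, 10, 10), 1, 2),
               "verlapping")
  expect_error(pairInteractionEnergy(co, topo, c(10, 10, 10), 1, 1),
               "disjoint")
})

test_that("fixture ground-truth energies equal the implementation", {
  fx <- makeMembraneFixture(nGsl = 3, species = "GD1a", nWater = 10,
                            nDecoys = 2, seed = 12)
  at <- atomTable(fx$topology)
  pe <- fx$truth$pairEnergies
  expect_gt(nrow(pe), 0)
  for (k in seq_len(nrow(pe))) {
    ga <- at$atom[at$mol == pe$molA[k]]
    gb <- at$atom[at$mol == pe$molB[k]]
    e <- pairInteractionEnergy(fx$coords, fx$topology, fx$box, ga, gb)
    expect_equal(e, pe$energy[k], tolerance = 1e-10)
  }
})

test_that("the energy summary normalizes by the partner count", {
  # ratio definition on published-scale numbers
  expect_equal(-56 / 12, -4.667, tolerance = 1e-3)

  fx <- makeMembraneFixture(nGsl = 2, species = "GM1", nWater = 6,
                            nDecoys = 0, seed = 13)
  tab <- energySummary(fx$coords, fx$topology, fx$moietyMap, fx$box)
  gg <- tab[tab$partner_class == "GSL/GSL", ]
  expect_identical(unique(tab$species), "GM1")
  # two GSLs: the single possible partner pair
  at <- atomTable(fx$topology)
  mm <- moietyOf(fx$moietyMap)
  hg1 <- at$atom[at$mol == 1 &
                   mm[as.character(at$atom)] != "Cer"]
  e12 <- pairInteractionEnergy(fx$coords, fx$topology, fx$box, hg1,
                               at$atom[at$mol == 2])
  if (gg$n_partners > 0) {
    expect_equal(gg$total_kJ_mol, e12, tolerance = 1e-10)
    expect_equal(gg$normalized_kJ_mol, gg$total_kJ_mol / gg$n_partners)
  } else {
    expect_true(is.na(gg$normalized_kJ_mol))
  }
})

test_that("a class without partners reports a missing normalized value", {
  fx <- makeMembraneFixture(nGsl = 2, species = "GM1", nWater = 0,
                            nDecoys = 0, seed = 14,
                            box = c(12, 12, 8))
  # molecules sit ~1 nm apart at closest approach: outside a 0.5 nm cutoff
  tab <- energySummary(fx$coords, fx$topology, fx$moietyMap, fx$box,
                       cutoff = 0.5)
  gg <- tab[tab$partner_class == "GSL/GSL", ]
  expect_identical(gg$n_partners, 0)
  expect_true(is.na(gg$normalized_kJ_mol))
})

test_that("percent energy change follows the magnitude convention", {
  expect_equal(percentEnergyChange(-35, -56), 60)
  expect_equal(percentEnergyChange(-35, -35), 0)
  expect_equal(percentEnergyChange(-35, -51), 45.7, tolerance = 0.05)
  expect_error(percentEnergyChange(0, -10), "nonzero")
})

test_that("uniform random atoms give a flat density profile", {
  set.seed(3)
  n <- 4000
  atoms <- data.frame(atom = 1:n, element = "C", charge = 0, sigma = 0.3,
                      epsilon = 0.3, mol = 1:n, species = "other")
  topo <- Topology(atoms)
  co <- cbind(runif(n) * 5, runif(n) * 5, runif(n) * 5)
  prof <- densityProfile(co, topo, 1:n, c(5, 5, 5), nBins = 10,
                         normalization = "none", weight = "number")
  expected <- n / 125  # atoms per nm^3
  perBin <- n / 10
  tol <- 3 * sqrt(perBin) / perBin  # 3 Poisson SE, relative
  expect_true(all(abs(prof$density / expected - 1) < tol))
})

test_that("the unnormalized profile integrates to the selection count", {
  fx <- randomMolecularFixture(50, box = c(3, 3, 3), seed = 4)
  at <- atomTable(fx$topology)
  prof <- densityProfile(fx$coords, fx$topology, at$atom, fx$box,
                         nBins = 20, normalization = "none",
                         weight = "number")
  binW <- attr(prof, "binWidth_nm")
  crossArea <- 9
  expect_equal(sum(prof$density) * binW * crossArea, nrow(at))
})

test_that("a planted Gaussian layer is recovered at the right position", {
  set.seed(9)
  n <- 2000; mu <- 3.2; sdz <- 0.4
  atoms <- data.frame(atom = 1:n, element = "O", charge = 0, sigma = 0.3,
                      epsilon = 0.3, mol = 1:n, species = "other")
  topo <- Topology(atoms)
  co <- cbind(runif(n) * 6, runif(n) * 6,
              pmin(pmax(rnorm(n, mu, sdz), 0.01), 5.99))
  prof <- densityProfile(co, topo, 1:n, c(6, 6, 6), nBins = 60)
  expect_equal(max(prof$density), 1)  # peak-normalized
  muHat <- sum(prof$center_nm * prof$density) / sum(prof$density)
  expect_lt(abs(muHat - mu), sdz / sqrt(n) * 5 + 0.05)
})

test_that("degenerate profile inputs are rejected", {
  fx <- randomMolecularFixture(5, box = c(3, 3, 3), seed = 6)
  expect_error(densityProfile(fx$coords, fx$topology, integer(),
                              fx$box), "empty")
  expect_error(densityProfile(fx$coords, fx$topology, 1:3, fx$box,
                              nBins = 5), "nBins")
})
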