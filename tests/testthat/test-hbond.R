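# Hydrogen-bond detection and the per-moiety / headgroup-water tables.

waterDimer <- function(dOO = 0.28, angleDeg = 5) {
  th <- angleDeg * pi / 180
  atoms <- data.frame(
    atom = 1:6, element = c("O", "H", "H", "O", "H", "H"),
    charge = rep(c(-0.8476, 0.4238, 0.4238), 2),
    sigma = rep(c(0.3166, 0, 0), 2), epsilon = rep(c(0.65, 0, 0), 2),
    mol = rep(1:2, each = 3), species = "water")
  coords <- rbind(
    c(1, 1, 1),                                    # donor O
    c(1 + 0.096 * cos(th), 1 + 0.096 * sin(th), 1),# donating H
    c(1 - 0.07, 1 - 0.06, 1),                      # other H
    c(1 + dOO, 1, 1),                              # acceptor O
    c(1 + dOO + 0.09, 1 + 0.03, 1),                # acceptor H (points away)
    c(1 + dOO + 0.02, 1 - 0.094, 1))
  list(coords = coords, box = c(4, 4, 4),
       topology = Topology(atoms, rbind(c(1, 2), c(1, 3), c(4, 5), c(4, 6))))
}

test_that("an ideal water dimer has exactly one hydrogen bond", {
  d <- waterDimer()
  b <- detectHBonds(d$coords, d$topology, d$box)
  expect_identical(nrow(b), 1L)
  expect_identical(b$donor, 1L)
  expect_identical(b$acceptor, 4L)
})

test_that("a stretched dimer beyond the cutoff has no bond", {
  d <- waterDimer(dOO = 0.40)
  expect_identical(nrow(detectHBonds(d$coords, d$topology, d$box)), 0L)
})

test_that("the angle criterion rejects bent geometries", {
  d <- waterDimer(angleDeg = 45)
  expect_identical(nrow(detectHBonds(d$coords, d$topology, d$box)), 0L)
  crit <- HBondCriterion(maxAngle = 50)
  expect_identical(nrow(detectHBonds(d$coords, d$topology, d$box, crit)),
                   1L)
})

test_that("cell-list detection matches the all-pairs oracle", {
  for (seed in 1:5) {
    n <- sample(100:320, 1)  # up to ~1000 atoms
    fx <- randomMolecularFixture(n, box = c(4, 4, 4), seed = seed)
    crit <- HBondCriterion()
    got <- detectHBonds(fx$coords, fx$topology, fx$box, crit)
    want <- bruteForceHBonds(fx$coords, fx$topology, fx$box, crit)
    key <- function(b) sort(sprintf("%d_%d_%d", b$donor, b$hydrogen,
                                    b$acceptor))
    expect_identical(key(got), key(want))
  }
})

test_that("periodic images are honoured in detection", {
  d <- waterDimer()
  # translate the dimer so the bond spans the periodic boundary
  co <- d$coords
  co[, 1] <- (co[, 1] + 2.96) %% 4
  b <- detectHBonds(co, d$topology, d$box)
  expect_identical(nrow(b), 1L)
  expect_identical(b$donor, 1L)
})

test_that("explicit donors without hydrogens raise a named error", {
  d <- waterDimer()
  expect_error(detectHBonds(d$coords, d$topology, d$box, donors = 4:5),
               "5")
  expect_silent(detectHBonds(d$coords, d$topology, d$box, donors = 4L))
})

test_that("planted-fixture bookkeeping is reproduced exactly", {
  pb <- data.frame(moietyA = "Sia3", moietyB = "Sia3", count = 4L)
  fx <- makeMembraneFixture(nGsl = 2, species = "GM1", plantedBonds = pb,
                            nWater = 6, nDecoys = 3, seed = 21)
  tab <- moietyHBondTable(fx$coords, fx$topology, fx$moietyMap, fx$box)
  sia3 <- tab$mean_bonds_per_molecule[tab$moiety == "Sia3"]
  expect_equal(sia3, 4 / 2)  # 4 bonds over 2 molecules, counted per bond
  expect_equal(tab$mean_bonds_per_molecule[tab$moiety == "total"], 2)
  others <- tab$mean_bonds_per_molecule[!tab$moiety %in%
                                          c("Sia3", "total")]
  expect_true(all(others == 0))
})

test_that("mixed-moiety bonds count once at each end", {
  pb <- data.frame(moietyA = "Sia3", moietyB = "Gal2", count = 2L)
  fx <- makeMembraneFixture(nGsl = 3, species = "GM1", plantedBonds = pb,
                            nWater = 0, nDecoys = 0, seed = 22)
  tab <- moietyHBondTable(fx$coords, fx$topology, fx$moietyMap, fx$box)
  get <- function(m) tab$mean_bonds_per_molecule[tab$moiety == m]
  expect_equal(get("Sia3"), 2 / 3)
  expect_equal(get("Gal2"), 2 / 3)
  expect_equal(get("total"), get("Sia3") + get("Gal2"))
})

test_that("decoys near the cutoff contribute nothing", {
  fx <- makeMembraneFixture(nGsl = 3, species = "GM1",
                            nWater = 0, nDecoys = 5, seed = 23)
  expect_gt(fx$truth$nDecoys, 0)
  tab <- moietyHBondTable(fx$coords, fx$topology, fx$moietyMap, fx$box)
  expect_true(all(tab$mean_bonds_per_molecule == 0))
})

test_that("headgroup-water counts and Sia fractions match planted truth", {
  wc <- data.frame(moiety = c("Sia3", "Gal5"), count = c(3L, 2L))
  fx <- makeMembraneFixture(nGsl = 2, species = "GM1", nWater = 8,
                            nDecoys = 0, waterContacts = wc, seed = 24)
  wt <- headgroupWaterHBonds(fx$coords, fx$topology, fx$moietyMap, fx$box)
  hg <- wt$bonds_per_gsl[wt$group == "headgroup"]
  sia <- wt$bonds_per_gsl[wt$group == "Sia3"]
  expect_equal(hg, 5 / 2)
  expect_equal(sia, 3 / 2)
  expect_equal(wt$sia_fraction_pct[wt$group == "Sia3"],
               round(100 * (3 / 2) / (5 / 2), 1))
})

test_that("isolated mode restricts the count to one designated molecule", {
  wc <- data.frame(moiety = "Sia3", count = 2L)
  fx <- makeMembraneFixture(nGsl = 2, species = "GM1", nWater = 4,
                            nDecoys = 0, waterContacts = wc, seed = 25)
  # contacts alternate molecules 1, 2 -> one each
  w1 <- headgroupWaterHBonds(fx$coords, fx$topology, fx$moietyMap, fx$box,
                             mode = "isolated", isolatedMol = 1)
  expect_equal(w1$bonds_per_gsl[w1$group == "headgroup"], 1)
  expect_error(
    headgroupWaterHBonds(fx$coords, fx$topology, fx$moietyMap, fx$box,
                         mode = "isolated"),
    "designated")
})

test_that("a waterless fixture reports zero counts and missing fractions", {
  fx <- makeMembraneFixture(nGsl = 2, species = "GM1", nWater = 0,
                            nDecoys = 0, seed = 26)
  wt <- headgroupWaterHBonds(fx$coords, fx$topology, fx$moietyMap, fx$box)
  expect_true(all(wt$bonds_per_gsl == 0))
  expect_true(all(is.na(wt$sia_fraction_pct)))
})

test_that("block standard errors shrink with longer trajectories", {
  # stationary synthetic trajectory: the planted bond count per frame is
  # an iid draw, so the block SE should shrink with trajectory length
  mkframes <- function(n) lapply(1:n, function(i) {
    set.seed(400 + i)
    cnt <- 1L + rbinom(1, 3, 0.5)
    fx <- makeMembraneFixture(
      nGsl = 2, species = "GM1",
      plantedBonds = data.frame(moietyA = "Sia3", moietyB = "Sia3",
                                count = cnt),
      nWater = 0, nDecoys = 0, seed = 31)
    fx$coords
  })
  fx0 <- makeMembraneFixture(nGsl = 2, species = "GM1",
                             plantedBonds = data.frame(
                               moietyA = "Sia3", moietyB = "Sia3",
                               count = 2L),
                             nWater = 0, nDecoys = 0, seed = 31)
  t10 <- moietyHBondTable(mkframes(10), fx0$topology, fx0$moietyMap,
                          fx0$box, blockCount = 5L)
  t40 <- moietyHBondTable(mkframes(40), fx0$topology, fx0$moietyMap,
                          fx0$box, blockCount = 5L)
  se10 <- t10$se[t10$moiety == "Sia3"]
  se40 <- t40$se[t40$moiety == "Sia3"]
  expect_lt(se40, se10)
})

test_that("the Sia fraction helper reproduces the published arithmetic", {
  expect_equal(siaWaterFraction(12.2, 32.6), 37.4)
  expect_equal(siaWaterFraction(12.6, 43.5), 29.0)
  expect_true(is.na(siaWaterFraction(1, 0)))
})
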