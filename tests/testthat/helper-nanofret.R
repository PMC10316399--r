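# Shared fixtures and independent oracles for the test suite.

# FRET pair used throughout the tests: an R0/tauD combination typical of
# green/orange Bodipy-type membrane probes.
testParams <- function(rMin = 1.0) FretParameters(5.7, 5.8, rMin = rMin)

# a ProbeConfiguration from literal coordinates (bypasses placement)
probesAt <- function(donorXY, acceptorXY, donorLeaflet = NULL,
                     acceptorLeaflet = NULL, boxLength = 100,
                     bilayerSep = 5) {
  donorXY <- matrix(donorXY, ncol = 2, byrow = TRUE)
  acceptorXY <- matrix(acceptorXY, ncol = 2, byrow = TRUE)
  if (is.null(donorLeaflet)) donorLeaflet <- rep(0L, nrow(donorXY))
  if (is.null(acceptorLeaflet)) acceptorLeaflet <- rep(0L, nrow(acceptorXY))
  new("ProbeConfiguration",
      donorXY = donorXY, donorLeaflet = as.integer(donorLeaflet),
      donorInDomain = rep(FALSE, nrow(donorXY)),
      acceptorXY = acceptorXY,
      acceptorLeaflet = as.integer(acceptorLeaflet),
      acceptorInDomain = rep(FALSE, nrow(acceptorXY)),
      boxLength = boxLength, bilayerSep = bilayerSep)
}

# brute-force donor decay oracle: plain double loop over all pairs in R
bruteForceDecay <- function(probes, params, timeGrid) {
  nD <- nrow(probes@donorXY)
  f <- numeric(length(timeGrid))
  for (i in seq_len(nD)) {
    s <- 0
    for (j in seq_len(nrow(probes@acceptorXY))) {
      r <- pairDistance(probes@donorXY[i, ], probes@acceptorXY[j, ],
                        probes@donorLeaflet[i], probes@acceptorLeaflet[j],
                        probes@boxLength, probes@bilayerSep)
      s <- s + (params@forsterRadius / r)^6
    }
    f <- f + exp(-(timeGrid / params@donorLifetime) * (1 + s))
  }
  f / nD
}

# brute-force hydrogen-bond oracle: all donor-H x acceptor triples in R
bruteForceHBonds <- function(coords, topology, box, criterion,
                             excludeIntra = TRUE) {
  at <- atomTable(topology)
  bd <- bondTable(topology)
  e <- setNames(at$element, at$atom)
  mol <- setNames(at$mol, at$atom)
  pos <- function(id) coords[match(id, at$atom), ]
  dh <- rbind(bd[e[as.character(bd[, 2])] == "H", , drop = FALSE],
              bd[e[as.character(bd[, 1])] == "H", 2:1, drop = FALSE])
  dh <- dh[e[as.character(dh[, 1])] %in% criterion@donorElements, ,
           drop = FALSE]
  acc <- at$atom[at$element %in% criterion@acceptorElements]
  mic <- function(v) v - box * round(v / ifelse(box > 0, box, Inf))
  hits <- list()
  for (p in seq_len(nrow(dh))) {
    d <- dh[p, 1]; h <- dh[p, 2]
    vh <- mic(pos(h) - pos(d))
    for (a in acc) {
      if (a == d || a == h) next
      if (excludeIntra && mol[as.character(a)] == mol[as.character(d)])
        next
      va <- mic(pos(a) - pos(d))
      ra <- sqrt(sum(va^2))
      if (ra > criterion@maxDist || ra < 1e-6) next
      cosang <- sum(vh * va) / (sqrt(sum(vh^2)) * ra)
      if (cosang >= cos(criterion@maxAngle * pi / 180))
        hits[[length(hits) + 1L]] <- c(d, h, a)
    }
  }
  if (!length(hits))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  m <- do.call(rbind, hits)
  data.frame(donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3])
}

# brute-force nonbonded energy oracle in R
bruteForceEnergy <- function(coords, topology, box, groupA, groupB,
                             cutoff = 1.2) {
  at <- atomTable(topology)
  fke <- 138.935458
  e <- 0
  for (a in match(groupA, at$atom)) {
    for (b in match(groupB, at$atom)) {
      d <- coords[a, ] - coords[b, ]
      d <- d - box * round(d / ifelse(box > 0, box, Inf))
      r <- sqrt(sum(d^2))
      if (r > cutoff) next
      sij <- (at$sigma[a] + at$sigma[b]) / 2
      eij <- sqrt(at$epsilon[a] * at$epsilon[b])
      sr6 <- (sij / r)^6
      e <- e + fke * at$charge[a] * at$charge[b] / r +
        4 * eij * (sr6^2 - sr6)
    }
  }
  e
}

# random "molecular" fixture for oracle-equivalence tests: nMol small
# water-like molecules at random positions (no planted structure)
randomMolecularFixture <- function(nMol, box, seed) {
  set.seed(seed)
  rows <- list(); bonds <- list()
  for (m in seq_len(nMol)) {
    o <- runif(3) * (box - 0.2) + 0.1
    ids <- (m - 1L) * 3L + 1:3
    # random orientation of the two hydrogens
    u <- rnorm(3); u <- 0.096 * u / sqrt(sum(u^2))
    v <- rnorm(3); v <- 0.096 * v / sqrt(sum(v^2))
    rows[[m]] <- data.frame(
      atom = ids, element = c("O", "H", "H"),
      charge = c(-0.8476, 0.4238, 0.4238),
      sigma = c(0.3166, 0, 0), epsilon = c(0.65, 0, 0),
      mol = m, species = "water",
      x = o[1] + c(0, u[1], v[1]), y = o[2] + c(0, u[2], v[2]),
      z = o[3] + c(0, u[3], v[3]))
    bonds[[m]] <- rbind(ids[1:2], ids[c(1, 3)])
  }
  atoms <- do.call(rbind, rows)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  list(coords = coords, box = box,
       topology = Topology(atoms[, 1:7], do.call(rbind, bonds)))
}

refTablePath <- function(name) {
  system.file("extdata", name, package = "nanoFRET", mustWork = TRUE)
}
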