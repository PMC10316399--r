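## Synthetic-data generators: Poisson TCSPC decay cohorts emulating the
## per-vesicle FRET experiments, and small membrane coordinate fixtures
## with planted hydrogen bonds and analytically known pair energies.

#' Cohort scenario description
#'
#' Bundles the generating conditions of one lipid-composition cohort:
#' the generating nanodomain state (R, A), the vesicle-to-vesicle spread,
#' cohort size and per-decay photon counts.
#'
#' @param label composition string (e.g. \code{"DOPC/Chol/GSL 75/25/5"}).
#' @param radius generating nanodomain radius (nm; ignored when
#'   \code{area = 0}).
#' @param area generating domain area fraction.
#' @param relSdR relative vesicle-to-vesicle SD on the radius.
#' @param sdA absolute vesicle-to-vesicle SD on the area fraction
#'   (truncated at the \code{[0, 0.65]} bounds).
#' @param nGuvs cohort size (the experiments imaged 5-10 vesicles per
#'   composition).
#' @param counts total photon counts per decay.
#' @param backgroundFraction uniform background fraction of total counts.
#' @param seed integer cohort seed.
#' @return A list of class \code{"guvScenario"}.
#' @export
guvScenario <- function(label, radius, area, relSdR = 0.10, sdA = 0.05,
                        nGuvs = 8L, counts = 1e5,
                        backgroundFraction = 0.01, seed = 1L) {
  stopifnot(nGuvs >= 1, counts > 0, relSdR >= 0, sdA >= 0)
  structure(list(label = label, radius = radius, area = area,
                 relSdR = relSdR, sdA = sdA, nGuvs = as.integer(nGuvs),
                 counts = counts, backgroundFraction = backgroundFraction,
                 seed = as.integer(seed)),
            class = "guvScenario")
}

#' Poissonized TCSPC histogram from a model decay
#'
#' Expected counts per channel are proportional to the model intensity plus
#' a uniform background, scaled so the expectation totals
#' \code{totalCounts}; channel counts are drawn independently Poisson.
#'
#' @param modelDecay normalized \code{\link{DecayCurve}} (intensity).
#' @param totalCounts expected total photon count (>= 1).
#' @param backgroundFraction fraction of counts in the uniform background.
#' @param seed integer seed (deterministic draw).
#' @return A \code{\link{DecayCurve}} with counts (model expectation kept
#'   in the metadata).
#' @export
makeTCSPC <- function(modelDecay, totalCounts, backgroundFraction = 0,
                      seed = 1L) {
  stopifnot(is(modelDecay, "DecayCurve"), length(modelDecay@intensity) > 0,
            totalCounts >= 1)
  if (backgroundFraction < 0) stop("backgroundFraction must be >= 0")
  f <- modelDecay@intensity
  n <- length(f)
  lambda <- (1 - backgroundFraction) * totalCounts * f / sum(f) +
    backgroundFraction * totalCounts / n
  set.seed(expandSeed(seed, 23L))
  counts <- rpois(n, lambda)
  DecayCurve(modelDecay@time, counts = counts,
             metadata = c(modelDecay@metadata,
                          list(totalCounts = totalCounts,
                               backgroundFraction = backgroundFraction,
                               expected = lambda, kind = "tcspc")))
}

#' Generate a synthetic vesicle cohort with ground-truth manifest
#'
#' Each vesicle's generating (R, A) is the scenario value jittered by the
#' stated vesicle-to-vesicle variability; its decay is the Monte-Carlo
#' ensemble forward model at that state, Poissonized to the scenario's
#' photon count. The manifest records the per-vesicle truth so recovery
#' can be scored without re-reading generator internals.
#'
#' @param scenario a \code{\link{guvScenario}}.
#' @param params a \code{\link{FretParameters}}.
#' @param nRealizations minimum forward-model realizations per vesicle.
#' @param minDonorSamples target total donor count per vesicle decay; a
#'   real vesicle's decay is self-averaged over a membrane area far larger
#'   than the simulation box, so realizations are added until the target
#'   is met.
#' @param bilayerSep,partitionDonor,partitionAcceptor,probeDensity
#'   membrane/probe settings (see \code{\link{DomainModel}}).
#' @param timeGrid time grid (ns).
#' @return List with \code{decays} (named list of count
#'   \code{\link{DecayCurve}}s) and \code{manifest} (data.frame with the
#'   per-vesicle generating truth).
#' @export
makeGUVCohort <- function(scenario, params, nRealizations = 8L,
                          bilayerSep = 5.0, partitionDonor = 5.0,
                          partitionAcceptor = 5.0,
                          probeDensity = .DEFAULT_PROBE_DENSITY,
                          timeGrid = defaultTimeGrid(params),
                          minDonorSamples = 1e6) {
  stopifnot(inherits(scenario, "guvScenario"), is(params, "FretParameters"))
  set.seed(expandSeed(scenario$seed, 31L))
  n <- scenario$nGuvs
  rTrue <- scenario$radius * (1 + scenario$relSdR * rnorm(n))
  rTrue <- pmax(rTrue, 1)
  aTrue <- pmin(pmax(scenario$area + scenario$sdA * rnorm(n), 0),
                .MAX_AREA_FRACTION)
  if (scenario$area == 0) aTrue[] <- 0
  decays <- vector("list", n)
  ids <- sprintf("guv%02d", seq_len(n))
  for (i in seq_len(n)) {
    L <- if (aTrue[i] > 0) defaultBoxLength(rTrue[i], params@forsterRadius)
         else 40 * params@forsterRadius
    model <- DomainModel(radius = max(rTrue[i], 1e-6),
                         areaFraction = aTrue[i], boxLength = L,
                         bilayerSep = bilayerSep,
                         partitionDonor = partitionDonor,
                         partitionAcceptor = partitionAcceptor)
    np <- probeCount(L, probeDensity)
    nr <- max(nRealizations, ceiling(minDonorSamples / np))
    dec <- ensembleDecay(model, params, nr, nDonors = np,
                         nAcceptors = np,
                         seed = expandSeed(scenario$seed, 41L, i),
                         timeGrid = timeGrid)
    decays[[i]] <- makeTCSPC(dec, scenario$counts,
                             scenario$backgroundFraction,
                             seed = expandSeed(scenario$seed, 43L, i))
  }
  names(decays) <- ids
  manifest <- data.frame(guv = ids, label = scenario$label,
                         radius_nm = rTrue, area = aTrue,
                         counts = scenario$counts,
                         background_fraction = scenario$backgroundFraction,
                         seed = scenario$seed)
  list(decays = decays, manifest = manifest)
}

## ---------------------------------------------------------------------
## Membrane coordinate fixtures with planted hydrogen bonds.

## Moieties carried by each supported GSL species, innermost first.
.SPECIES_MOIETIES <- list(
  GD1a       = c("Glc1", "Gal2", "Sia3", "GalNAc4", "Gal5", "Sia6"),
  GM1        = c("Glc1", "Gal2", "Sia3", "GalNAc4", "Gal5"),
  GM3        = c("Glc1", "Gal2", "Sia3"),
  asialoGM1  = c("Glc1", "Gal2", "GalNAc4", "Gal5")
)

## Hydroxyl sites per pseudo-sugar moiety (sugars carry 3-4 OH groups;
## four sites also give planted-bond bookkeeping room).
.OH_PER_MOIETY <- 4L

#' Moieties of a supported glycosphingolipid species
#'
#' @param species one of \code{"GD1a"}, \code{"GM1"}, \code{"GM3"},
#'   \code{"asialoGM1"}.
#' @return Character vector of sugar moiety labels (innermost first).
#' @export
speciesMoieties <- function(species) {
  m <- .SPECIES_MOIETIES[[species]]
  if (is.null(m)) stop("unknown GSL species: ", species)
  m
}

## One pseudo-GSL molecule: per moiety one backbone carbon plus
## .OH_PER_MOIETY hydroxyl (O-H) sites in a row; moieties stacked along z.
## Geometry keeps all intra- and inter-moiety O...O contacts outside the
## default hydrogen-bond criterion (0.30 nm spacing but 90-degree angles;
## 0.35 nm vertical spacing at 90 degrees).
.buildGSL <- function(species, molId, origin, atomStart) {
  moieties <- c("Cer", speciesMoieties(species))
  atoms <- list(); bonds <- list(); moiety <- list()
  id <- atomStart
  for (k in seq_along(moieties)) {
    base <- origin + c(0, 0, 0.35 * (k - 1))
    cId <- id; id <- id + 1L
    rows <- data.frame(atom = cId, element = "C", charge = 0.4,
                       sigma = 0.34, epsilon = 0.36, mol = molId,
                       species = species,
                       x = base[1], y = base[2], z = base[3])
    for (u in seq_len(.OH_PER_MOIETY)) {
      oId <- id; hId <- id + 1L; id <- id + 2L
      ox <- base[1] + 0.14 + 0.30 * (u - 1)
      rows <- rbind(rows, data.frame(
        atom = c(oId, hId), element = c("O", "H"),
        charge = c(-0.4, 0.3), sigma = c(0.30, 0), epsilon = c(0.65, 0),
        mol = molId, species = species,
        x = c(ox, ox), y = c(base[2], base[2] + 0.096),
        z = base[3]))
      bonds[[length(bonds) + 1L]] <- rbind(c(cId, oId), c(oId, hId))
    }
    atoms[[k]] <- rows
    moiety[[k]] <- data.frame(atom = rows$atom, moiety = moieties[k])
  }
  list(atoms = do.call(rbind, atoms), bonds = do.call(rbind, bonds),
       moiety = do.call(rbind, moiety), nextAtom = id)
}

#' Build a membrane coordinate fixture with planted hydrogen bonds
#'
#' Constructs a small, fully synthetic membrane-like configuration:
#' \code{nGsl} pseudo-GSL molecules of one species on a lateral grid, water
#' molecules, a consistent topology (charges, Lennard-Jones parameters,
#' bonds) and moiety map. Requested intermolecular GSL-GSL hydrogen bonds
#' are planted at ideal geometry (O-O 0.28 nm, 5-degree angle), decoy
#' O...O contacts sit at 0.40 nm (beyond the default 0.35 nm cutoff), and
#' optional headgroup-water contacts are planted the same way. The ground
#' truth lists every planted bond and the analytic Coulomb+Lennard-Jones
#' energy of every molecule pair with any atom pair inside the cutoff.
#'
#' @param nGsl number of GSL molecules (>= 2 when bonds are planted).
#' @param species GSL species (see \code{\link{speciesMoieties}}).
#' @param plantedBonds data.frame with columns \code{moietyA},
#'   \code{moietyB}, \code{count}: intermolecular bonds to plant.
#' @param nWater number of water molecules.
#' @param box numeric length-3 box vector (nm).
#' @param nDecoys number of decoy donor-acceptor contacts beyond the
#'   distance cutoff.
#' @param waterContacts data.frame with columns \code{moiety},
#'   \code{count}: headgroup-water bonds to plant (optional).
#' @param seed integer seed.
#' @param energyCutoff cutoff (nm) used for the ground-truth energies.
#' @return List with \code{coords} (n x 3 matrix, nm), \code{box},
#'   \code{topology} (\code{\link{Topology}}), \code{moietyMap}
#'   (\code{\link{MoietyMap}}), and \code{truth} (planted bonds, planted
#'   water bonds, decoy count, per-molecule-pair analytic energies).
#' @export
makeMembraneFixture <- function(nGsl = 4L, species = "GM1",
                                plantedBonds = data.frame(
                                  moietyA = character(),
                                  moietyB = character(),
                                  count = integer()),
                                nWater = 20L,
                                box = c(8, 8, 8), nDecoys = 4L,
                                waterContacts = NULL,
                                seed = 1L, energyCutoff = 1.2) {
  set.seed(expandSeed(seed, 51L))
  moieties <- speciesMoieties(species)
  if (nrow(plantedBonds)) {
    bad <- setdiff(unique(c(plantedBonds$moietyA, plantedBonds$moietyB)),
                   moieties)
    if (length(bad))
      stop("planted bond moieties not on species ", species, ": ",
           paste(bad, collapse = ", "))
    if (nGsl < 2L) stop("planting intermolecular bonds needs >= 2 GSLs")
  }

  atoms <- list(); bonds <- list(); moiety <- list()
  nextAtom <- 1L
  perRow <- ceiling(sqrt(nGsl))
  if (2 * perRow > box[1] || 2 * perRow > box[2])
    stop("box too small to pack ", nGsl, " GSL molecules")
  for (m in seq_len(nGsl)) {
    gx <- ((m - 1) %% perRow) * 2 + 0.3
    gy <- ((m - 1) %/% perRow) * 2 + 0.5
    g <- .buildGSL(species, m, c(gx, gy, 0.5), nextAtom)
    atoms[[m]] <- g$atoms; bonds[[m]] <- g$bonds; moiety[[m]] <- g$moiety
    nextAtom <- g$nextAtom
  }
  atoms <- do.call(rbind, atoms)
  bonds <- do.call(rbind, bonds)
  moiety <- do.call(rbind, moiety)

  usedO <- integer()
  freeO <- function(mol, moi) {
    ids <- intersect(moiety$atom[moiety$moiety == moi],
                     atoms$atom[atoms$mol == mol & atoms$element == "O"])
    setdiff(ids, usedO)
  }
  hOf <- function(oid) {
    cand <- c(bonds[bonds[, 1] == oid, 2], bonds[bonds[, 2] == oid, 1])
    cand[atoms$element[match(cand, atoms$atom)] == "H"]
  }
  setPos <- function(id, xyz) {
    i <- match(id, atoms$atom)
    atoms$x[i] <<- xyz[1]; atoms$y[i] <<- xyz[2]; atoms$z[i] <<- xyz[3]
  }
  getPos <- function(id) {
    i <- match(id, atoms$atom)
    c(atoms$x[i], atoms$y[i], atoms$z[i])
  }
  zMol <- max(atoms$z)  # molecular slab extent before any relocation

  ## ideal planted geometry in a reserved slab at the top of the box:
  ## donor O at the site, its H 5 degrees off the O...O axis, acceptor O
  ## 0.28 nm along +x; the acceptor's own H points away (180 degrees).
  placePair <- function(dO, aO, siteIdx, yOff) {
    base <- c(0.6 + ((siteIdx - 1) %% 6) * 1.2, yOff,
              box[3] - 0.4 - 0.45 * ((siteIdx - 1) %/% 6))
    if (base[3] <= zMol + 0.35 ||
        (nWater > 0 && base[3] <= box[3] - 2.2 + 0.35))
      stop("planted-bond slab collides with molecules or water: box too small")
    th <- 5 * pi / 180
    setPos(dO, base)
    setPos(hOf(dO)[1], base + 0.096 * c(cos(th), sin(th), 0))
    setPos(aO, base + c(0.28, 0, 0))
    setPos(hOf(aO)[1], base + c(0.28 + 0.096, 0, 0))
  }

  truthBonds <- list()
  siteIdx <- 0L
  if (nrow(plantedBonds)) {
    pairPool <- utils::combn(nGsl, 2)
    k <- 0L
    for (r in seq_len(nrow(plantedBonds))) {
      for (cnt in seq_len(plantedBonds$count[r])) {
        pr <- pairPool[, (k %% ncol(pairPool)) + 1L]
        if (k %% 2L == 1L) pr <- rev(pr)  # alternate donor direction
        k <- k + 1L
        dOs <- freeO(pr[1], plantedBonds$moietyA[r])
        aOs <- freeO(pr[2], plantedBonds$moietyB[r])
        if (!length(dOs) || !length(aOs))
          stop("planted bonds infeasible: hydroxyl sites of ",
               plantedBonds$moietyA[r], "/", plantedBonds$moietyB[r],
               " exhausted")
        siteIdx <- siteIdx + 1L
        placePair(dOs[1], aOs[1], siteIdx, yOff = 0.3)
        usedO <- c(usedO, dOs[1], aOs[1])
        truthBonds[[length(truthBonds) + 1L]] <- data.frame(
          donor = dOs[1], hydrogen = hOf(dOs[1])[1], acceptor = aOs[1],
          molDonor = pr[1], molAcceptor = pr[2],
          moietyDonor = plantedBonds$moietyA[r],
          moietyAcceptor = plantedBonds$moietyB[r])
      }
    }
  }

  ## decoys: same slab construction, O...O stretched to 0.40 nm
  decoys <- 0L
  if (nDecoys > 0 && nGsl >= 2) {
    pairPool <- utils::combn(nGsl, 2)
    for (dcy in seq_len(nDecoys)) {
      pr <- pairPool[, ((dcy - 1L) %% ncol(pairPool)) + 1L]
      mois <- sample(moieties, 2L, replace = TRUE)
      dOs <- freeO(pr[1], mois[1]); aOs <- freeO(pr[2], mois[2])
      if (!length(dOs) || !length(aOs)) next
      base <- c(0.6 + ((dcy - 1) %% 6) * 1.2, box[2] - 0.3,
                box[3] - 0.4 - 0.45 * ((dcy - 1) %/% 6))
      setPos(dOs[1], base)
      setPos(hOf(dOs[1])[1], base + c(0.096, 0, 0))
      setPos(aOs[1], base + c(0.40, 0, 0))
      setPos(hOf(aOs[1])[1], base + c(0.40 + 0.096, 0, 0))
      usedO <- c(usedO, dOs[1], aOs[1])
      decoys <- decoys + 1L
    }
  }

  ## waters scattered in a slab clear of everything planted
  if (nWater > 0) {
    if (box[3] - 2.2 <= zMol + 0.8)
      stop("box too small for a water slab above the molecules")
    waterRows <- vector("list", nWater)
    for (w in seq_len(nWater)) {
      molId <- nGsl + w
      o <- c(runif(1, 0.3, box[1] - 0.3), runif(1, 0.5, box[2] - 0.5),
             runif(1, zMol + 0.8, box[3] - 2.2))
      ids <- nextAtom + 0:2
      waterRows[[w]] <- data.frame(
        atom = ids, element = c("O", "H", "H"),
        charge = c(-0.8476, 0.4238, 0.4238),
        sigma = c(0.3166, 0, 0), epsilon = c(0.650, 0, 0),
        mol = molId, species = "water",
        x = o[1] + c(0, 0.096, -0.024), y = o[2] + c(0, 0, 0.093),
        z = o[3])
      bonds <- rbind(bonds, c(ids[1], ids[2]), c(ids[1], ids[3]))
      moiety <- rbind(moiety, data.frame(atom = ids, moiety = "water"))
      nextAtom <- nextAtom + 3L
    }
    atoms <- rbind(atoms, do.call(rbind, waterRows))
  }

  ## planted headgroup-water contacts: the water O donates to an unused
  ## hydroxyl O along -y, so the hydroxyl's own +y hydrogen cannot form
  ## the reverse bond
  truthWater <- list()
  if (!is.null(waterContacts) && nrow(waterContacts)) {
    if (nWater < sum(waterContacts$count))
      stop("not enough waters to plant the requested contacts")
    wIdx <- 0L
    for (r in seq_len(nrow(waterContacts))) {
      for (cnt in seq_len(waterContacts$count[r])) {
        wIdx <- wIdx + 1L
        mol <- ((wIdx - 1L) %% nGsl) + 1L
        gOs <- freeO(mol, waterContacts$moiety[r])
        if (!length(gOs))
          stop("planted water contacts infeasible: hydroxyl sites of ",
               waterContacts$moiety[r], " exhausted on molecule ", mol)
        gO <- gOs[1]
        usedO <- c(usedO, gO)
        wMol <- nGsl + wIdx
        wO <- atoms$atom[atoms$mol == wMol & atoms$element == "O"]
        wH <- atoms$atom[atoms$mol == wMol & atoms$element == "H"]
        gPos <- getPos(gO)
        setPos(wO, gPos + c(0, -0.28, 0))
        setPos(wH[1], gPos + c(0, -0.28 + 0.096, 0))
        setPos(wH[2], gPos + c(0.093, -0.304, 0))
        truthWater[[length(truthWater) + 1L]] <- data.frame(
          donor = wO, hydrogen = wH[1], acceptor = gO,
          molDonor = wMol, molAcceptor = mol,
          moietyDonor = "water", moietyAcceptor = waterContacts$moiety[r])
      }
    }
  }

  coords <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(coords) <- atoms$atom
  topo <- Topology(atoms[, c("atom", "element", "charge", "sigma",
                             "epsilon", "mol", "species")], bonds)
  mmap <- MoietyMap(moiety$atom, moiety$moiety)

  truth <- list(
    bonds = if (length(truthBonds)) do.call(rbind, truthBonds)
            else data.frame(),
    waterBonds = if (length(truthWater)) do.call(rbind, truthWater)
                 else data.frame(),
    nDecoys = decoys,
    pairEnergies = .truthPairEnergies(coords, box, topo, energyCutoff))

  list(coords = coords, box = box, topology = topo, moietyMap = mmap,
       truth = truth)
}

## Analytic per-molecule-pair energies computed directly in R (plain
## formula, no neighbor structures) as the fixture's ground truth.
.truthPairEnergies <- function(coords, box, topology, cutoff) {
  at <- atomTable(topology)
  fke <- 138.935458
  mols <- sort(unique(at$mol))
  out <- list()
  for (i in seq_along(mols)) {
    for (j in seq_len(i - 1L)) {
      ia <- which(at$mol == mols[i]); ib <- which(at$mol == mols[j])
      e <- 0; any <- FALSE
      for (a in ia) for (b in ib) {
        d <- coords[a, ] - coords[b, ]
        d <- d - box * round(d / box)
        r <- sqrt(sum(d^2))
        if (r > cutoff) next
        any <- TRUE
        sij <- (at$sigma[a] + at$sigma[b]) / 2
        eij <- sqrt(at$epsilon[a] * at$epsilon[b])
        sr6 <- (sij / r)^6
        e <- e + fke * at$charge[a] * at$charge[b] / r +
          4 * eij * (sr6^2 - sr6)
      }
      if (any)
        out[[length(out) + 1L]] <- data.frame(molA = mols[j],
                                              molB = mols[i], energy = e)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(molA = integer(), molB = integer(), energy = numeric())
}
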