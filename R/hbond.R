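## Geometric hydrogen-bond analysis of membrane configurations: detection,
## per-moiety bookkeeping between glycosphingolipids, and headgroup-water
## statistics.

.gslSpeciesOf <- function(topology) {
  intersect(unique(atomTable(topology)$species), names(.SPECIES_MOIETIES))
}

## donor-hydrogen pair list (one row per covalently bound H on an eligible
## donor element); explicit donor ids are checked for bound hydrogens.
.donorHydrogenPairs <- function(topology, criterion, donors = NULL) {
  at <- atomTable(topology)
  bd <- bondTable(topology)
  isH <- at$element == "H"
  hByAtom <- list()
  if (nrow(bd)) {
    e1 <- at$element[match(bd[, 1], at$atom)]
    e2 <- at$element[match(bd[, 2], at$atom)]
    dh <- rbind(bd[e2 == "H", , drop = FALSE],
                bd[e1 == "H", 2:1, drop = FALSE])
    delem <- at$element[match(dh[, 1], at$atom)]
    dh <- dh[delem %in% criterion@donorElements, , drop = FALSE]
  } else {
    dh <- matrix(integer(), ncol = 2)
  }
  if (!is.null(donors)) {
    missing <- setdiff(donors, dh[, 1])
    if (length(missing))
      stop("donor atom(s) without bound hydrogen: ",
           paste(missing, collapse = ", "))
    dh <- dh[dh[, 1] %in% donors, , drop = FALSE]
  }
  dh
}

#' Detect hydrogen bonds in one configuration
#'
#' A (donor, hydrogen, acceptor) triple is reported when the
#' donor-acceptor distance is at most the criterion cutoff and the
#' hydrogen-donor-acceptor angle is at most the angle cutoff, under the
#' minimum-image convention. Neighbor search uses cell lists.
#'
#' @param coords n x 3 coordinate matrix (nm), rows ordered as the
#'   topology's atom table.
#' @param topology a \code{\link{Topology}}.
#' @param box numeric length-3 periodic box (nm); a 0 entry marks a
#'   non-periodic dimension.
#' @param criterion an \code{\link{HBondCriterion}}.
#' @param excludeIntra drop bonds within one molecule.
#' @param donors optional explicit donor atom ids; an id without a bound
#'   hydrogen raises an error naming the atom.
#' @return data.frame with atom-id columns \code{donor}, \code{hydrogen},
#'   \code{acceptor}.
#' @export
detectHBonds <- function(coords, topology, box,
                         criterion = HBondCriterion(),
                         excludeIntra = TRUE, donors = NULL) {
  at <- atomTable(topology)
  stopifnot(nrow(coords) == nrow(at), length(box) == 3L)
  dh <- .donorHydrogenPairs(topology, criterion, donors)
  accIds <- at$atom[at$element %in% criterion@acceptorElements]
  if (!nrow(dh) || !length(accIds))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  idx <- function(ids) match(ids, at$atom) - 1L
  hits <- hbond_detect_cpp(coords, as.numeric(box),
                           idx(dh[, 1]), idx(dh[, 2]), idx(accIds),
                           as.integer(at$mol), criterion@maxDist,
                           criterion@maxAngle, excludeIntra)
  data.frame(donor = at$atom[hits[, 1] + 1L],
             hydrogen = at$atom[hits[, 2] + 1L],
             acceptor = at$atom[hits[, 3] + 1L])
}

.asFrameList <- function(frames) {
  if (is.matrix(frames)) list(frames) else frames
}

## block-averaged standard error of a per-frame series
.blockSE <- function(x, blockCount) {
  n <- length(x)
  blockCount <- max(1L, min(blockCount, n))
  if (blockCount < 2L) return(NA_real_)
  grp <- cut(seq_len(n), blockCount, labels = FALSE)
  bm <- tapply(x, grp, mean)
  sd(bm) / sqrt(blockCount)
}

#' Per-moiety table of intermolecular GSL-GSL hydrogen bonds
#'
#' Counts hydrogen bonds between distinct glycosphingolipid molecules and
#' attributes each bond to the sugar moieties of its two ends: a bond
#' contributes one count to the donor-end moiety and one to the
#' acceptor-end moiety when they differ, and a single count when both
#' ends lie on the same moiety (a Sia3-Sia3 bond is one Sia3 bond, not
#' two). Counts are divided by the number of GSL molecules and averaged
#' over frames; the per-species total equals the sum over moieties. If
#' sphingomyelin is present, the SM-SM bond count per SM molecule is
#' reported as a reference row. Standard errors come from block
#' averaging of the per-frame series.
#'
#' @param frames coordinate matrix or list of matrices (nm).
#' @param topology a \code{\link{Topology}}.
#' @param moietyMap a \code{\link{MoietyMap}}.
#' @param box length-3 box vector (nm).
#' @param criterion an \code{\link{HBondCriterion}}.
#' @param blockCount number of contiguous blocks for the SE.
#' @return data.frame with columns \code{species}, \code{moiety} (sugar
#'   moieties, \code{"total"}, and \code{"SM-SM"} when applicable),
#'   \code{mean_bonds_per_molecule}, \code{se}.
#' @export
moietyHBondTable <- function(frames, topology, moietyMap, box,
                             criterion = HBondCriterion(),
                             blockCount = 5L) {
  frames <- .asFrameList(frames)
  stopifnot(length(frames) >= 1L)
  at <- atomTable(topology)
  gslSpecies <- .gslSpeciesOf(topology)
  if (!length(gslSpecies)) stop("no GSL molecules in topology")
  labels <- moietyOf(moietyMap)
  moietyOfAtom <- labels[as.character(at$atom)]
  speciesOfMol <- tapply(at$species, at$mol, function(s) s[1])

  perFrame <- lapply(frames, function(fr) {
    bonds <- detectHBonds(fr, topology, box, criterion, excludeIntra = TRUE)
    dMol <- at$mol[match(bonds$donor, at$atom)]
    aMol <- at$mol[match(bonds$acceptor, at$atom)]
    dSp <- as.character(speciesOfMol[as.character(dMol)])
    aSp <- as.character(speciesOfMol[as.character(aMol)])
    gg <- dSp %in% gslSpecies & aSp %in% gslSpecies
    dm <- moietyOfAtom[as.character(bonds$donor[gg])]
    am <- moietyOfAtom[as.character(bonds$acceptor[gg])]
    dsp <- dSp[gg]; asp <- aSp[gg]
    # one count per distinct (species, moiety) end of each bond
    same <- dsp == asp & dm == am
    ends <- rbind(
      data.frame(species = dsp, moiety = dm),
      data.frame(species = asp[!same], moiety = am[!same]))
    smsm <- sum(dSp == "SM" & aSp == "SM")
    list(ends = ends, smsm = smsm)
  })

  out <- list()
  for (sp in gslSpecies) {
    nMol <- sum(speciesOfMol == sp)
    mo <- speciesMoieties(sp)
    counts <- sapply(perFrame, function(pf) {
      vapply(mo, function(m)
        sum(pf$ends$species == sp & pf$ends$moiety == m) / nMol, numeric(1))
    })
    counts <- matrix(counts, nrow = length(mo),
                     dimnames = list(mo, NULL))
    rows <- data.frame(
      species = sp, moiety = mo,
      mean_bonds_per_molecule = rowMeans(counts),
      se = apply(counts, 1L, .blockSE, blockCount = blockCount))
    total <- data.frame(
      species = sp, moiety = "total",
      mean_bonds_per_molecule = sum(rowMeans(counts)),
      se = .blockSE(colSums(counts), blockCount))
    out[[sp]] <- rbind(rows, total)
  }
  res <- do.call(rbind, out)
  if ("SM" %in% speciesOfMol) {
    nSM <- sum(speciesOfMol == "SM")
    smser <- vapply(perFrame, function(pf) pf$smsm / nSM, numeric(1))
    res <- rbind(res, data.frame(
      species = "SM", moiety = "SM-SM",
      mean_bonds_per_molecule = mean(smser),
      se = .blockSE(smser, blockCount)))
  }
  rownames(res) <- NULL
  res
}

#' Headgroup-water hydrogen bonds per GSL molecule
#'
#' Counts hydrogen bonds between glycosphingolipid headgroup (sugar
#' moiety) atoms and water, per GSL molecule and per frame, separately for
#' the whole headgroup and for each sialic-acid moiety; the Sia fraction
#' is \code{100 * Sia / headgroup}. In \code{"isolated"} mode the count is
#' restricted to one designated GSL molecule.
#'
#' @inheritParams moietyHBondTable
#' @param mode \code{"nanodomain"} (all GSL molecules) or
#'   \code{"isolated"} (one designated molecule).
#' @param isolatedMol molecule id of the isolated GSL (required in
#'   isolated mode).
#' @return data.frame with columns \code{species}, \code{group}
#'   (\code{"headgroup"} or a Sia moiety), \code{bonds_per_gsl},
#'   \code{se}, \code{sia_fraction_pct} (one decimal, \code{NA} for the
#'   headgroup rows or when undefined).
#' @export
headgroupWaterHBonds <- function(frames, topology, moietyMap, box,
                                 criterion = HBondCriterion(),
                                 mode = c("nanodomain", "isolated"),
                                 isolatedMol = NULL, blockCount = 5L) {
  mode <- match.arg(mode)
  frames <- .asFrameList(frames)
  at <- atomTable(topology)
  hasWater <- any(at$species == "water")
  gslSpecies <- .gslSpeciesOf(topology)
  if (!length(gslSpecies)) stop("no GSL molecules in topology")
  if (mode == "isolated") {
    if (is.null(isolatedMol))
      stop("isolated mode requires a designated GSL molecule id")
    if (!isolatedMol %in% at$mol[at$species %in% gslSpecies])
      stop("designated molecule ", isolatedMol, " is not a GSL")
  }
  labels <- moietyOf(moietyMap)
  moietyOfAtom <- labels[as.character(at$atom)]
  speciesOfMol <- tapply(at$species, at$mol, function(s) s[1])

  perFrame <- lapply(frames, function(fr) {
    if (!hasWater) return(NULL)
    bonds <- detectHBonds(fr, topology, box, criterion, excludeIntra = TRUE)
    if (!nrow(bonds)) return(NULL)
    dMoi <- moietyOfAtom[as.character(bonds$donor)]
    aMoi <- moietyOfAtom[as.character(bonds$acceptor)]
    dMol <- at$mol[match(bonds$donor, at$atom)]
    aMol <- at$mol[match(bonds$acceptor, at$atom)]
    # orient each bond as (gsl sugar atom; partner water)
    gw <- dMoi %in% .SUGAR_MOIETIES & aMoi == "water"
    wg <- aMoi %in% .SUGAR_MOIETIES & dMoi == "water"
    data.frame(mol = c(dMol[gw], aMol[wg]),
               moiety = c(dMoi[gw], aMoi[wg]))
  })

  gslMols <- as.integer(names(speciesOfMol)[speciesOfMol %in% gslSpecies])
  if (mode == "isolated") gslMols <- as.integer(isolatedMol)

  out <- list()
  for (sp in gslSpecies) {
    mols <- gslMols[speciesOfMol[as.character(gslMols)] == sp]
    if (!length(mols)) next
    sias <- intersect(speciesMoieties(sp), c("Sia3", "Sia6"))
    groups <- c("headgroup", sias)
    series <- sapply(perFrame, function(pf) {
      vapply(groups, function(g) {
        if (is.null(pf)) return(0)
        keep <- pf$mol %in% mols &
          (if (g == "headgroup") pf$moiety %in% .SUGAR_MOIETIES
           else pf$moiety == g)
        sum(keep) / length(mols)
      }, numeric(1))
    })
    series <- matrix(series, nrow = length(groups),
                     dimnames = list(groups, NULL))
    means <- rowMeans(series)
    frac <- rep(NA_real_, length(groups))
    if (means["headgroup"] > 0 && length(sias))
      frac[match(sias, groups)] <-
        round(100 * means[sias] / means["headgroup"], 1)
    out[[sp]] <- data.frame(
      species = sp, group = groups, bonds_per_gsl = means,
      se = apply(series, 1L, .blockSE, blockCount = blockCount),
      sia_fraction_pct = frac)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sia-to-headgroup hydrogen-bond fraction
#'
#' \code{100 * siaBonds / headgroupBonds}, reported to one decimal, the
#' headline statistic of the headgroup-water analysis.
#'
#' @param siaBonds hydrogen bonds formed by one Sia moiety (per GSL).
#' @param headgroupBonds bonds formed by the whole headgroup (per GSL).
#' @return Percentage, one decimal; \code{NA} if the headgroup count is 0.
#' @examples
#' siaWaterFraction(12.2, 32.6)  # 37.4
#' @export
siaWaterFraction <- function(siaBonds, headgroupBonds) {
  ifelse(headgroupBonds > 0, round(100 * siaBonds / headgroupBonds, 1),
         NA_real_)
}
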