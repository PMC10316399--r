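## Pairwise nonbonded interaction energies (Coulomb + Lennard-Jones,
## Lorentz-Berthelot combination, plain cutoff, minimum image) and their
## per-partner bookkeeping.

#' Nonbonded interaction energy between two atom groups
#'
#' \deqn{E = \sum_{i \in A, j \in B, r_{ij} \le r_c} \left[ f
#' \frac{q_i q_j}{r_{ij}} + 4\epsilon_{ij}\left(
#' \left(\frac{\sigma_{ij}}{r_{ij}}\right)^{12} -
#' \left(\frac{\sigma_{ij}}{r_{ij}}\right)^{6}\right)\right]} with
#' \eqn{f = 138.935458} kJ mol\eqn{^{-1}} nm e\eqn{^{-2}},
#' \eqn{\sigma_{ij} = (\sigma_i + \sigma_j)/2},
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}}, plain cutoff and
#' minimum-image convention. Direct-space terms only: no Ewald/mesh
#' reciprocal part, so the decomposition into molecule pairs is exact.
#'
#' @param coords n x 3 coordinate matrix (nm), rows ordered as the
#'   topology's atom table.
#' @param topology a \code{\link{Topology}}.
#' @param box length-3 box vector (nm; 0 = non-periodic dimension).
#' @param groupA,groupB disjoint atom-id vectors.
#' @param cutoff distance cutoff (nm).
#' @return Energy in kJ/mol.
#' @export
pairInteractionEnergy <- function(coords, topology, box, groupA, groupB,
                                  cutoff = 1.2) {
  at <- atomTable(topology)
  stopifnot(nrow(coords) == nrow(at))
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  ia <- match(groupA, at$atom); ib <- match(groupB, at$atom)
  if (anyNA(ia) || anyNA(ib)) stop("group atom ids not in topology")
  pair_energy_cpp(coords, as.numeric(box), ia - 1L, ib - 1L,
                  at$charge, at$sigma, at$epsilon, cutoff)
}

#' Per-species interaction-energy table with partner normalization
#'
#' For each glycosphingolipid molecule, sums the nonbonded energy between
#' its sugar headgroup and every other non-water molecule, classed by the
#' partner's species (GSL/GSL "homogeneous" vs DOPC/SM/Chol
#' "heterogeneous"), and averages over GSL molecules and frames. An
#' interacting partner is a molecule with at least one atom pair inside
#' the cutoff in at least \code{partnerFraction} of the frames; the
#' normalized energy is the class total divided by the partner count
#' (reported missing when a class has no partner).
#'
#' @param frames coordinate matrix or list of matrices (nm).
#' @param topology a \code{\link{Topology}}.
#' @param moietyMap a \code{\link{MoietyMap}} (identifies headgroup atoms).
#' @param box length-3 box vector (nm).
#' @param cutoff interaction cutoff (nm).
#' @param partnerFraction minimum fraction of frames with contact for a
#'   molecule to count as an interacting partner.
#' @param gslSide \code{"headgroup"} (sugar-moiety atoms only, the
#'   default) or \code{"molecule"} (all GSL atoms).
#' @return data.frame with columns \code{species} (the GSL),
#'   \code{partner_class}, \code{total_kJ_mol} (per GSL molecule),
#'   \code{n_partners} (per GSL molecule), \code{normalized_kJ_mol}.
#' @export
energySummary <- function(frames, topology, moietyMap, box, cutoff = 1.2,
                          partnerFraction = 0.5,
                          gslSide = c("headgroup", "molecule")) {
  gslSide <- match.arg(gslSide)
  frames <- .asFrameList(frames)
  at <- atomTable(topology)
  gslSpecies <- .gslSpeciesOf(topology)
  if (!length(gslSpecies)) stop("no GSL molecules in topology")
  labels <- moietyOf(moietyMap)
  speciesOfMol <- tapply(at$species, at$mol, function(s) s[1])
  mols <- as.integer(names(speciesOfMol))

  gslMols <- mols[speciesOfMol %in% gslSpecies]
  partnerMols <- mols[speciesOfMol != "water"]

  idxOfMol <- split(seq_len(nrow(at)), at$mol)
  hgIdx <- lapply(as.character(gslMols), function(m) {
    idx <- idxOfMol[[m]]
    if (gslSide == "molecule") return(idx)
    idx[labels[as.character(at$atom[idx])] %in% .SUGAR_MOIETIES]
  })
  names(hgIdx) <- as.character(gslMols)

  nf <- length(frames)
  # energy[g, p, f] and contact[g, p, f] over GSL g, partner molecule p
  pairs <- expand.grid(g = gslMols, p = partnerMols)
  pairs <- pairs[pairs$g != pairs$p, ]
  eArr <- matrix(0, nrow(pairs), nf)
  cArr <- matrix(FALSE, nrow(pairs), nf)
  for (f in seq_len(nf)) {
    fr <- frames[[f]]
    for (k in seq_len(nrow(pairs))) {
      ia <- hgIdx[[as.character(pairs$g[k])]]
      ib <- idxOfMol[[as.character(pairs$p[k])]]
      dmin <- min_group_dist_cpp(fr, as.numeric(box), ia - 1L, ib - 1L)
      if (dmin < 1e-3) stop("overlapping atoms between molecules ",
                            pairs$g[k], " and ", pairs$p[k])
      cArr[k, f] <- dmin <= cutoff
      if (cArr[k, f])
        eArr[k, f] <- pair_energy_cpp(fr, as.numeric(box), ia - 1L,
                                      ib - 1L, at$charge, at$sigma,
                                      at$epsilon, cutoff)
    }
  }
  isPartner <- rowMeans(cArr) >= partnerFraction

  classOf <- function(p) {
    sp <- as.character(speciesOfMol[as.character(p)])
    ifelse(sp %in% gslSpecies, "GSL/GSL", sp)
  }
  out <- list()
  for (sp in gslSpecies) {
    gm <- gslMols[speciesOfMol[as.character(gslMols)] == sp]
    cls <- classOf(pairs$p)
    allClasses <- unique(c("GSL/GSL",
                           setdiff(unique(classOf(partnerMols)), "GSL/GSL")))
    for (cl in allClasses) {
      sel <- pairs$g %in% gm & cls == cl
      # per-GSL per-frame class total, then grand mean
      tot <- if (any(sel)) {
        perG <- vapply(gm, function(g)
          mean(colSums(eArr[sel & pairs$g == g, , drop = FALSE])),
          numeric(1))
        mean(perG)
      } else 0
      npart <- if (any(sel)) {
        mean(vapply(gm, function(g)
          sum(isPartner[sel & pairs$g == g]), numeric(1)))
      } else 0
      out[[length(out) + 1L]] <- data.frame(
        species = sp, partner_class = cl, total_kJ_mol = tot,
        n_partners = npart,
        normalized_kJ_mol = if (npart > 0) tot / npart else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percent change in interaction-energy magnitude
#'
#' \code{100 * (|eNew| - |eRef|) / |eRef|}: the relative increase in the
#' magnitude of an interaction energy (e.g. on adding sialic-acid
#' moieties to a neutral glycosphingolipid). Returned unrounded; tables
#' conventionally report the nearest integer.
#'
#' @param eRef reference energy (kJ/mol, nonzero).
#' @param eNew new energy (kJ/mol).
#' @return Percent change.
#' @examples
#' percentEnergyChange(-35, -56)  # 60
#' @export
percentEnergyChange <- function(eRef, eNew) {
  if (any(eRef == 0)) stop("reference energy must be nonzero")
  100 * (abs(eNew) - abs(eRef)) / abs(eRef)
}

## Standard atomic masses (u) for the mass-weighted density profile.
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06)

#' Partial density profile along the membrane normal
#'
#' Bins the mass (or number) density of a selection of atoms along one box
#' axis, averaged over frames. With \code{normalization = "peak"} the
#' profile is scaled to unit maximum; \code{"none"} returns densities in
#' u/nm^3 (or atoms/nm^3).
#'
#' @param frames coordinate matrix or list of matrices (nm).
#' @param topology a \code{\link{Topology}}.
#' @param selection atom-id vector (non-empty).
#' @param box length-3 box vector (nm).
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @param nBins number of bins (>= 10).
#' @param normalization \code{"peak"} or \code{"none"}.
#' @param weight \code{"mass"} or \code{"number"}.
#' @return data.frame with columns \code{center_nm}, \code{density} and
#'   attributes \code{normalization}, \code{weight}, \code{binWidth_nm}.
#' @export
densityProfile <- function(frames, topology, selection, box,
                           axis = c("z", "x", "y"), nBins = 50L,
                           normalization = c("peak", "none"),
                           weight = c("mass", "number")) {
  axis <- match.arg(axis)
  normalization <- match.arg(normalization)
  weight <- match.arg(weight)
  if (!length(selection)) stop("empty selection")
  if (nBins < 10L) stop("nBins must be >= 10")
  frames <- .asFrameList(frames)
  at <- atomTable(topology)
  idx <- match(selection, at$atom)
  if (anyNA(idx)) stop("selection atom ids not in topology")
  ax <- match(axis, c("x", "y", "z"))
  Lax <- box[ax]
  if (!(Lax > 0)) stop("box has no extent along the chosen axis")
  w <- if (weight == "mass") {
    m <- .ATOMIC_MASS[at$element[idx]]
    if (anyNA(m)) stop("no mass for element(s): ",
                       paste(unique(at$element[idx][is.na(m)]),
                             collapse = ", "))
    m
  } else rep(1, length(idx))
  edges <- seq(0, Lax, length.out = nBins + 1L)
  binW <- Lax / nBins
  acc <- numeric(nBins)
  for (fr in frames) {
    z <- fr[idx, ax] %% Lax
    b <- pmin(pmax(floor(z / binW) + 1L, 1L), nBins)
    acc <- acc + vapply(seq_len(nBins), function(k) sum(w[b == k]),
                        numeric(1))
  }
  crossArea <- prod(box[-ax][box[-ax] > 0])
  dens <- acc / length(frames) / (binW * max(crossArea, 1))
  if (normalization == "peak" && max(dens) > 0) dens <- dens / max(dens)
  out <- data.frame(center_nm = (head(edges, -1) + tail(edges, -1)) / 2,
                    density = dens)
  attr(out, "normalization") <- normalization
  attr(out, "weight") <- weight
  attr(out, "binWidth_nm") <- binW
  out
}
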