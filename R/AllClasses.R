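#' @import methods
#' @importFrom stats integrate rbinom rnorm rpois runif sd setNames approx optimize aggregate
#' @importFrom utils read.table write.table write.csv head tail packageVersion
#' @importFrom graphics hist
#' @useDynLib nanoFRET, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Maximum nanodomain area fraction the hard-disc placement supports.
## Above this, Metropolis relaxation of the disc packing is not guaranteed
## to converge on the patch sizes used here.
.MAX_AREA_FRACTION <- 0.65

#' Nanodomain membrane model
#'
#' Parametrizes a flat, periodic bilayer patch decorated with circular
#' nanodomains: domain radius \eqn{R} (nm), area fraction \eqn{A} covered by
#' domains, the lateral box size, the transbilayer separation of the two
#' fluorophore planes, and the partition coefficients of donor and acceptor
#' probes between the domain and bulk phases.
#'
#' @slot radius numeric, nanodomain radius in nm.
#' @slot areaFraction numeric, fraction of membrane area covered by domains,
#'   in \code{[0, 0.65]}.
#' @slot boxLength numeric, lateral box edge in nm (periodic boundaries).
#' @slot bilayerSep numeric, distance between the two leaflet fluorophore
#'   planes in nm.
#' @slot partitionDonor,partitionAcceptor numeric, partition coefficients
#'   \eqn{K \ge 0} of the probes (domain/bulk surface-density ratio).
#' @exportClass DomainModel
setClass("DomainModel",
  representation(
    radius = "numeric",
    areaFraction = "numeric",
    boxLength = "numeric",
    bilayerSep = "numeric",
    partitionDonor = "numeric",
    partitionAcceptor = "numeric"
  )
)

setValidity("DomainModel", function(object) {
  msg <- character()
  a <- object@areaFraction
  if (length(a) != 1L || is.na(a) || a < 0 || a > .MAX_AREA_FRACTION)
    msg <- c(msg, sprintf("areaFraction must lie in [0, %.2f]", .MAX_AREA_FRACTION))
  if (length(a) == 1L && !is.na(a) && a > 0 &&
      (length(object@radius) != 1L || !(object@radius > 0)))
    msg <- c(msg, "radius must be > 0 when areaFraction > 0")
  if (length(object@boxLength) != 1L || !(object@boxLength > 0))
    msg <- c(msg, "boxLength must be a positive scalar")
  if (object@areaFraction > 0 && object@boxLength < 10 * object@radius)
    msg <- c(msg, "boxLength must be at least 10 x radius (finite-size control)")
  if (object@bilayerSep < 0)
    msg <- c(msg, "bilayerSep must be >= 0")
  if (object@partitionDonor < 0 || object@partitionAcceptor < 0)
    msg <- c(msg, "partition coefficients must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname DomainModel-class
#' @param radius,areaFraction,boxLength,bilayerSep,partitionDonor,partitionAcceptor
#'   see the corresponding slots.
#' @return A \code{DomainModel} object.
#' @examples
#' dm <- DomainModel(radius = 15, areaFraction = 0.55, boxLength = 150)
#' radius(dm)
#' @export
DomainModel <- function(radius, areaFraction, boxLength,
                        bilayerSep = 5.0,
                        partitionDonor = 5.0, partitionAcceptor = 5.0) {
  new("DomainModel",
    radius = as.numeric(radius), areaFraction = as.numeric(areaFraction),
    boxLength = as.numeric(boxLength), bilayerSep = as.numeric(bilayerSep),
    partitionDonor = as.numeric(partitionDonor),
    partitionAcceptor = as.numeric(partitionAcceptor))
}

#' Realized nanodomain disc configuration
#'
#' Centers of non-overlapping discs of a common radius on the periodic patch.
#'
#' @slot centers two-column matrix of disc centers (nm), possibly 0 rows.
#' @slot radius numeric, disc radius (nm).
#' @slot boxLength numeric, lateral box edge (nm).
#' @exportClass DomainConfiguration
setClass("DomainConfiguration",
  representation(centers = "matrix", radius = "numeric", boxLength = "numeric")
)

setValidity("DomainConfiguration", function(object) {
  msg <- character()
  if (ncol(object@centers) != 2L && nrow(object@centers) > 0L)
    msg <- c(msg, "centers must have two columns")
  if (nrow(object@centers) > 0L) {
    if (any(object@centers < 0) || any(object@centers >= object@boxLength))
      msg <- c(msg, "centers must lie in [0, boxLength)")
    dmin <- minPairDistTorus(object@centers, object@boxLength)
    if (is.finite(dmin) && dmin < 2 * object@radius - 1e-9)
      msg <- c(msg, "discs overlap: min center distance < 2 x radius")
  }
  if (length(msg)) msg else TRUE
})

#' Donor/acceptor probe configuration
#'
#' Lateral probe positions on a periodic patch, a leaflet label per probe
#' (0 = outer plane, 1 = inner plane) and a flag marking probes that fall
#' inside a nanodomain disc.
#'
#' @slot donorXY,acceptorXY two-column matrices of lateral positions (nm).
#' @slot donorLeaflet,acceptorLeaflet integer vectors of 0/1 leaflet labels.
#' @slot donorInDomain,acceptorInDomain logical vectors.
#' @slot boxLength,bilayerSep numeric scalars (nm).
#' @exportClass ProbeConfiguration
setClass("ProbeConfiguration",
  representation(
    donorXY = "matrix", donorLeaflet = "integer", donorInDomain = "logical",
    acceptorXY = "matrix", acceptorLeaflet = "integer",
    acceptorInDomain = "logical",
    boxLength = "numeric", bilayerSep = "numeric"
  )
)

setValidity("ProbeConfiguration", function(object) {
  msg <- character()
  L <- object@boxLength
  chk <- function(xy, lab) {
    if (nrow(xy) > 0L && (any(xy < 0) || any(xy >= L)))
      sprintf("%s positions must lie in [0, boxLength)", lab) else NULL
  }
  msg <- c(msg, chk(object@donorXY, "donor"), chk(object@acceptorXY, "acceptor"))
  if (nrow(object@donorXY) != length(object@donorLeaflet) ||
      nrow(object@donorXY) != length(object@donorInDomain))
    msg <- c(msg, "donor slots have inconsistent lengths")
  if (nrow(object@acceptorXY) != length(object@acceptorLeaflet) ||
      nrow(object@acceptorXY) != length(object@acceptorInDomain))
    msg <- c(msg, "acceptor slots have inconsistent lengths")
  if (length(msg)) msg else TRUE
})

#' Photophysical parameters of the FRET pair
#'
#' @slot forsterRadius numeric, Forster radius \eqn{R_0} in nm (the
#'   donor-acceptor distance with 50\% transfer efficiency; the orientation
#'   factor is taken as absorbed into this value).
#' @slot donorLifetime numeric, unquenched donor lifetime \eqn{\tau_D} in ns.
#' @slot rMin numeric, minimum allowed donor-acceptor lateral separation in
#'   nm (probe excluded volume; prevents divergence of \eqn{(R_0/r)^6}).
#' @exportClass FretParameters
setClass("FretParameters",
  representation(forsterRadius = "numeric", donorLifetime = "numeric",
                 rMin = "numeric")
)

setValidity("FretParameters", function(object) {
  msg <- character()
  if (!(object@forsterRadius > 0)) msg <- c(msg, "forsterRadius must be > 0")
  if (!(object@donorLifetime > 0)) msg <- c(msg, "donorLifetime must be > 0")
  if (object@rMin < 0) msg <- c(msg, "rMin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname FretParameters-class
#' @param forsterRadius,donorLifetime,rMin see slots.
#' @return A \code{FretParameters} object.
#' @export
FretParameters <- function(forsterRadius, donorLifetime, rMin = 1.0) {
  new("FretParameters", forsterRadius = as.numeric(forsterRadius),
      donorLifetime = as.numeric(donorLifetime), rMin = as.numeric(rMin))
}

#' Time-resolved donor decay curve
#'
#' A uniform time grid carrying either a normalized model decay
#' (\code{intensity}, with \code{intensity[1]} corresponding to \eqn{t=0}
#' and value 1) or measured/synthetic photon counts (\code{counts}), or
#' both. Monte-Carlo standard errors may be attached for ensemble decays.
#'
#' @slot time numeric, strictly increasing uniform time grid (ns).
#' @slot intensity numeric, normalized model intensity (or length 0).
#' @slot counts numeric, non-negative integer photon counts (or length 0).
#' @slot se numeric, per-channel Monte-Carlo standard error (or length 0).
#' @slot channelWidth numeric, channel width (ns).
#' @slot metadata list, free-form header metadata (tauD, R0, ...).
#' @exportClass DecayCurve
setClass("DecayCurve",
  representation(time = "numeric", intensity = "numeric", counts = "numeric",
                 se = "numeric", channelWidth = "numeric", metadata = "list")
)

setValidity("DecayCurve", function(object) {
  msg <- character()
  t <- object@time
  if (length(t) < 2L) msg <- c(msg, "time grid needs at least 2 points")
  else {
    dt <- diff(t)
    if (any(dt <= 0)) msg <- c(msg, "time grid must be strictly increasing")
    else if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      msg <- c(msg, "time grid must have a uniform channel width")
  }
  if (length(object@intensity) &&
      length(object@intensity) != length(t))
    msg <- c(msg, "intensity length must match time grid")
  if (length(object@counts)) {
    if (length(object@counts) != length(t))
      msg <- c(msg, "counts length must match time grid")
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (!length(object@intensity) && !length(object@counts))
    msg <- c(msg, "a DecayCurve needs intensity and/or counts")
  if (length(msg)) msg else TRUE
})

#' @rdname DecayCurve-class
#' @param time,intensity,counts,se,channelWidth,metadata see slots;
#'   \code{channelWidth} defaults to the grid spacing.
#' @return A \code{DecayCurve}.
#' @export
DecayCurve <- function(time, intensity = numeric(), counts = numeric(),
                       se = numeric(), channelWidth = NULL,
                       metadata = list()) {
  if (is.null(channelWidth))
    channelWidth <- if (length(time) > 1L) time[2] - time[1] else NA_real_
  new("DecayCurve", time = as.numeric(time),
      intensity = as.numeric(intensity), counts = as.numeric(counts),
      se = as.numeric(se), channelWidth = as.numeric(channelWidth),
      metadata = metadata)
}

#' Per-vesicle fit result
#'
#' The (R, A) grid node minimizing the Poisson-weighted chi-square for one
#' GUV decay, together with the full chi-square surface so that flat
#' (poorly identified) directions can be inspected.
#'
#' @slot guvId character identifier.
#' @slot radiusHat,areaHat numeric point estimates (nm, dimensionless).
#' @slot chiSquare numeric, minimized chi-square.
#' @slot surface data.frame with columns \code{radius_nm}, \code{area},
#'   \code{chisq}, \code{amplitude}, \code{background}, \code{valid}.
#' @slot seed integer master seed of the fit.
#' @slot tieTolerance numeric chi-square margin used for statistical
#'   tie-breaking (nodes within the margin of the minimum are
#'   indistinguishable at the library's Monte-Carlo resolution).
#' @exportClass FitResult
setClass("FitResult",
  representation(guvId = "character", radiusHat = "numeric",
                 areaHat = "numeric", chiSquare = "numeric",
                 surface = "data.frame", seed = "integer",
                 tieTolerance = "numeric"),
  prototype(tieTolerance = 0)
)

setValidity("FitResult", function(object) {
  msg <- character()
  if (!is.finite(object@chiSquare) || object@chiSquare < 0)
    msg <- c(msg, "chiSquare must be finite and >= 0")
  s <- object@surface
  if (nrow(s)) {
    # compare against the highest-precision pass available: refined
    # (rescored) nodes when present, else the coarse grid
    ok <- s$valid & (if (any(s$refined)) s$refined else TRUE)
    if (any(ok) &&
        object@chiSquare > min(s$chisq[ok]) + object@tieTolerance + 1e-9)
      msg <- c(msg,
               "(radiusHat, areaHat) must attain the minimal chi-square (within the tie tolerance)")
  }
  if (length(msg)) msg else TRUE
})

#' Cohort summary of per-vesicle fits
#'
#' @slot results list of \code{FitResult}.
#' @slot meanRadius,meanArea numeric arithmetic means over vesicles.
#' @slot histRadius,histArea data.frames with columns \code{lower},
#'   \code{upper}, \code{count}.
#' @exportClass DistributionSummary
setClass("DistributionSummary",
  representation(results = "list", meanRadius = "numeric",
                 meanArea = "numeric", histRadius = "data.frame",
                 histArea = "data.frame")
)

#' Molecular topology table
#'
#' Per-atom chemistry needed by the hydrogen-bond and interaction-energy
#' stages: element, partial charge, Lennard-Jones parameters, molecule id
#' and molecular species, plus the intramolecular bond list.
#'
#' @slot atoms data.frame with columns \code{atom} (integer id),
#'   \code{element}, \code{charge} (e), \code{sigma} (nm), \code{epsilon}
#'   (kJ/mol), \code{mol} (integer molecule id), \code{species}.
#' @slot bonds two-column integer matrix of bonded atom-id pairs.
#' @exportClass Topology
setClass("Topology",
  representation(atoms = "data.frame", bonds = "matrix")
)

setValidity("Topology", function(object) {
  msg <- character()
  need <- c("atom", "element", "charge", "sigma", "epsilon", "mol", "species")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms table must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@atoms$atom))
      msg <- c(msg, "atom ids must be unique")
    if (nrow(object@bonds)) {
      id2mol <- setNames(object@atoms$mol, object@atoms$atom)
      m1 <- id2mol[as.character(object@bonds[, 1])]
      m2 <- id2mol[as.character(object@bonds[, 2])]
      if (any(is.na(m1)) || any(is.na(m2)))
        msg <- c(msg, "bonds reference unknown atom ids")
      else if (any(m1 != m2))
        msg <- c(msg, "bonds must connect atoms of the same molecule")
    }
    qs <- tapply(object@atoms$charge, object@atoms$mol, sum)
    if (any(abs(qs - round(qs)) > 1e-6))
      msg <- c(msg, "net molecular charges must be integral to 1e-6 e")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Topology-class
#' @param atoms,bonds see slots; \code{bonds} may be a 2-column matrix or
#'   data.frame of atom-id pairs.
#' @return A \code{Topology}.
#' @export
Topology <- function(atoms, bonds = matrix(integer(), ncol = 2)) {
  bonds <- as.matrix(bonds)
  if (!nrow(bonds)) bonds <- matrix(integer(), ncol = 2)
  storage.mode(bonds) <- "integer"
  atoms$atom <- as.integer(atoms$atom)
  atoms$mol <- as.integer(atoms$mol)
  new("Topology", atoms = as.data.frame(atoms), bonds = bonds)
}

## Canonical sugar-moiety labels of the ganglioside headgroup plus the
## bookkeeping labels for the remainder of the system.
.MOIETY_LEVELS <- c("Cer", "Glc1", "Gal2", "Sia3", "GalNAc4", "Gal5", "Sia6",
                    "headgroup", "water", "other")
.SUGAR_MOIETIES <- c("Glc1", "Gal2", "Sia3", "GalNAc4", "Gal5", "Sia6")

#' Atom-to-moiety assignment
#'
#' Maps atom ids to named sugar units of the glycosphingolipid headgroup
#' (Glc1, Gal2, Sia3, GalNAc4, Gal5, Sia6), the ceramide backbone, water, a
#' generic non-GSL headgroup, or "other".
#'
#' @slot labels character vector of moiety labels, names = atom ids.
#' @exportClass MoietyMap
setClass("MoietyMap", representation(labels = "character"))

setValidity("MoietyMap", function(object) {
  bad <- setdiff(unique(object@labels), .MOIETY_LEVELS)
  if (length(bad))
    paste("unknown moiety labels:", paste(bad, collapse = ", "))
  else if (is.null(names(object@labels)))
    "labels must be named by atom id"
  else TRUE
})

#' @rdname MoietyMap-class
#' @param atom integer atom ids.
#' @param moiety character moiety labels, same length.
#' @return A \code{MoietyMap}.
#' @export
MoietyMap <- function(atom, moiety) {
  new("MoietyMap", labels = setNames(as.character(moiety), as.character(atom)))
}

#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen...acceptor triple counts as a hydrogen bond when the
#' donor-acceptor distance is at most \code{maxDist} and the
#' hydrogen-donor-acceptor angle is at most \code{maxAngle}.
#'
#' @slot maxDist numeric, donor-acceptor distance cutoff (nm).
#' @slot maxAngle numeric, H-donor-acceptor angle cutoff (degrees).
#' @slot donorElements,acceptorElements character, elements eligible as
#'   donors (must carry a bound hydrogen) and acceptors.
#' @exportClass HBondCriterion
setClass("HBondCriterion",
  representation(maxDist = "numeric", maxAngle = "numeric",
                 donorElements = "character", acceptorElements = "character")
)

setValidity("HBondCriterion", function(object) {
  msg <- character()
  if (!(object@maxDist > 0)) msg <- c(msg, "maxDist must be > 0")
  if (!(object@maxAngle > 0 && object@maxAngle <= 90))
    msg <- c(msg, "maxAngle must lie in (0, 90] degrees")
  if (length(msg)) msg else TRUE
})

#' @rdname HBondCriterion-class
#' @param maxDist,maxAngle,donorElements,acceptorElements see slots. The
#'   defaults (0.35 nm, 30 degrees, N/O donors and acceptors) are the common
#'   convention of molecular-trajectory analysis tools.
#' @return An \code{HBondCriterion}.
#' @export
HBondCriterion <- function(maxDist = 0.35, maxAngle = 30,
                           donorElements = c("N", "O"),
                           acceptorElements = c("N", "O")) {
  new("HBondCriterion", maxDist = as.numeric(maxDist),
      maxAngle = as.numeric(maxAngle),
      donorElements = donorElements, acceptorElements = acceptorElements)
}
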