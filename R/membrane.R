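## Geometry of the nanodomain patch: hard-disc placement, probe placement
## with phase partitioning, and the periodic (minimum-image) pair metric.

#' Minimum pairwise center distance under the torus metric
#'
#' @param centers two-column matrix of points (nm).
#' @param boxLength box edge (nm).
#' @return Minimum pairwise minimum-image distance, \code{Inf} for fewer
#'   than two points.
#' @keywords internal
minPairDistTorus <- function(centers, boxLength) {
  n <- nrow(centers)
  if (is.null(n) || n < 2L) return(Inf)
  min_pair_dist_cpp(centers, boxLength)
}

#' Default simulation box edge
#'
#' The lateral box must be large relative to both the domain radius and the
#' Forster radius so that periodic images do not distort the decay.
#'
#' @param radius nanodomain radius (nm).
#' @param forsterRadius Forster radius (nm).
#' @return Box edge \code{max(10 * radius, 40 * forsterRadius)} in nm.
#' @export
defaultBoxLength <- function(radius, forsterRadius) {
  max(10 * radius, 40 * forsterRadius)
}

#' Place non-overlapping nanodomain discs
#'
#' Places \code{N = round(A L^2 / (pi R^2))} discs of radius \code{R} on the
#' periodic patch without overlaps. Placement starts from a random
#' configuration and removes overlaps by zero-temperature Metropolis
#' displacement moves, which reaches coverages well above the random
#' sequential adsorption jamming limit (~55\%) up to the supported maximum
#' of 65\%.
#'
#' @param model a \code{\link{DomainModel}}.
#' @param seed integer seed (deterministic placement).
#' @param shuffleSweeps Metropolis randomization sweeps after the initial
#'   overlap-free placement.
#' @return A \code{\link{DomainConfiguration}}.
#' @examples
#' cfg <- placeDomains(DomainModel(15, 0.4, 160), seed = 1)
#' nDomains(cfg)
#' @export
placeDomains <- function(model, seed, shuffleSweeps = 10L) {
  stopifnot(is(model, "DomainModel"))
  validObject(model)
  L <- model@boxLength
  A <- model@areaFraction
  R <- model@radius
  n <- if (A > 0) as.integer(round(A * L^2 / (pi * R^2))) else 0L
  if (n == 0L) {
    return(new("DomainConfiguration",
               centers = matrix(numeric(), ncol = 2), radius = R,
               boxLength = L))
  }
  set.seed(expandSeed(seed, 11L))
  centers <- place_discs_cpp(n, R, L, as.integer(shuffleSweeps))
  if (nrow(centers) == 0L) {
    stop(sprintf(
      "disc placement failed: area fraction %.3f not reachable for R = %.3g nm, L = %.3g nm (achievable maximum about %.2f)",
      A, R, L, .MAX_AREA_FRACTION))
  }
  new("DomainConfiguration", centers = centers, radius = R, boxLength = L)
}

#' Grid-sampled coverage of a disc configuration
#'
#' Monte-Carlo style estimate of the covered-area fraction from a regular
#' lattice of sample points, used to check consistency between the requested
#' area fraction and the realized packing.
#'
#' @param config a \code{\link{DomainConfiguration}}.
#' @param nGrid number of lattice points per box edge.
#' @return Estimated covered fraction in \code{[0, 1]}.
#' @export
coverageEstimate <- function(config, nGrid = 256L) {
  stopifnot(is(config, "DomainConfiguration"))
  if (nrow(config@centers) == 0L) return(0)
  coverage_grid_cpp(config@centers, config@radius, config@boxLength,
                    as.integer(nGrid))
}

#' In-domain probability of a partitioning probe
#'
#' For a probe with partition coefficient \code{K} (ratio of its surface
#' density inside vs outside nanodomains) on a membrane with domain area
#' fraction \code{A}, the probability of residing inside a domain is
#' \code{K A / (K A + 1 - A)}.
#'
#' @param K partition coefficient (>= 0).
#' @param A domain area fraction.
#' @return Probability in \code{[0, 1]}.
#' @export
partitionProbability <- function(K, A) {
  ifelse(A <= 0, 0, K * A / (K * A + (1 - A)))
}

#' Place donor and acceptor probes on a domain configuration
#'
#' Each probe is assigned to the domain phase with probability
#' \code{K A / (K A + 1 - A)} (its partition equilibrium), placed uniformly
#' within the assigned phase by rejection sampling, and split evenly
#' between the two leaflets. Domains are taken as registered across
#' leaflets (the same lateral discs apply to both). A donor-acceptor
#' excluded distance \code{rMin} is enforced at placement time.
#'
#' @param config a \code{\link{DomainConfiguration}}.
#' @param nDonors,nAcceptors probe counts (> 0).
#' @param partitionDonor,partitionAcceptor partition coefficients.
#' @param seed integer seed.
#' @param rMin minimum donor-acceptor separation (nm).
#' @param bilayerSep transbilayer fluorophore-plane separation (nm).
#' @return A \code{\link{ProbeConfiguration}}.
#' @export
placeProbes <- function(config, nDonors, nAcceptors,
                        partitionDonor = 1, partitionAcceptor = 1,
                        seed = 1L, rMin = 1.0, bilayerSep = 5.0) {
  stopifnot(is(config, "DomainConfiguration"), nDonors > 0, nAcceptors > 0)
  L <- config@boxLength
  Areal <- nrow(config@centers) * pi * config@radius^2 / L^2
  pD <- partitionProbability(partitionDonor, Areal)
  pA <- partitionProbability(partitionAcceptor, Areal)
  if (Areal >= 1 - 1e-12 && (pD < 1 || pA < 1))
    stop("bulk phase has zero area but probes must be placed there")
  set.seed(expandSeed(seed, 13L))
  res <- place_probes_cpp(config@centers, config@radius, L,
                          as.integer(nDonors), as.integer(nAcceptors),
                          pD, pA, rMin, bilayerSep)
  new("ProbeConfiguration",
      donorXY = res$donorXY, donorLeaflet = as.integer(res$donorLeaflet),
      donorInDomain = as.logical(res$donorInDomain),
      acceptorXY = res$acceptorXY,
      acceptorLeaflet = as.integer(res$acceptorLeaflet),
      acceptorInDomain = as.logical(res$acceptorInDomain),
      boxLength = L, bilayerSep = bilayerSep)
}

#' Minimum-image probe pair distance
#'
#' Lateral separation uses the minimum-image convention on the periodic
#' patch; pairs on opposite leaflets add the transbilayer separation in
#' quadrature: \code{d = sqrt(d_lat^2 + dz^2)}.
#'
#' @param p,q length-2 numeric lateral positions (nm).
#' @param leafletP,leafletQ leaflet labels (0/1).
#' @param boxLength box edge (nm).
#' @param bilayerSep leaflet plane separation (nm).
#' @return Distance in nm.
#' @examples
#' pairDistance(c(0, 0), c(99, 0), 0, 0, boxLength = 100)  # 1 nm
#' @export
pairDistance <- function(p, q, leafletP = 0L, leafletQ = 0L,
                         boxLength, bilayerSep = 0) {
  d <- abs(p - q)
  d <- pmin(d, boxLength - d)
  dz <- if (leafletP == leafletQ) 0 else bilayerSep
  sqrt(sum(d^2) + dz^2)
}
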