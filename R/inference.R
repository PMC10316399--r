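## The MC-FRET inverse problem: grid search over (R, A) matching simulated
## model decays to a measured TCSPC histogram with a Poisson-weighted
## chi-square, independently for each vesicle.

#' Default (R, A) fit grid
#'
#' Logarithmic in the domain radius (reported nanodomain radii span roughly
#' 5-122 nm, so the grid covers 2-200 nm) and linear in the area fraction
#' in steps of 0.05 up to the supported maximum of 0.65. The uniform
#' (no-domain) state enters as a single A = 0 node because the decay is
#' independent of R there.
#'
#' @param rRange radius range (nm), length 2.
#' @param nR number of radius nodes.
#' @param aMax maximum area fraction.
#' @param aStep area-fraction step.
#' @return data.frame with columns \code{radius_nm}, \code{area}.
#' @export
makeFitGrid <- function(rRange = c(2, 200), nR = 12L, aMax = 0.65,
                        aStep = 0.05) {
  rs <- exp(seq(log(rRange[1]), log(rRange[2]), length.out = nR))
  as <- seq(aStep, aMax, by = aStep)
  grid <- expand.grid(radius_nm = rs, area = as, KEEP.OUT.ATTRS = FALSE)
  rbind(data.frame(radius_nm = rs[1], area = 0), grid)
}

.nodeModel <- function(radius, area, params, bilayerSep, partitionDonor,
                       partitionAcceptor) {
  L <- if (area > 0) defaultBoxLength(radius, params@forsterRadius)
       else 40 * params@forsterRadius
  DomainModel(radius = max(radius, 1e-6), areaFraction = area, boxLength = L,
              bilayerSep = bilayerSep, partitionDonor = partitionDonor,
              partitionAcceptor = partitionAcceptor)
}

#' Simulate a library of model decays over a fit grid
#'
#' One ensemble decay per grid node, all nodes sharing the same
#' per-realization random streams (the same master-seed expansion) so that
#' Monte-Carlo jitter is correlated across nodes and largely cancels in
#' chi-square comparisons.
#'
#' @param grid data.frame with \code{radius_nm}, \code{area}.
#' @param params a \code{\link{FretParameters}}.
#' @param timeGrid time grid of the measured decays (ns).
#' @param nRealizations minimum Monte-Carlo realizations per node.
#' @param seed master seed.
#' @param bilayerSep,partitionDonor,partitionAcceptor,probeDensity model
#'   settings shared by all nodes.
#' @param minDonorSamples target total donor count per node; nodes with
#'   small boxes run more realizations until the target is met, keeping
#'   the Monte-Carlo jitter of the chi-square surface roughly uniform
#'   across the grid.
#' @return List with \code{nodes} (the grid), \code{intensity} and
#'   \code{se} matrices (channels x nodes), and the call settings.
#' @export
simulateDecayLibrary <- function(grid, params, timeGrid,
                                 nRealizations = 8L, seed = 1L,
                                 bilayerSep = 5.0, partitionDonor = 5.0,
                                 partitionAcceptor = 5.0,
                                 probeDensity = .DEFAULT_PROBE_DENSITY,
                                 minDonorSamples = 2e5) {
  nt <- length(timeGrid)
  intensity <- matrix(NA_real_, nt, nrow(grid))
  se <- matrix(NA_real_, nt, nrow(grid))
  valid <- rep(TRUE, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    dec <- tryCatch({
      model <- .nodeModel(grid$radius_nm[k], grid$area[k], params,
                          bilayerSep, partitionDonor, partitionAcceptor)
      n <- probeCount(model@boxLength, probeDensity)
      nr <- max(nRealizations, ceiling(minDonorSamples / n))
      ensembleDecay(model, params, nr, nDonors = n,
                    nAcceptors = n, seed = seed, timeGrid = timeGrid)
    }, error = function(e) {
      message(sprintf("grid node (R=%.3g, A=%.3g) failed: %s",
                      grid$radius_nm[k], grid$area[k], conditionMessage(e)))
      NULL
    })
    if (is.null(dec)) valid[k] <- FALSE
    else { intensity[, k] <- dec@intensity; se[, k] <- dec@se }
  }
  list(nodes = grid, intensity = intensity, se = se, valid = valid,
       params = params, timeGrid = timeGrid,
       nRealizations = as.integer(nRealizations), seed = as.integer(seed),
       bilayerSep = bilayerSep, partitionDonor = partitionDonor,
       partitionAcceptor = partitionAcceptor, probeDensity = probeDensity,
       minDonorSamples = minDonorSamples)
}

## Scale a normalized model shape to the measured histogram: the
## amplitude is fixed by matching the total expected count to the total
## measured count given the background, so the only fitted nuisance is a
## non-negative constant background (1-D minimization of the
## Poisson-weighted chi-square). Leaving the amplitude free as well
## would flatten the (R, A) chi-square ridge and destroy radius
## identifiability.
.scaleToCounts <- function(counts, shape) {
  n <- length(counts)
  S <- sum(counts)
  Sf <- sum(shape)
  evalBeta <- function(beta) {
    alpha <- max((S - n * beta) / Sf, 0)
    m <- alpha * shape + beta
    sum((counts - m)^2 / pmax(m, 1))
  }
  upper <- S / n
  opt <- optimize(evalBeta, c(0, upper), tol = upper * 1e-6 + 1e-12)
  beta <- opt$minimum
  # the boundary beta = 0 is a frequent optimum; optimize() cannot land
  # exactly on it, so check it explicitly
  if (evalBeta(0) <= opt$objective) beta <- 0
  alpha <- max((S - n * beta) / Sf, 0)
  m <- alpha * shape + beta
  list(alpha = alpha, beta = beta,
       chisq = sum((counts - m)^2 / pmax(m, 1)))
}

## Argmin with tie handling. Exact ties break toward smaller area
## fraction, then smaller radius. Additionally, the uniform (A = 0) node
## is preferred whenever it lies within `nullTol` of the minimum:
## domains far below the Forster radius produce decays identical to the
## uniform membrane, so the no-domain state is the parsimonious call
## among such indistinguishable fits. The tolerance is matched to the
## Monte-Carlo resolution of the high-precision model pass.
.orderNodes <- function(chisq, area, radius, nullTol = 0) {
  lo <- min(chisq, na.rm = TRUE)
  tied <- which(is.finite(chisq) & chisq <= lo + 1e-9)
  best <- tied[order(area[tied], radius[tied])[1]]
  if (nullTol > 0) {
    nulls <- which(is.finite(chisq) & area == 0)
    if (length(nulls) && min(chisq[nulls]) <= lo + nullTol)
      best <- nulls[which.min(chisq[nulls])]
  }
  best
}

#' Fit the nanodomain model to one measured decay
#'
#' Scores every (R, A) grid node by simulating the corresponding ensemble
#' decay, scaling it to the measured counts with a fitted amplitude and
#' non-negative constant background, and computing the Poisson-weighted
#' chi-square \eqn{\sum_k (c_k - m_k)^2 / \max(m_k, 1)}. Ties are broken
#' toward smaller A, then smaller R. One local bisection pass around the
#' grid minimum (geometric midpoints in R, half-steps in A) refines the
#' estimate.
#'
#' @param measured a \code{\link{DecayCurve}} carrying counts.
#' @param grid fit grid (see \code{\link{makeFitGrid}}).
#' @param params a \code{\link{FretParameters}}.
#' @param nRealizations minimum Monte-Carlo realizations per node.
#' @param seed master seed of the fit.
#' @param library optional precomputed \code{\link{simulateDecayLibrary}}
#'   result (shared across vesicles of a cohort).
#' @param refine logical, run the local refinement pass.
#' @param guvId identifier stored in the result.
#' @param tieTolerance chi-square margin within which the uniform
#'   (A = 0) node counts as tied with the minimum and is preferred (the
#'   parsimonious call for decays that sub-resolution domain states
#'   reproduce exactly); exact ties among domain nodes resolve toward
#'   smaller A, then smaller R. The default window of 3 covers the
#'   spread of the minimum over several exactly-degenerate nodes at the
#'   high-precision pass's Monte-Carlo resolution (~0.7 chi-square per
#'   node) while staying far below the smallest real contrast to the
#'   uniform state seen for any domain scenario (~40).
#' @param refineCache optional environment memoizing high-precision node
#'   decays so cohort fits do not resimulate shared nodes.
#' @param candidateMargin chi-square margin above the coarse minimum
#'   within which grid nodes are re-scored at high precision.
#' @param maxCandidates cap on the number of re-scored nodes.
#' @param stage2Samples donor-sample target of the high-precision pass.
#' @param ... model settings passed to \code{simulateDecayLibrary}.
#' @return A \code{\link{FitResult}}.
#' @export
fitGUV <- function(measured, grid = makeFitGrid(), params,
                   nRealizations = 8L, seed = 1L, library = NULL,
                   refine = TRUE, guvId = "guv", tieTolerance = 3,
                   refineCache = NULL, candidateMargin = 15,
                   maxCandidates = 6L, stage2Samples = 1e6, ...) {
  stopifnot(is(measured, "DecayCurve"))
  counts <- measured@counts
  if (!length(counts) || sum(counts) <= 0)
    stop("measured decay has no (or all-zero) counts")
  if (is.null(library))
    library <- simulateDecayLibrary(grid, params, measured@time,
                                    nRealizations, seed, ...)
  nodes <- library$nodes
  fits <- lapply(seq_len(nrow(nodes)), function(k) {
    if (!library$valid[k]) return(list(alpha = NA, beta = NA, chisq = Inf))
    .scaleToCounts(counts, library$intensity[, k])
  })
  surface <- data.frame(
    radius_nm = nodes$radius_nm, area = nodes$area,
    chisq = vapply(fits, `[[`, numeric(1), "chisq"),
    amplitude = vapply(fits, function(f) as.numeric(f$alpha), numeric(1)),
    background = vapply(fits, function(f) as.numeric(f$beta), numeric(1)),
    valid = library$valid, refined = FALSE)
  if (!any(surface$valid)) stop("no valid grid node; fit impossible")

  if (is.null(refineCache)) refineCache <- new.env(parent = emptyenv())

  # high-precision rescoring of one batch of candidate nodes (cached)
  rescore <- function(cand) {
    keys <- sprintf("%.8g_%.8g", cand$radius_nm, cand$area)
    miss <- !vapply(keys, exists, logical(1), envir = refineCache)
    if (any(miss)) {
      ref <- simulateDecayLibrary(cand[miss, , drop = FALSE], params,
                                  measured@time,
                                  library$nRealizations, library$seed,
                                  bilayerSep = library$bilayerSep,
                                  partitionDonor = library$partitionDonor,
                                  partitionAcceptor = library$partitionAcceptor,
                                  probeDensity = library$probeDensity,
                                  minDonorSamples = stage2Samples)
      mi <- which(miss)
      for (k in seq_along(mi))
        assign(keys[mi[k]],
               if (ref$valid[k]) ref$intensity[, k] else NULL,
               envir = refineCache)
    }
    do.call(rbind, lapply(seq_len(nrow(cand)), function(k) {
      shape <- get(keys[k], envir = refineCache)
      if (is.null(shape))
        return(data.frame(radius_nm = cand$radius_nm[k],
                          area = cand$area[k], chisq = Inf,
                          amplitude = NA_real_, background = NA_real_,
                          valid = FALSE, refined = TRUE))
      f <- .scaleToCounts(counts, shape)
      data.frame(radius_nm = cand$radius_nm[k], area = cand$area[k],
                 chisq = f$chisq, amplitude = f$alpha,
                 background = f$beta, valid = TRUE, refined = TRUE)
    }))
  }

  if (refine) {
    # stage 2: rescore every node statistically close to the coarse
    # minimum at higher precision, so the final comparison is made at a
    # Monte-Carlo resolution matching the small tie tolerance
    lo <- min(surface$chisq[surface$valid])
    candIdx <- which(surface$valid & surface$chisq <= lo + candidateMargin)
    candIdx <- candIdx[order(surface$chisq[candIdx])]
    candIdx <- head(candIdx, maxCandidates)
    # the uniform node is always rescored when it is competitive at all,
    # so the null-preference rule sees it at full precision
    nullIdx <- which(surface$valid & surface$area == 0 &
                       surface$chisq <= lo + candidateMargin)
    candIdx <- union(candIdx, nullIdx)
    stage2 <- rescore(surface[candIdx, c("radius_nm", "area")])
    best2 <- .orderNodes(stage2$chisq, stage2$area, stage2$radius_nm,
                         tieTolerance)
    # local bisection around the high-precision winner
    cand <- .refinementNodes(stage2$radius_nm[best2], stage2$area[best2],
                             nodes)
    if (nrow(cand)) stage2 <- rbind(stage2, rescore(cand))
    surface <- rbind(surface, stage2)
    final <- stage2[.orderNodes(stage2$chisq, stage2$area,
                                stage2$radius_nm, tieTolerance), ]
  } else {
    final <- surface[.orderNodes(surface$chisq, surface$area,
                                 surface$radius_nm, tieTolerance), ]
  }

  new("FitResult", guvId = as.character(guvId),
      radiusHat = final$radius_nm, areaHat = final$area,
      chiSquare = final$chisq, surface = surface,
      seed = as.integer(seed), tieTolerance = as.numeric(tieTolerance))
}

## Candidate nodes for the local bisection pass around a grid minimum.
.refinementNodes <- function(rBest, aBest, nodes) {
  out <- list()
  rs <- sort(unique(nodes$radius_nm[nodes$area > 0]))
  as <- sort(unique(nodes$area))
  if (aBest > 0) {
    i <- which.min(abs(rs - rBest))
    if (i > 1L)
      out <- c(out, list(data.frame(radius_nm = sqrt(rs[i - 1] * rs[i]),
                                    area = aBest)))
    if (i < length(rs))
      out <- c(out, list(data.frame(radius_nm = sqrt(rs[i] * rs[i + 1]),
                                    area = aBest)))
  }
  aStep <- if (length(as) > 1L) min(diff(as)) else 0.05
  for (a in c(aBest - aStep / 2, aBest + aStep / 2)) {
    if (a > 0 && a <= max(as))
      out <- c(out, list(data.frame(
        radius_nm = if (aBest > 0) rBest else min(rs), area = a)))
  }
  if (!length(out)) return(data.frame(radius_nm = numeric(),
                                      area = numeric()))
  unique(do.call(rbind, out))
}

#' Fit a cohort of vesicle decays with a shared model library
#'
#' All vesicles are fitted against the same simulated decay library (the
#' measured time grids must match), mirroring per-vesicle independent
#' analysis while avoiding recomputing the forward model.
#'
#' @param decays named list of \code{\link{DecayCurve}} objects with counts.
#' @inheritParams fitGUV
#' @return List of \code{\link{FitResult}}, one per decay.
#' @export
fitCohort <- function(decays, grid = makeFitGrid(), params,
                      nRealizations = 8L, seed = 1L, refine = TRUE,
                      tieTolerance = 3, candidateMargin = 15,
                      maxCandidates = 6L, stage2Samples = 1e6, ...) {
  stopifnot(length(decays) >= 1L)
  t0 <- decays[[1]]@time
  for (d in decays)
    if (length(d@time) != length(t0) || max(abs(d@time - t0)) > 1e-9)
      stop("all cohort decays must share one time grid")
  lib <- simulateDecayLibrary(grid, params, t0, nRealizations, seed, ...)
  ids <- names(decays)
  if (is.null(ids)) ids <- sprintf("guv%02d", seq_along(decays))
  cache <- new.env(parent = emptyenv())
  out <- lapply(seq_along(decays), function(i) {
    fitGUV(decays[[i]], grid, params, nRealizations, seed, library = lib,
           refine = refine, guvId = ids[i], tieTolerance = tieTolerance,
           refineCache = cache, candidateMargin = candidateMargin,
           maxCandidates = maxCandidates, stage2Samples = stage2Samples)
  })
  names(out) <- ids
  out
}

#' Aggregate per-vesicle fits into a cohort distribution summary
#'
#' Arithmetic means of the per-vesicle radius and coverage estimates plus
#' frequency histograms, the per-composition summary of a cohort of
#' vesicles.
#'
#' @param results list of \code{\link{FitResult}}.
#' @param binEdgesR histogram bin edges for the radius (nm); default covers
#'   the observed range in 10 bins.
#' @param binEdgesA bin edges for the area fraction; default 0-0.65 in
#'   steps of 0.05.
#' @return A \code{\link{DistributionSummary}}.
#' @export
aggregateGUVs <- function(results, binEdgesR = NULL, binEdgesA = NULL) {
  if (!length(results)) stop("no fit results to aggregate")
  stopifnot(all(vapply(results, is, logical(1), "FitResult")))
  rs <- vapply(results, radiusHat, numeric(1))
  as <- vapply(results, areaHat, numeric(1))
  if (is.null(binEdgesR)) {
    lo <- floor(min(rs)); hi <- ceiling(max(rs))
    if (hi <= lo) hi <- lo + 1
    binEdgesR <- seq(lo, hi, length.out = 11L)
  }
  if (is.null(binEdgesA)) binEdgesA <- seq(0, 0.65, by = 0.05)
  histOf <- function(x, edges) {
    edges[1] <- min(edges[1], min(x)); edges[length(edges)] <-
      max(edges[length(edges)], max(x))
    counts <- hist(x, breaks = edges, plot = FALSE,
                   include.lowest = TRUE, right = FALSE)$counts
    data.frame(lower = head(edges, -1), upper = tail(edges, -1),
               count = counts)
  }
  new("DistributionSummary", results = results,
      meanRadius = mean(rs), meanArea = mean(as),
      histRadius = histOf(rs, binEdgesR), histArea = histOf(as, binEdgesA))
}
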