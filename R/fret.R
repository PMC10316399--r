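## Forward simulation of time-resolved donor decays.
##
## The donor ensemble is static over the excited-state lifetime, transfer
## is donor -> acceptor only, and each donor i decays as
## exp(-(t/tauD) * (1 + s_i)) with s_i = sum_j (R0 / r_ij)^6 over all
## acceptors j.

## Default per-leaflet probe surface density (nm^-2): 0.5 mol % of lipids
## at ~0.65 nm^2 area per lipid.
.DEFAULT_PROBE_DENSITY <- 0.005 / 0.65

#' Default TCSPC-style time grid
#'
#' 1024 channels of width \code{tauD / 64}, spanning 16 donor lifetimes and
#' starting at t = 0.
#'
#' @param params a \code{\link{FretParameters}} (or numeric \code{tauD}).
#' @param nChannels number of channels.
#' @param channelsPerLifetime channels per donor lifetime.
#' @return Numeric time grid (ns).
#' @export
defaultTimeGrid <- function(params, nChannels = 1024L,
                            channelsPerLifetime = 64L) {
  tauD <- if (is(params, "FretParameters")) params@donorLifetime
          else as.numeric(params)
  dt <- tauD / channelsPerLifetime
  seq(0, by = dt, length.out = nChannels)
}

#' Expected donor and acceptor counts for a model box
#'
#' Probe copy numbers corresponding to a surface density per leaflet (both
#' leaflets are labeled), rounded to the nearest even integer so the two
#' leaflets carry equal numbers.
#'
#' @param boxLength lateral box edge (nm).
#' @param density per-leaflet probe surface density (nm^-2).
#' @return Integer count (total over both leaflets).
#' @export
probeCount <- function(boxLength, density = .DEFAULT_PROBE_DENSITY) {
  max(2L, 2L * as.integer(round(density * boxLength^2)))
}

#' Donor decay of a single probe configuration
#'
#' Evaluates \deqn{F(t) = \frac{1}{N_D} \sum_i \exp\left(-\frac{t}{\tau_D}
#' \left[1 + \sum_j (R_0 / r_{ij})^6\right]\right)} term by term with
#' minimum-image pair distances (cross-leaflet pairs add the bilayer
#' separation in quadrature). Positions are static during the decay.
#'
#' @param probes a \code{\link{ProbeConfiguration}}.
#' @param params a \code{\link{FretParameters}}.
#' @param timeGrid time grid in ns (default \code{\link{defaultTimeGrid}}).
#' @return A \code{\link{DecayCurve}} with normalized intensity.
#' @export
donorDecaySnapshot <- function(probes, params,
                               timeGrid = defaultTimeGrid(params)) {
  stopifnot(is(probes, "ProbeConfiguration"), is(params, "FretParameters"))
  s <- rate_sums_cpp(probes@donorXY, probes@donorLeaflet,
                     probes@acceptorXY, probes@acceptorLeaflet,
                     probes@boxLength, probes@bilayerSep,
                     params@forsterRadius, params@rMin, -1)
  f <- decay_from_rates_cpp(s, timeGrid / params@donorLifetime,
                            length(s) + 1L, length(s) + 1L)
  DecayCurve(timeGrid, intensity = f,
             metadata = list(tauD = params@donorLifetime,
                             R0 = params@forsterRadius, kind = "snapshot"))
}

## One forward realization: discs + probes + per-donor rate sums.
## `cutoffFactor` truncates the acceptor sum at cutoffFactor * R0 with a
## mean-field tail; <= 0 disables truncation.
.realizationRates <- function(model, params, nDonors, nAcceptors, seed,
                              cutoffFactor = 4) {
  cfg <- placeDomains(model, seed)
  pr <- placeProbes(cfg, nDonors, nAcceptors,
                    model@partitionDonor, model@partitionAcceptor,
                    seed = expandSeed(seed, 17L), rMin = params@rMin,
                    bilayerSep = model@bilayerSep)
  cutoff <- if (cutoffFactor > 0) cutoffFactor * params@forsterRadius else -1
  rate_sums_cpp(pr@donorXY, pr@donorLeaflet, pr@acceptorXY,
                pr@acceptorLeaflet, pr@boxLength, pr@bilayerSep,
                params@forsterRadius, params@rMin, cutoff)
}

#' Ensemble-averaged Monte-Carlo donor decay
#'
#' Averages \code{\link{donorDecaySnapshot}} over independent realizations
#' of the domain and probe placement, attaching the per-channel Monte-Carlo
#' standard error of the mean.
#'
#' @param model a \code{\link{DomainModel}}.
#' @param params a \code{\link{FretParameters}}.
#' @param nRealizations number of independent realizations (>= 1).
#' @param nDonors,nAcceptors probe counts per realization; default from the
#'   0.5 mol \% labeling density and the model box.
#' @param seed integer master seed.
#' @param timeGrid time grid (ns).
#' @param cutoffFactor acceptor-sum truncation radius in units of R0
#'   (mean-field tail beyond); set <= 0 for exact all-pairs sums.
#' @param nBatches batches for the batch-means standard error (more
#'   batches give the SE estimate more degrees of freedom).
#' @return A \code{\link{DecayCurve}} with intensity and \code{se}.
#' @export
ensembleDecay <- function(model, params, nRealizations = 10L,
                          nDonors = probeCount(model@boxLength),
                          nAcceptors = probeCount(model@boxLength),
                          seed = 1L,
                          timeGrid = defaultTimeGrid(params),
                          cutoffFactor = 4, nBatches = 10L) {
  stopifnot(is(model, "DomainModel"), is(params, "FretParameters"),
            nRealizations >= 1)
  x <- timeGrid / params@donorLifetime
  # realizations are pooled into batches; the decay is evaluated once per
  # batch from the pooled per-donor rate sums (equal donor counts per
  # realization make the pooled evaluation exactly the realization mean),
  # and the Monte-Carlo standard error comes from the batch means
  nBatch <- min(nRealizations, as.integer(nBatches))
  pool <- vector("list", nBatch)
  for (r in seq_len(nRealizations)) {
    s <- .realizationRates(model, params, nDonors, nAcceptors,
                           seed = expandSeed(seed, 100L, r), cutoffFactor)
    b <- ((r - 1L) %% nBatch) + 1L
    pool[[b]] <- c(pool[[b]], list(s))
  }
  sizes <- vapply(pool, length, integer(1))
  acc <- vapply(pool, function(p)
    decay_from_rates_cpp(unlist(p), x, 4096L, 2048L),
    numeric(length(timeGrid)))
  acc <- matrix(acc, nrow = length(timeGrid))
  f <- as.numeric(acc %*% (sizes / nRealizations))
  se <- if (nBatch > 1)
    apply(acc, 1L, sd) / sqrt(nBatch) else rep(0, length(timeGrid))
  DecayCurve(timeGrid, intensity = f, se = se,
             metadata = list(tauD = params@donorLifetime,
                             R0 = params@forsterRadius,
                             nRealizations = nRealizations,
                             nDonors = nDonors, nAcceptors = nAcceptors,
                             seed = seed, kind = "ensemble"))
}

#' Analytic decay for acceptors uniform in infinite planes
#'
#' For acceptors Poisson-distributed with surface density \code{sigmaA} in
#' each fluorophore plane, \deqn{F(t) = e^{-t/\tau_D} \prod_p \exp\left(
#' -2\pi\sigma_A \int_{a_p}^{\infty} \left[1 - e^{-(t/\tau_D)(R_0/r)^6}
#' \right] r\,dr\right)} with lower limit \code{rMin} for the donor's own
#' plane and the bilayer separation for the opposite plane. For
#' \code{rMin = 0} (single plane) the exponent has the closed form
#' \eqn{\pi \sigma_A R_0^2 \Gamma(2/3) (t/\tau_D)^{1/3}}, used as an
#' internal cross-check.
#'
#' @param sigmaA acceptor surface density per plane (nm^-2, >= 0).
#' @param params a \code{\link{FretParameters}}.
#' @param timeGrid time grid (ns).
#' @param bilayerSep plane separation (nm); \code{NULL} for a single plane.
#' @param relTol integration tolerance.
#' @return A \code{\link{DecayCurve}}.
#' @export
uniformPlaneDecay <- function(sigmaA, params,
                              timeGrid = defaultTimeGrid(params),
                              bilayerSep = NULL, relTol = 1e-9) {
  stopifnot(sigmaA >= 0, is(params, "FretParameters"))
  R0 <- params@forsterRadius
  x <- timeGrid / params@donorLifetime
  lowers <- c(params@rMin, bilayerSep)
  g <- vapply(x, function(xi) {
    if (xi <= 0 || sigmaA == 0) return(0)
    tot <- 0
    for (a in lowers) {
      integrand <- function(r) (1 - exp(-xi * (R0 / r)^6)) * r
      upper <- max(R0 * (xi / 1e-12)^(1 / 6), a * 2, R0 * 2)
      lo <- max(a, 1e-9)
      int <- integrate(integrand, lower = lo, upper = upper,
                       rel.tol = relTol, abs.tol = 1e-12,
                       subdivisions = 500L)
      if (int$message != "OK")
        stop("plane integral did not converge: ", int$message,
             " (abs.error ", format(int$abs.error), ")")
      tot <- tot + 2 * pi * sigmaA * int$value
    }
    tot
  }, numeric(1))
  DecayCurve(timeGrid, intensity = exp(-x - g),
             metadata = list(tauD = params@donorLifetime, R0 = R0,
                             sigmaA = sigmaA, kind = "uniform-plane"))
}

#' Closed-form single-plane quench exponent at rMin = 0
#'
#' \eqn{\pi \sigma_A R_0^2 \Gamma(2/3) x^{1/3}} with \eqn{x = t/\tau_D}.
#'
#' @param sigmaA acceptor density (nm^-2).
#' @param forsterRadius R0 (nm).
#' @param x reduced time t/tauD.
#' @return The exponent value(s).
#' @export
planeQuenchExponent <- function(sigmaA, forsterRadius, x) {
  pi * sigmaA * forsterRadius^2 * gamma(2 / 3) * x^(1 / 3)
}

#' FRET efficiency of a model decay
#'
#' \eqn{E = 1 - \frac{1}{\tau_D}\int_0^\infty F(t)\,dt}, evaluated by the
#' trapezoidal rule and clamped to \code{[0, 1]}. If the grid spans fewer
#' than 10 donor lifetimes a single-exponential tail correction from the
#' last channel is applied and recorded in the result's
#' \code{"truncated"} attribute.
#'
#' @param decay a \code{\link{DecayCurve}} with normalized intensity.
#' @param donorLifetime tau_D in ns.
#' @return Efficiency in \code{[0, 1]} (attribute \code{truncated} flags a
#'   short grid).
#' @export
fretEfficiency <- function(decay, donorLifetime) {
  stopifnot(is(decay, "DecayCurve"), length(decay@intensity) > 0)
  t <- decay@time
  f <- decay@intensity
  if (abs(f[1] - 1) > 1e-6)
    stop("fretEfficiency expects a normalized model decay (F(0) = 1)")
  integral <- sum(diff(t) * (head(f, -1) + tail(f, -1)) / 2)
  truncated <- max(t) < 10 * donorLifetime
  if (truncated) {
    # tail correction: continue the final channel with the unquenched rate
    integral <- integral + f[length(f)] * donorLifetime
    warning("decay grid shorter than 10 donor lifetimes; ",
            "single-exponential tail correction applied")
  }
  e <- 1 - integral / donorLifetime
  e <- min(max(e, 0), 1)
  attr(e, "truncated") <- truncated
  e
}

#' Convolve a model decay with a tabulated instrument response
#'
#' Discrete causal convolution of a normalized model decay with an
#' instrument response function sampled on the same channel width; the
#' IRF is normalized to unit sum and the result is renormalized to
#' F(0-peak) = 1. Measured decays can then be fitted against
#' IRF-convolved model libraries by passing the convolved curves.
#'
#' @param decay a \code{\link{DecayCurve}} with model intensity.
#' @param irf numeric vector of IRF samples (same channel width).
#' @return A \code{\link{DecayCurve}} with the convolved intensity.
#' @export
convolveIRF <- function(decay, irf) {
  stopifnot(is(decay, "DecayCurve"), length(decay@intensity) > 0,
            length(irf) >= 1, all(irf >= 0), sum(irf) > 0)
  irf <- irf / sum(irf)
  n <- length(decay@intensity)
  out <- stats::convolve(decay@intensity, rev(irf), type = "open")[1:n]
  out <- out / max(out)
  DecayCurve(decay@time, intensity = out,
             metadata = c(decay@metadata, list(irf = TRUE)))
}
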