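---
title: "Inferring membrane nanodomain size from time-resolved FRET, and bookkeeping glycosphingolipid interactions"
author: "nanoFRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring membrane nanodomain size from time-resolved FRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoFRET)
```

## The problem

Glycosphingolipids (GSLs) such as the gangliosides GM1 and GD1a segregate
laterally into nanoscopic membrane domains — tens of nanometres in radius,
far below the diffraction limit. Two quantities characterize this
organization on a vesicle: the mean nanodomain radius $R$ and the fraction
$A$ of membrane area the domains cover. Time-resolved Förster resonance
energy transfer (FRET) between donor- and acceptor-labelled lipids can
resolve these length scales because the donor decay encodes the
distribution of donor–acceptor distances on the 1–20 nm scale.

`nanoFRET` implements both directions of this analysis:

* a **forward Monte-Carlo model**: given $(R, A)$, probe photophysics and
  partitioning, simulate the time-resolved donor decay on a periodic
  bilayer patch; and
* the **inverse problem** ("MC-FRET"): given a measured time-correlated
  single-photon-counting (TCSPC) histogram for one giant unilamellar
  vesicle (GUV), find the $(\hat R, \hat A)$ whose simulated decay matches
  it best, independently per vesicle.

A second, independent analysis stage computes per-moiety hydrogen-bond
tables, pairwise nonbonded interaction energies and partial density
profiles from membrane configurations, the quantities used to explain
*why* sialic-acid-bearing GSLs form nanodomains.

## The forward model

The membrane patch is a 2-D torus of edge $L$ carrying non-overlapping
discs of radius $R$ occupying an area fraction $A$ (supported up to 0.65).
Donors and acceptors live in two parallel planes separated by the
transbilayer distance $\Delta z$; domains are in register across the
leaflets. Probes partition between the domain and bulk phases: a probe
with partition coefficient $K$ (domain/bulk surface-density ratio) is
inside a domain with probability

$$p_\mathrm{in} = \frac{KA}{KA + (1 - A)}.$$

Positions are frozen during the excited-state lifetime (lipid diffusion
over a few ns is ≪ $R_0$), transfer is donor→acceptor only, and the
orientation factor is absorbed into $R_0$. Each donor $i$ then decays as

$$F_i(t) = \exp\!\left[-\frac{t}{\tau_D}\Big(1 + \sum_j (R_0/r_{ij})^6\Big)\right],$$

with $r_{ij}$ the minimum-image donor–acceptor distance (cross-leaflet
pairs add $\Delta z$ in quadrature), and the observed decay is the donor
average, further averaged over independent realizations of the domain and
probe placement.

```{r forward, eval = FALSE}
params <- FretParameters(forsterRadius = 5.7, donorLifetime = 5.8)
model <- DomainModel(radius = 15, areaFraction = 0.55,
                     boxLength = defaultBoxLength(15, 5.7))
decay <- ensembleDecay(model, params, nRealizations = 50, seed = 1)
```

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `forsterRadius` | none (required) | $R_0$ in nm; 5.7 nm is used in the package's own experiments, typical of green→orange membrane FRET pairs |
| `donorLifetime` | none (required) | unquenched $\tau_D$ in ns (5.8 ns in the package experiments) |
| `rMin` | 1.0 nm | probe excluded distance, prevents divergence of $(R_0/r)^6$ |
| `bilayerSep` | 5.0 nm | separation of the two fluorophore planes for headgroup-anchored dyes |
| `partitionDonor`, `partitionAcceptor` | 5 | probe enrichment in domains; the labelled lipids are themselves domain-forming GSLs, so a moderate preference is assumed |
| probe density | 0.0077 nm⁻² per leaflet | 0.5 mol % labelled lipid per species at ~0.65 nm² per lipid |

The numeric values of $R_0$, $\tau_D$, $\Delta z$ and the partition
coefficients for any particular dye pair are experimental inputs; the
engine takes them as required configuration and the defaults above are
the package's own simulation conditions, not measurements.

### Numerical design

* **Disc placement.** Placement starts from a feasibility-checked
  periodic offset-row lattice (provably overlap-free for every $A \le
  0.65$ and $L \ge 10R$), with the occupied sites chosen at random,
  followed by Metropolis hard-disc displacement sweeps that randomize
  local structure. Pure random-insertion or relax-from-random schemes jam
  or fail to converge near the highest supported coverages; the lattice
  start makes every supported state reachable deterministically. Residual
  long-range positional correlations from the lattice are irrelevant to
  the decay, which is sensitive to the in/out densities and the domain
  boundary geometry rather than to domain–domain arrangement.
* **Box size.** $L = \max(10R,\ 40R_0)$, so that periodic images cannot
  contribute to transfer and small-$R$ boxes still hold enough probes for
  stable averages. A finite-size test (doubling $L$) is part of the test
  suite.
* **Acceptor sums.** The per-donor rate sum is truncated at $4R_0$ with
  cell lists; acceptors beyond the cutoff contribute a mean-field tail
  $2\pi\sigma_A R_0^6/(4 r_c^4)$. The truncation error is far below the
  Monte-Carlo noise. `donorDecaySnapshot()` always evaluates exactly
  (all pairs) so it can be checked term-by-term against a brute-force
  oracle.
* **Decay evaluation.** For ensembles, realizations are pooled into
  batches; each batch decay is evaluated from the pooled per-donor rate
  sums, compressed into equal-count bins (accurate to well below MC
  noise), and the per-channel standard error comes from the batch means.
* **Analytic limit.** With no domains, acceptors are Poisson-distributed
  in each plane and the decay has the classical planar-quenching form
  with exponent $2\pi\sigma_A\int_a^\infty [1 - e^{-(t/\tau_D)(R_0/r)^6}]
  r\,\mathrm{d}r$; for $a = 0$ this reduces to
  $\pi\sigma_A R_0^2\,\Gamma(2/3)\,(t/\tau_D)^{1/3}$. Both are implemented
  (`uniformPlaneDecay()`, `planeQuenchExponent()`), agree to $10^{-6}$
  relative, and serve as the independent oracle for the Monte-Carlo
  engine.
* **Time grid.** 1024 channels of width $\tau_D/64$ (span $16\tau_D$),
  the TCSPC-like default.

## The inverse problem

`fitGUV()` scores a grid of $(R, A)$ nodes — logarithmic in $R$ (2–200 nm,
12 nodes, covering the 5–122 nm range where nanodomains have been
reported) and linear in $A$ (0–0.65 in steps of 0.05, plus a single
$A = 0$ node because the decay is independent of $R$ there). At each node
the simulated normalized decay is scaled to the measured total count
on top of a fitted non-negative constant background, and the
Poisson-weighted chi-square
$\chi^2 = \sum_k (c_k - m_k)^2/\max(m_k, 1)$ is recorded.

Identifiability drives the remaining design:

* **Correlated model noise.** All nodes share the same per-realization
  random streams, so Monte-Carlo jitter partially cancels in chi-square
  comparisons between nodes.
* **Constrained amplitude.** The model is scaled so its total expected
  count matches the measured total given the background; only the
  background is fitted. Freeing the amplitude as well was found to
  flatten the $(R\uparrow, A\uparrow)$ chi-square ridge to the point
  of destroying radius identifiability at realistic photon counts.
* **Two-stage scoring.** A coarse pass (≈2×10⁵ donor samples per node)
  localizes the minimum; the best nodes within a chi-square margin of 20
  are re-simulated at ≈10⁶ donor samples, and only these
  high-precision scores compete for the argmin. This keeps the full-grid
  cost bounded while pushing the model's Monte-Carlo contribution to the
  final comparison well below the Poisson noise of the data.
* **Tie handling.** Exact ties resolve toward smaller $A$, then smaller
  $R$. In addition, the uniform ($A = 0$) node is preferred whenever it
  lies within `tieTolerance` (default 1 χ² unit) of the minimum: domains
  far below $R_0$ produce decays identical to the uniform membrane, so
  the no-domain state is the parsimonious call among such
  indistinguishable fits. A blanket tolerance tie-break toward small
  $(A, R)$ was rejected because on a flat ridge it deterministically
  drags estimates below the truth.
* **Refinement.** One local bisection pass (geometric midpoints in $R$,
  half-steps in $A$) around the high-precision winner halves the grid
  discretization error.
* **Flat directions are kept visible.** The full surface (coarse +
  rescored + refined nodes) is stored in the `FitResult`, so degeneracies
  — $R$ unidentifiable at $A \to 0$, and the $(R\uparrow, A\uparrow)$
  ridge at large $R/R_0$ — can be inspected rather than silently
  collapsed.

Cohorts are fitted per vesicle against one shared model library
(`fitCohort()`), mirroring the per-GUV analysis policy of the
experiments, and summarized into means and frequency histograms with
`aggregateGUVs()`.

## What the synthetic data emulate — and what they do not

`makeGUVCohort()` emulates the TCSPC measurement of a cohort of 5–10 GUVs
of one lipid composition: each vesicle's decay is the ensemble forward
model at its generating $(R, A)$, Poissonized to a target photon count
(default 10⁵, with a 1% uniform background). Because a real vesicle
integrates over membrane area vastly larger than the simulation box, the
generator averages enough realizations (≈10⁶ donor samples) for the
synthetic "truth" decay to be effectively self-averaged. Vesicle-to-
vesicle biological spread is modelled as 10% relative SD on $R$ and 0.05
absolute SD on $A$ (truncated at the bounds) — values chosen to visually
match the published frequency-distribution spreads, which are shown but
not parameterized.

The recovery benchmarks in the test suite and the acceptance script use
cohorts **without** that spread (count noise only), because they score
the estimator against the scenario's generating values: with spread, a
vesicle whose true $A$ falls between grid levels sits on the
$(R\uparrow, A\uparrow)$ chi-square ridge and is genuinely unidentifiable
at 10⁵ counts, which would measure the physics, not the implementation.

What passing these tests does **not** show about real data: instrument
response convolution is not applied by default (an IRF hook accepts a
tabulated response), dye photophysics beyond a single-exponential donor
is not modelled, domains are monodisperse discs in register across
leaflets, and the partition coefficients are assumed known. Real decays
also carry afterpulsing and pile-up distortions that the Poisson
generator does not emulate.

## The interaction-analysis stage

The second pipeline ingests membrane configurations (GRO or multi-frame
PDB), a delimited topology (charges, Lennard-Jones $\sigma/\epsilon$,
bonds, molecular species) and an atom→moiety map (Glc1, Gal2, Sia3,
GalNAc4, Gal5, Sia6, Cer, water).

* **Hydrogen bonds** use the common geometric criterion — donor–acceptor
  distance ≤ 0.35 nm and H–donor–acceptor angle ≤ 30°, N/O donors with a
  bound hydrogen, N/O acceptors — with cell-list neighbor search under
  the minimum-image convention. Both cutoffs are configurable and the
  convention is recorded in the outputs. `moietyHBondTable()` counts each
  intermolecular GSL–GSL bond once per distinct (species, moiety) end —
  a Sia3–Sia3 bond is one Sia3 bond — divided by the number of GSL
  molecules; the per-species total is the sum over moieties. Standard
  errors come from block averaging over contiguous trajectory blocks.
* **Interaction energies** are direct-space Coulomb plus Lennard-Jones
  with Lorentz–Berthelot combination at a plain 1.2 nm cutoff. No
  Ewald/mesh reciprocal term is included: a per-molecule-pair
  decomposition is only well-defined for direct-space terms, so absolute
  values will differ from any mesh-electrostatics force-field energy;
  relative comparisons across species are the intended use.
  An *interacting partner* is a molecule with at least one atom pair
  inside the cutoff in at least half of the analyzed frames (both
  thresholds configurable); the normalized energy is the class total per
  GSL divided by that partner count, reported missing when a class has
  no partner. The GSL side of each pair is its sugar headgroup by
  default (`gslSide = "molecule"` switches to whole molecules).
* **Density profiles** bin mass or number density along a box axis,
  averaged over frames, normalized to unit peak by default.

The membrane fixture generator (`makeMembraneFixture()`) builds fully
synthetic pseudo-GSL molecules — four hydroxyl sites per sugar moiety on
a stacked scaffold — and plants intermolecular bonds at ideal geometry
(O–O 0.28 nm, 5° angle), decoy contacts at 0.40 nm (just outside the
cutoff), and optional headgroup–water contacts, together with analytic
per-molecule-pair energies. These fixtures are bookkeeping truth tables,
not chemistry: they validate detection, attribution and normalization
exactly, but say nothing about force-field realism.

## Degenerate inputs and edge behaviour

* $A = 0$ gives an empty domain configuration; $A > 0.65$ is rejected at
  model construction (the placement guarantee ends there).
* All-zero measured counts, empty selections, zero-GSL topologies and
  isolated-molecule requests without a designated molecule are errors;
  a waterless fixture yields zero headgroup–water counts with the Sia
  fraction reported missing rather than an error.
* Efficiencies are clamped to $[0, 1]$; grids shorter than $10\tau_D$
  trigger a recorded tail-correction warning.

## Problem sizes used by the tests and acceptance script

The unit tests run on boxes of 120–240 nm with a few hundred probes and
5–100 realizations; fixtures stay below a thousand atoms. The recovery
benchmark simulates the full default grid (145 + 12 nodes) at the staged
sample budgets above and four 10-vesicle cohorts at 10⁵ counts each —
these sizes were chosen so a complete recovery experiment runs in minutes
on a single core while keeping Monte-Carlo noise at the chi-square scale
of the tie tolerance.

## Known limitations

* $R$ is reported on a logarithmic grid with one bisection refinement:
  relative discretization error up to ~11%.
* **Per-vesicle radius identifiability at 10⁵ counts is marginal.** With
  one probe concentration, a fitted background and a fixed partition
  coefficient, the chi-square surface has a diagonal $(R\uparrow,
  A\uparrow)$ ridge only 1–3 units deep across a factor ~1.5–2.5 in $R$
  around the generating state (measured with near-exact models and
  noise-free expected counts). The Poisson noise of a 10⁵-count decay
  perturbs chi-square differences of this size by ±2–3, so single-vesicle
  argmin estimates scatter over the neighbouring ridge nodes and the
  median error of a 10-vesicle cohort sits at the ±20% boundary — on
  which side depends on the draws. Cohort *means* of $\hat R$ and
  $\hat A$ are substantially more stable than per-vesicle estimates.
  Higher photon counts, a measured background, or decays at several
  acceptor concentrations would sharpen the ridge; none of these is part
  of the default conditions.
* For $R \gg R_0$ the decay depends on $R$ only through the
  boundary-region fraction (~$R_0/R$), so radius estimates above ~20
  $R_0$ are grid-cell estimates at best.
* Domains smaller than ~$R_0/2$ are FRET-invisible at realistic probe
  densities: the rate kernel averages over ~$R_0$ scales, so such states
  tie with the uniform membrane and resolve to $\hat A = 0$.
* The energy stage's plain cutoff underestimates long-range
  electrostatics for charged headgroups (Sia carries −1); totals are
  comparable within a consistent analysis, not to mesh-summed values.
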