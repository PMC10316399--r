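# nanoFRET

Membrane nanodomain size inference by Monte-Carlo FRET, plus per-moiety
interaction bookkeeping for glycosphingolipid bilayers.

## What problem this solves, and for whom

Gangliosides and related glycosphingolipids (GSLs) cluster into membrane
nanodomains of 5–120 nm radius — far below optical resolution. Membrane
biophysicists characterize these domains on giant unilamellar vesicles
(GUVs) by time-resolved FRET: the donor fluorescence decay of a labelled
lipid encodes the nanometre-scale distribution of donor–acceptor
distances, and matching Monte-Carlo-simulated decays to the measured
time-correlated single-photon-counting (TCSPC) histogram yields, per
vesicle, the mean nanodomain radius ⟨R⟩ and the membrane area fraction
⟨A⟩ the domains cover ("MC-FRET"). A companion analysis stage answers
the *why*: per-sugar-moiety hydrogen-bond counts, pairwise
Coulomb + Lennard-Jones interaction energies normalized per interacting
partner, headgroup–water hydrogen bonding and partial density profiles
computed from membrane configurations.

## The model in brief

On a periodic bilayer patch carrying non-overlapping discs of radius *R*
at area fraction *A*, donors and acceptors partition into domains with
probability *K·A / (K·A + 1 − A)* and sit in two leaflet planes Δz apart.
Each donor decays as

    F_i(t) = exp(−(t/τ_D)·[1 + Σ_j (R0/r_ij)^6])

and the ensemble decay is the donor and configuration average. The
inverse fit scores an (R, A) grid with a Poisson-weighted χ² after
scaling each simulated decay to the measured total count on top of a
fitted constant background; exact ties resolve to smaller A then
smaller R, and the no-domain state is preferred among statistically
indistinguishable fits. The
no-domain limit has the classical planar-quenching closed form
π σ_A R0² Γ(2/3) (t/τ_D)^{1/3}, used as an internal oracle.

## Worked example

```r
library(nanoFRET)

params <- FretParameters(forsterRadius = 5.7, donorLifetime = 5.8)

# forward: simulate vesicles with 15-nm domains covering 55% of the area
scenario <- guvScenario("DOPC/Chol/GSL 75/25/5", radius = 15, area = 0.55,
                        relSdR = 0, sdA = 0, nGuvs = 3, counts = 1e5,
                        seed = 42)
cohort <- makeGUVCohort(scenario, params)

# inverse: fit each vesicle on the default (R, A) grid
fits <- fitCohort(cohort$decays, makeFitGrid(), params, seed = 7)
summary <- aggregateGUVs(fits)
summary
```

```
DistributionSummary: 3 vesicles, <R> = 12.52 nm, <A> = 0.492
```

Here `<R>` and `<A>` are the arithmetic means of the per-vesicle
estimates; the generating truth was R = 15 nm, A = 0.55. At 10⁵ photon
counts per vesicle, single-vesicle estimates scatter over neighbouring
grid nodes along a shallow chi-square ridge (the methods vignette
quantifies this), so a 3-vesicle mean lands within roughly one grid
step of the truth. Each `FitResult` carries the full χ² surface so flat
(poorly identified) directions can be inspected.

The interaction stage works from coordinate + topology files or from the
synthetic fixture generator:

```r
fx <- makeMembraneFixture(nGsl = 3, species = "GM1",
                          plantedBonds = data.frame(moietyA = "Sia3",
                                                    moietyB = "Sia3",
                                                    count = 4),
                          nWater = 10, seed = 1)
moietyHBondTable(fx$coords, fx$topology, fx$moietyMap, fx$box)
```

```
  species  moiety mean_bonds_per_molecule se
1     GM1    Glc1                   0.000 NA
2     GM1    Gal2                   0.000 NA
3     GM1    Sia3                   1.333 NA
4     GM1 GalNAc4                   0.000 NA
5     GM1    Gal5                   0.000 NA
6     GM1   total                   1.333 NA
```

Four planted Sia3–Sia3 bonds over three molecules give 4/3 ≈ 1.33 bonds
per molecule, all attributed to the sialic-acid moiety.

A thin command-line wrapper (`inst/scripts/nanofret`) exposes the
pipelines as subcommands (`simulate-decay`, `fit-guv`, `cohort`,
`synth-cohort`, `synth-fixture`, `hbonds`, `energies`, `density`); every
run writes its resolved configuration next to its outputs, and identical
configurations reproduce byte-identical results.

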