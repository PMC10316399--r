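Package: nanoFRET
Title: Membrane Nanodomain Size Inference by Monte-Carlo FRET and
    Glycosphingolipid Interaction Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward Monte-Carlo simulation of time-resolved donor
    fluorescence decays for FRET probes partitioning into nanoscopic lipid
    domains, and the matching inverse problem: per-vesicle inference of the
    mean nanodomain radius and membrane area coverage from time-correlated
    single-photon counting (TCSPC) decay histograms. A second analysis stage
    computes per-moiety hydrogen-bond tables, pairwise Coulomb plus
    Lennard-Jones interaction energies with per-partner normalization,
    headgroup-water hydrogen-bond statistics and partial density profiles
    from membrane configurations of glycosphingolipid-containing bilayers.
    Includes synthetic-data generators for Poisson TCSPC decay cohorts and
    membrane coordinate fixtures with planted hydrogen bonds and known
    analytic energies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
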