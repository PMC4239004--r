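Package: funnelpot
Title: Funnel-Sculpted Knowledge-Based Pair Potentials for Protein Decoy
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates smooth C-alpha pair potentials that mimic
    native-decoy distance measures. Implements four structural distance
    measures (RMSD after optimal superposition, GDT-TS*, the fraction of lost
    native contacts Q*, and harmonic/anharmonic elastic-network deformation
    energies FlexE and MT), cubic B-spline pair potentials for single models
    (PPD) and for decoy ensembles restricted to an iteratively refined
    consensus contact map (PPE), a convex funnel-sculpting trainer that fits
    the 210 x 8 spline coefficient table by regularized least squares with
    per-protein proportionality constants, and an evaluation layer (R-score,
    energy-distance Pearson correlation, mean absolute deviation summaries).
    A synthetic decoy generator produces self-avoiding C-alpha chains with
    controlled perturbations and optional planted energy-distance funnels so
    the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    optparse,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
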