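Package: mrmforge
Title: Empirical MRM Transition Generation from Stepped Collision-Energy LC-MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts pooled-sample high-resolution LC-MS feature data and
    data-dependent MS/MS spectra acquired at discrete collision energies
    (0, 10, 20, 40 eV) into curated, retention-time-scheduled multiple
    reaction monitoring (MRM) transition tables for triple-quadrupole
    instruments. Provides monoisotopic consolidation of isotopologue
    features, adduct grouping with representative-precursor selection,
    empirical in-source fragment filtering based on accurate-mass
    association, chromatographic coelution and collision-energy dependence,
    cross-energy fragment tracking, interpolating-spline optimization of
    per-fragment collision energy, quantifier and qualifier transition
    selection, and scheduled dynamic MRM method export. Includes a seeded
    synthetic-run generator with ground-truth manifests and benchmarking
    utilities for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    mzR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
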