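# mrmforge

Targeted quantification on triple-quadrupole (QqQ) instruments needs, for
every compound, a *transition*: a precursor m/z → fragment m/z pair monitored
at a collision energy (CE) chosen to maximise the fragment's signal.
Building those transition lists for untargeted metabolomics and lipidomics
panels is normally a manual, per-compound infusion exercise. **mrmforge**
derives them empirically from two discovery runs of a pooled master sample:
a high-resolution MS1 feature table and data-dependent MS/MS spectra
acquired at four discrete collision energies (0, 10, 20 and 40 eV).

It is aimed at mass-spectrometrists who already have pooled-sample
high-resolution discovery data and want a scheduled, vendor-agnostic MRM
method out of it without spectral-library dependence.

## What it does

1. **Feature curation.** Coeluting isotopologues (spaced 1.003355/z Da) are
   consolidated into monoisotopic features; redundant adduct forms
   ([M+H]⁺/[M+Na]⁺/[M+NH4]⁺/..., configurable delta table) are grouped with
   one representative precursor retained per group. Adducts without a
   redundant partner stay independent precursors — they are analytically
   valid species, not noise.
2. **In-source fragment (ISF) filtering.** An MS1 feature is removed as
   ISF-derived only when three empirical criteria converge: a higher-mass
   coeluting feature (±0.05 min) whose MS/MS contains a matching fragment
   (±5–10 ppm), with that fragment already detected at 0 eV and persisting
   or increasing at higher energies. The 0 eV scan is treated as a
   low-energy reference, not as fragment-free.
3. **Fragment tracking.** Per curated precursor, the top ten fragment ions
   of each energy's spectrum are grouped across energies within ±0.5 Da of
   a running intensity-weighted centroid, giving one CE–intensity profile
   per fragment. Fragments within 2.0 Da of the precursor are excluded.
4. **CE optimisation.** Each profile observed at ≥3 energies is fit with an
   interpolating spline (degree k = 2, smoothing s = 0); the optimal CE is
   the argmax of the fitted curve over the sampled span, clamped to the
   5 eV instrument floor. Profiles with fewer energies fall back to the
   observed optimum.
5. **Transition selection and scheduling.** The most intense stable fragment
   becomes the quantifier, the next one the qualifier (≥2.0 Da from the
   precursor, reproducible across ≥3 energies); transitions are scheduled
   within ±0.3 min of the pooled-sample retention time at a 500 ms cycle,
   with dynamic polarity switching when both modes are present. A
   previously validated transition table can seed quantifier choice
   (reference-guided mode) while the CE still comes from the empirical
   spline.

A seeded synthetic-run generator (`generatorSpec()`/`generateRun()`) plants
compounds, isotope envelopes, adducts, ISFs and per-fragment Gaussian CE
response curves with a full ground-truth manifest, so every stage is
testable without instrument data, and `scoreAgainstTruth()` /
`benchTransitions()` report ΔCE distributions, ±0.5 Da fragment agreement
and quantifier overlap.

## Worked example

```r
library(mrmforge)

run <- generateRun(generatorSpec(n_compounds = 50, n_isf = 30),
                   seed = 42, outdir = tempfile())
res <- buildMRM(run$feature_table, run$mzml, runConfig(seed = 42))
res
#> MRMRun
#>   stage counts:
#>     features_total               228
#>     features_with_ms2            74
#>     after_isotope_consolidation  74
#>     after_adduct_grouping        74
#>     after_isf_removal            51
#>     curated_precursors           51
#>     compounds_with_spectra       51
#>     compounds_emitted            51
#>     transitions                  102
```

The 228 emitted features include isotopologues and adducts (no MS/MS, so
the MS/MS-bearing count starts at 74) and 30 planted in-source fragments;
ISF filtering removes 29 of them (one noisy ISF escapes the coelution
window), leaving 51 curated precursors. Scoring against the manifest:

```r
scoreAgainstTruth(res, run$truth)
#> ISF recall 0.97, precision 1.00; retention 1.00
#> median dCE +1.24 eV, median |dCE| 2.09 eV, 90% within 5 eV, 100% within 10 eV
#> quantifier identity 0.96

head(transitions(mrmMethod(res)), 3)
#>          compound precursor_mz fragment_mz   ce_ev  rt_min       role
#> 1 M834.5573T5.34p      834.557     307.498 24.5007 5.34377 quantifier
#> 2 M834.5573T5.34p      834.557     162.621 40.0000 5.34377  qualifier
#> 3 M851.9278T5.52p      851.928     366.195  5.0000 5.51789 quantifier
```

Each compound gets one quantifier and one qualifier with spline-optimised
CEs; `writeTransitionCSV()` / `writeDynamicMRMCSV()` export the method for
a QqQ method editor. A shell front end with `build`, `simulate`, `bench`
and `validate` subcommands is installed at
`system.file("scripts", "mrmforge", package = "mrmforge")`.

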