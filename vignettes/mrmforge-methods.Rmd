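---
title: "Empirical MRM transition generation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical MRM transition generation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmforge)
```

# The problem

A scheduled MRM method on a triple quadrupole monitors, per compound, one
quantifier and one or more qualifier transitions — precursor m/z → fragment
m/z pairs, each at a collision energy chosen to maximise the fragment's
yield — inside a narrow retention-time window. mrmforge derives such
methods from pooled-sample discovery data: a centroided MS1 feature table
and DDA MS/MS spectra acquired as separate events at the four discrete
collision energies 0, 10, 20 and 40 eV. This vignette documents the
underlying procedure, the tunable parameters, the numerical choices, and
what the accompanying synthetic-data generator does and does not emulate.

# Feature curation

**Isotope consolidation.** MS1 feature lists contain isotopologue peaks
spaced by the ¹³C–¹²C mass difference (1.003355 Da divided by the charge).
Features coeluting within the chromatographic-coherence window and matching
that spacing within the m/z tolerance are chained into clusters, and the
lowest-m/z (monoisotopic) member survives. Cluster seeding is greedy by
descending intensity with ties broken by ascending m/z, and a feature may
join only one cluster; the operation is therefore deterministic,
order-independent, idempotent, and never increases the feature count. We
check that envelopes decay monotonically — the expected pattern for small
molecules — but only log violations, since no abundance model is imposed.

**Adduct grouping.** Coeluting features whose m/z values map onto a common
neutral mass under the configured adduct deltas (defaults: H⁺, Na⁺, NH₄⁺,
K⁺ in positive mode; −H⁺, +HCOO⁻ in negative mode) are collapsed to one
group; the highest-intensity member is kept as the representative
precursor, maximising downstream MRM sensitivity. Adducts with no redundant
partner are deliberately *retained* as independent precursors: many
metabolites ionise preferentially — or exclusively — as adduct species, so
collapsing everything to a neutral mass would discard measurable chemistry.

Defaults: m/z tolerance 10 ppm, charges 1–3, coelution half-window
0.05 min. The coelution window is the same one used for in-source-fragment
filtering; applying one chromatographic-coherence window throughout is the
most conservative consistent choice. The tolerance and charge range are
exposed in `curationConfig()` because instrument resolution and analyte
class move them.

# In-source fragment filtering

In-source fragments (ISFs) are fragment ions formed before the first mass
analyzer; they masquerade as precursor features and, if kept, propagate
into transition lists as nonspecific targets. A feature F is classified as
ISF-derived only when three criteria converge for some candidate parent P:

1. *Accurate-mass association* — P's MS/MS contains a fragment matching
   F's m/z within the ppm tolerance (default 10 ppm, intended range 5–10).
2. *Chromatographic coelution* — |RT(F) − RT(P)| ≤ 0.05 min.
3. *Collision-energy dependence* — the fragment is detected in P's 0 eV
   spectrum and persists or increases at 10–40 eV. Nominal 0 eV spectra
   are a low-energy fragmentation reference, not assumed fragment-free.

"Persists or increases" is operationalised as: maximum intensity over
10/20/40 eV at least 0.5 × the 0 eV intensity. The factor is a package
decision — the qualitative behaviour fixes no number — chosen to tolerate
DDA sampling variation while excluding species that collapse immediately
above 0 eV; it is configurable (`isfConfig(persistence_factor=)`).
Parent candidates must exceed F's m/z by 2.0 Da (a fragment cannot outweigh
its parent) and carry ≥10% of F's intensity (guards against assigning a
dominant feature as the "fragment" of a trace feature). When several
parents qualify, the reported assignment takes the smallest ppm error, then
the smallest ΔRT; the verdict does not depend on the choice. Widening
either tolerance can only grow the removed set (monotonicity, exercised in
the tests).

The pipeline order is deisotope → adduct grouping → ISF filter; filtering
on consolidated features avoids classifying isotopologues of an ISF
separately.

# Fragment tracking and CE profiles

For each curated precursor the MS2 spectra are matched by precursor m/z
(10 ppm) and RT (±0.05 min), keeping per energy the spectrum with the
highest total ion current. Per energy, the ten most intense fragment peaks
enter tracking; peaks within 2.0 Da of the precursor are excluded *at
tracking time* so that unfragmented precursor survival can never become a
transition. Peaks are grouped across energies within ±0.5 Da of the
running intensity-weighted group centroid (centroid comparison prevents
chaining drift), seeded in descending intensity. When a peak's best group
already holds an observation at that energy, the peak seeds a new group
rather than silently replacing an isobaric fragment. A missing energy is
recorded as absent, not zero: absence in DDA may reflect sampling, not a
true zero.

Profiles observed at three or more energies are spline-eligible. Profiles
that fall below 10% of their maximum and later rebound above 50% are
flagged *irregular* — discontinuous behaviour inconsistent with a smooth
fragmentation-efficiency curve — and barred from quantifier candidacy
(still reported). A leading low value is not a trough: a profile that
simply rises to its maximum is regular. Both fractions are package
operationalisations of "discontinuous" and are configurable.

# Collision-energy optimisation

Fragment intensity as a function of collision energy is modelled with a
univariate interpolating spline, degree k = 2, smoothing s = 0, fit on the
raw intensity scale. The spline basis uses boundary knots repeated k+1
times and interior knots at midpoints of the interior abscissae — the
FITPACK interpolation rule — so the curve passes through every observed
point exactly; the coefficients solve a small `splines::splineDesign`
system. The optimal CE is the argmax located by a 0.1 eV grid search over
the *sampled* span refined by `stats::optimize`; extrapolated spline
excursions outside the sampled range are never trusted. Predictions below
5 eV are clamped to 5 eV, the lower operational limit of standard QqQ
instruments, and recorded as `clamped_floor`.

The degree default deserves a note: quadratic (k = 2) is the package
default, with cubic selectable via `splineConfig(spline_degree = 3)`; both
modes are tested. With only three observations a cubic request falls back
to the quadratic interpolant (a cubic needs four points). Profiles with
fewer than three energies use the observed-optimum fallback, floored at
5 eV. Duplicate energy abscissae cannot occur because spectrum sets keep
one spectrum per energy.

Numerical tolerances: interpolation residuals are zero to 1e−6 relative;
the grid-plus-refinement argmax agrees with a brute-force 0.01 eV grid to
within 0.1 eV (property-tested over 1,000 random profiles); the quadratic
interpolant itself is cross-checked in the test suite against scipy's
independent FITPACK implementation on a small profile set. A hook
(`splineConfig(adjust=)`) accepts a user-supplied CE-adjustment function
for supervised refinement models, which are otherwise out of scope.

# Transition selection and scheduling

The quantifier is the most intense *stable* fragment, where stable means
spline-eligible (≥3 energies) and not irregular; ties break by higher
energy coverage, then lower fragment m/z — fully deterministic. Qualifiers
are the next fragments by predicted intensity meeting the same
reproducibility rule and the ≥2.0 Da precursor separation (default one
qualifier; configurable). Compounds with a single reproducible fragment
emit a quantifier-only transition, flagged; compounds with only
low-coverage profiles use the fallback CE and are likewise flagged
single-transition. Expected qualifier/quantifier intensity ratios are
exported as metadata to support transition-ratio specificity checks in
downstream QC; they gate nothing here.

In reference-guided mode a prior transition table seeds quantifier choice:
a reference quantifier matching the precursor (10 ppm, same polarity) and
an observed fragment group within ±0.5 Da is promoted, but its CE is
always replaced by the empirically modelled one. Unmatched references are
ignored.

Merging experimental sets takes the union of compounds, collapsing
duplicates (same polarity, precursor within 10 ppm, quantifier within
0.5 Da, RT within the scheduling window) and keeping the instance with the
higher quantifier intensity — a package decision; merging is associative
and order-insensitive. Scheduling uses ±0.3 min windows around the
pooled-sample RT and a constant 500 ms cycle, with polarity switching
enabled automatically when both modes are present.

# The synthetic-data generator

`generateRun()` emulates the discovery acquisition: per compound a neutral
mass (120–900 Da), retention time (1–14 min), log-normal abundance, and
3–8 fragments whose CE response is a scaled Gaussian with peak location
μ ∈ [5, 38] eV and width σ ∈ [5, 15] eV, evaluated at 0/10/20/40 eV with a
1-count detection threshold. A smooth unimodal response is the minimal
assumption consistent with spline-argmax optimisation; the continuous
curve's analytic argmax (μ) is the oracle for CE-recovery tests. Isotope
envelopes decay geometrically (+1 at 0.2, +2 at 0.04 of the monoisotopic
intensity) — sufficient for consolidation tests, with no
elemental-composition modelling. 30% of compounds carry a redundant sodium
(formate) adduct feature. Planted ISF features coelute with their parent
within ±0.02 min and mirror a dedicated parent fragment constructed to be
detectable at 0 eV and persistent above it (μ ∈ [5, 15], σ ∈ [8, 15] eV).
The default noise model is multiplicative log-normal intensity error
(σ_log = 0.2), uniform ±3 ppm m/z jitter and Gaussian 0.01 min RT jitter —
values a pooled-sample QTOF acquisition would consider realistic;
`noise = NULL` gives the noiseless case. Per compound, fragment amplitudes
are spaced so successive sampled-maximum intensities differ by ≥25%,
making the planted quantifier unambiguous — without the margin, spline
overshoot could legitimately flip near-ties and no exact quantifier oracle
would exist.

DDA behaviour is emulated structurally: monoisotopic and ISF features are
"triggered" for MS/MS, isotopologues are not. This reproduces the
characteristic accounting in which isotope consolidation barely reduces
MS/MS-bearing feature counts while ISF removal reduces them substantially.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: chromatographic peak shapes and profile
scans (features are points, not peaks), chimeric MS/MS from co-isolation,
ion suppression, charge states above 1 in the emitted features, mass
accuracy drift, and real fragmentation chemistry (fragment m/z values are
random, carrying no structural relationship to the precursor beyond the
mass ordering). Recovery rates on synthetic runs are upper bounds on
real-data behaviour.

Determinism: a fixed seed reproduces every emitted file byte-identically;
the manifest (JSON) fully reconstructs the ground truth.

# Problem sizes and runtime

The test suite exercises runs of 5–100 compounds with up to 60 planted
ISFs; the spline oracle property uses 1,000 random profiles and the
CE-recovery study 500 planted fragments — sizes at which every stage's
behaviour is already asymptotically stable while the whole suite completes
in well under a minute. The acceptance script's adversarial selection set
uses five compounds with five planted near-precursor fragments each.

# Known limitations

- ISF filtering requires the parent to have a 0 eV spectrum; parents
  triggered only at higher energies cannot support the verdict and the
  fragment feature is retained (logged).
- Quadratic interpolation of a narrow response sampled at four energies
  biases the argmax toward the sampled grid; recovery degrades for
  response widths well below the 10 eV energy spacing (the noise sweep in
  the score report quantifies this per run).
- Feature tables are trusted as centroided and deconvoluted per polarity;
  no peak picking is performed.
- Scheduling assumes RT stability between discovery and deployment runs;
  the ±0.3 min window is not adapted to peak width.
- Peak areas in the output schema are populated only when a downstream
  integration step supplies them; the package itself stops at method
  generation.
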