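# Mass constants (u)
.PROTON <- 1.007276466
.C13_SPACING <- 1.003355       # 13C - 12C mass difference

#' Default adduct delta table
#'
#' Charge-carrier mass offsets relative to the neutral molecule M for the
#' adduct species retained by default.  Positive mode ships H, Na, NH4 and K;
#' negative mode -H and +HCOO (formate).  The table is editable: supply your
#' own data.frame with columns `label`, `delta`, `polarity` anywhere a
#' curation config is accepted.
#'
#' @return data.frame with columns `label`, `delta` (Da, m/z minus neutral
#'   mass for singly charged species) and `polarity`.
#' @export
#' @examples
#' defaultAdductTable()
defaultAdductTable <- function() {
  data.frame(
    label = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+K]+",
              "[M-H]-", "[M+HCOO]-"),
    delta = c(1.007276, 22.989218, 18.033823, 38.963158,
              -1.007276, 44.998201),
    polarity = c(rep("positive", 4), rep("negative", 2)),
    stringsAsFactors = FALSE)
}

#' Feature-curation configuration
#'
#' Tolerances for monoisotopic consolidation and adduct grouping.  The
#' coelution window reuses the in-source-fragment window (+/-0.05 min), the
#' most conservative chromatographic-coherence choice.
#'
#' @param ppm m/z tolerance in parts per million for isotope spacing and
#'   adduct delta matching.
#' @param rt_window_min coelution half-window in minutes.
#' @param charges integer vector of charge states considered for isotope
#'   envelopes.
#' @param max_isotopes maximum number of isotopologue peaks chained above the
#'   monoisotopic peak.
#' @param adducts adduct delta table, see [defaultAdductTable()].
#' @return list of class `curationConfig`.
#' @export
curationConfig <- function(ppm = 10, rt_window_min = 0.05, charges = 1:3,
                           max_isotopes = 4, adducts = defaultAdductTable()) {
  stopifnot(ppm > 0, rt_window_min > 0, all(charges >= 1))
  structure(list(ppm = ppm, rt_window_min = rt_window_min,
                 charges = as.integer(charges),
                 max_isotopes = as.integer(max_isotopes),
                 adducts = adducts),
            class = "curationConfig")
}

#' In-source-fragment filter configuration
#'
#' @param rt_window_min coelution half-window (minutes) between a candidate
#'   in-source fragment and its parent feature.
#' @param ppm accurate-mass association tolerance (ppm) between an MS1
#'   feature and a fragment peak in a parent's MS/MS spectrum.
#' @param persistence_factor a fragment detected at 0 eV counts as
#'   "persisting" at higher energies when its maximum intensity over
#'   10/20/40 eV is at least this fraction of its 0 eV intensity.
#' @param parent_min_mass_gap_da a parent candidate must exceed the fragment
#'   feature's m/z by at least this many Da.
#' @param parent_min_intensity_ratio a parent candidate's MS1 intensity must
#'   be at least this fraction of the fragment feature's intensity.
#' @param noise_threshold minimum MS/MS peak intensity counted as detected.
#' @return list of class `isfConfig`.
#' @export
isfConfig <- function(rt_window_min = 0.05, ppm = 10,
                      persistence_factor = 0.5,
                      parent_min_mass_gap_da = 2.0,
                      parent_min_intensity_ratio = 0.1,
                      noise_threshold = 0) {
  structure(list(rt_window_min = rt_window_min, ppm = ppm,
                 persistence_factor = persistence_factor,
                 parent_min_mass_gap_da = parent_min_mass_gap_da,
                 parent_min_intensity_ratio = parent_min_intensity_ratio,
                 noise_threshold = noise_threshold),
            class = "isfConfig")
}

#' Fragment-tracking configuration
#'
#' @param group_tol_da cross-energy fragment grouping tolerance (Da); peaks
#'   within this distance of a group's running intensity-weighted centroid
#'   join the group.
#' @param top_n number of most intense fragment peaks taken per collision
#'   energy.
#' @param precursor_exclusion_da fragments closer than this to the precursor
#'   m/z are excluded from tracking.
#' @param precursor_ppm precursor-to-spectrum m/z matching tolerance (ppm).
#' @param rt_window_min precursor-to-spectrum RT matching half-window (min).
#' @param rebound_fraction,trough_fraction irregularity rule: a profile is
#'   irregular when, ordered by energy, it falls below `trough_fraction` of
#'   its maximum and later rebounds above `rebound_fraction` of the maximum.
#' @return list of class `trackingConfig`.
#' @export
trackingConfig <- function(group_tol_da = 0.5, top_n = 10,
                           precursor_exclusion_da = 2.0,
                           precursor_ppm = 10, rt_window_min = 0.05,
                           rebound_fraction = 0.5, trough_fraction = 0.1) {
  structure(list(group_tol_da = group_tol_da, top_n = as.integer(top_n),
                 precursor_exclusion_da = precursor_exclusion_da,
                 precursor_ppm = precursor_ppm,
                 rt_window_min = rt_window_min,
                 rebound_fraction = rebound_fraction,
                 trough_fraction = trough_fraction),
            class = "trackingConfig")
}

#' Collision-energy spline configuration
#'
#' @param spline_degree degree of the interpolating spline (2 or 3; the
#'   default quadratic honours the explicit `k = 2` fitting parameter).
#' @param grid_step_ev step of the dense argmax grid search (eV).
#' @param ce_floor_ev lower operational collision-energy limit; predictions
#'   below it (or outside the sampled span) are clamped here.
#' @param ce_ceiling_ev upper collision-energy limit.
#' @param adjust optional function `(ce_opt, profile) -> ce` applied after
#'   prediction, a hook for supervised refinement models.
#' @return list of class `splineConfig`.
#' @export
splineConfig <- function(spline_degree = 2, grid_step_ev = 0.1,
                         ce_floor_ev = 5, ce_ceiling_ev = 40,
                         adjust = NULL) {
  stopifnot(spline_degree %in% c(2, 3))
  structure(list(spline_degree = as.integer(spline_degree),
                 grid_step_ev = grid_step_ev, ce_floor_ev = ce_floor_ev,
                 ce_ceiling_ev = ce_ceiling_ev, adjust = adjust),
            class = "splineConfig")
}

#' Transition-selection and scheduling configuration
#'
#' @param n_qualifiers qualifiers emitted per compound (the quantifier is
#'   always emitted).
#' @param min_precursor_gap_da minimum |precursor - fragment| separation (Da).
#' @param rt_window_min scheduling half-window around the pooled-sample
#'   retention time (minutes).
#' @param cycle_time_ms constant MRM cycle time (milliseconds).
#' @param dedup_ppm precursor m/z tolerance for collapsing duplicate
#'   compounds when merging experimental sets.
#' @return list of class `selectionConfig`.
#' @export
selectionConfig <- function(n_qualifiers = 1, min_precursor_gap_da = 2.0,
                            rt_window_min = 0.3, cycle_time_ms = 500,
                            dedup_ppm = 10) {
  structure(list(n_qualifiers = as.integer(n_qualifiers),
                 min_precursor_gap_da = min_precursor_gap_da,
                 rt_window_min = rt_window_min,
                 cycle_time_ms = cycle_time_ms, dedup_ppm = dedup_ppm),
            class = "selectionConfig")
}

#' Full run configuration
#'
#' Aggregates every stage configuration for [buildMRM()].  A serialized copy
#' is written into the output directory of each run.
#'
#' @param curation see [curationConfig()]
#' @param isf see [isfConfig()]
#' @param tracking see [trackingConfig()]
#' @param spline see [splineConfig()]
#' @param selection see [selectionConfig()]
#' @param seed integer seed recorded with the run
#' @return list of class `runConfig`.
#' @export
runConfig <- function(curation = curationConfig(), isf = isfConfig(),
                      tracking = trackingConfig(), spline = splineConfig(),
                      selection = selectionConfig(), seed = 1L) {
  structure(list(curation = curation, isf = isf, tracking = tracking,
                 spline = spline, selection = selection,
                 seed = as.integer(seed)),
            class = "runConfig")
}

# ppm tolerance in Da at a given m/z
.ppmTol <- function(mz, ppm) mz * ppm * 1e-6
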