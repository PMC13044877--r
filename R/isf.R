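#' Remove in-source-fragment-derived MS1 features
#'
#' In-source fragments (ISFs) are fragment ions formed before mass
#' selection; they appear as spurious MS1 "precursor" features that coelute
#' with their intact parent.  A feature F is classified as ISF-derived only
#' when three empirical criteria converge:
#'
#' 1. *Accurate-mass association* — a higher-mass feature P exists whose
#'    MS/MS contains a fragment peak matching F's m/z within `cfg$ppm`.
#' 2. *Chromatographic coelution* — F and P coelute within
#'    `cfg$rt_window_min` (default ±0.05 min).
#' 3. *Collision-energy dependence* — that fragment is detected in P's
#'    0 eV spectrum (the 0 eV acquisition is a low-energy reference, not
#'    assumed fragment-free) and persists or increases at higher energies:
#'    its maximum intensity over 10/20/40 eV is at least
#'    `cfg$persistence_factor` times its 0 eV intensity.
#'
#' Parent candidates must exceed F's m/z by `cfg$parent_min_mass_gap_da`
#' and carry at least `cfg$parent_min_intensity_ratio` of F's MS1 intensity.
#' When several parents qualify, the assignment records the one with the
#' smallest ppm error (ties by smallest RT difference); the verdict is
#' unaffected.  Every removal is justified by one assignment row.
#'
#' @param features curated feature data.frame (post isotope consolidation
#'   and adduct grouping).
#' @param ms2 spectrum table with the stepped-energy MS/MS scans, or a
#'   precomputed `buildSpectrumSets()` result for `features`.
#' @param cfg an [isfConfig()].
#' @return list with `retained` (features minus ISF-derived ones) and
#'   `assignments` (data.frame: `fragment_feature`, `parent_feature`,
#'   `delta_rt_min`, `mass_match_ppm`, `ce_behavior`, `verdict`; one row
#'   per ISF-derived feature).
#' @export
filterISF <- function(features, ms2, cfg = isfConfig()) {
  emptyAssign <- data.frame(fragment_feature = character(0),
                            parent_feature = character(0),
                            delta_rt_min = numeric(0),
                            mass_match_ppm = numeric(0),
                            ce_behavior = character(0),
                            verdict = character(0), stringsAsFactors = FALSE)
  if (nrow(features) == 0L)
    return(list(retained = features, assignments = emptyAssign))

  if (is.data.frame(ms2)) {
    tcfg <- trackingConfig(precursor_ppm = cfg$ppm,
                           rt_window_min = cfg$rt_window_min)
    sets <- suppressMessages(buildSpectrumSets(features, ms2, tcfg))$sets
  } else {
    sets <- ms2$sets
  }

  # peak intensity at `mz` (within ppm) in one spectrum row, 0 if absent
  peakAt <- function(spec, mz) {
    m <- spec$peaks[[1L]]
    if (is.null(m) || nrow(m) == 0L) return(0)
    hit <- abs(m[, 1L] - mz) <= .ppmTol(mz, cfg$ppm)
    if (!any(hit)) 0 else max(m[hit, 2L])
  }

  isf <- logical(nrow(features))
  assignments <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, , drop = FALSE]
    parents <- which(features$mz > f$mz + cfg$parent_min_mass_gap_da &
                       features$intensity >=
                         f$intensity * cfg$parent_min_intensity_ratio &
                       abs(features$rt_min - f$rt_min) <= cfg$rt_window_min &
                       features$polarity == f$polarity)
    best <- NULL
    for (j in parents) {
      pset <- sets[[features$feature_id[j]]]
      if (is.null(pset)) next                    # parent has no MS/MS at all
      sp0 <- pset$spectra[["0"]]
      if (is.null(sp0)) {
        message("parent ", features$feature_id[j],
                " lacks a 0 eV spectrum; collision-energy criterion ",
                "not supported")
        next
      }
      m0 <- sp0$peaks[[1L]]
      hit0 <- which(abs(m0[, 1L] - f$mz) <= .ppmTol(f$mz, cfg$ppm))
      if (!length(hit0)) next
      i0 <- max(m0[hit0, 2L])
      if (i0 <= cfg$noise_threshold) next
      hi <- vapply(c("10", "20", "40"), function(ce) {
        sp <- pset$spectra[[ce]]
        if (is.null(sp)) 0 else peakAt(sp, f$mz)
      }, numeric(1))
      if (max(hi) < cfg$persistence_factor * i0) next
      mz0 <- m0[hit0[which.max(m0[hit0, 2L])], 1L]
      err <- abs(mz0 - f$mz) / f$mz * 1e6
      drt <- features$rt_min[j] - f$rt_min
      if (is.null(best) || err < best$err ||
          (err == best$err && abs(drt) < abs(best$drt)))
        best <- list(j = j, err = err, drt = drt)
    }
    if (!is.null(best)) {
      isf[i] <- TRUE
      assignments[[length(assignments) + 1L]] <- data.frame(
        fragment_feature = f$feature_id,
        parent_feature = features$feature_id[best$j],
        delta_rt_min = best$drt, mass_match_ppm = best$err,
        ce_behavior = "detected_at_0eV_and_persists",
        verdict = "isf_derived", stringsAsFactors = FALSE)
    }
  }
  retained <- features[!isf, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       assignments = if (length(assignments))
         do.call(rbind, assignments) else emptyAssign)
}
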