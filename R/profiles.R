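#' Associate curated precursors with their stepped-energy MS/MS spectra
#'
#' For each precursor feature, collects the MS2 spectra whose precursor m/z
#' matches within `cfg$precursor_ppm` and whose retention time lies within
#' `cfg$rt_window_min`, keeping at most one spectrum per collision energy
#' (highest total ion current wins on duplicates).  Precursors with no MS2
#' anywhere are dropped and counted — in data-dependent acquisition only a
#' fraction of MS1 features is ever triggered for MS/MS, so the coverage
#' count is part of the run report.
#'
#' @param precursors curated feature data.frame.
#' @param ms2 spectrum table ([readMzML()] schema); only `ms_level == 2`
#'   rows are used.
#' @param cfg a [trackingConfig()].
#' @return list with `sets` (named list: per precursor `feature_id`, a list
#'   with `precursor` row and `spectra`, a list keyed by collision energy)
#'   and `n_uncovered` (precursors without MS/MS).
#' @export
buildSpectrumSets <- function(precursors, ms2, cfg = trackingConfig()) {
  ms2 <- ms2[ms2$ms_level == 2L, , drop = FALSE]
  sets <- list()
  n_uncovered <- 0L
  for (i in seq_len(nrow(precursors))) {
    p <- precursors[i, , drop = FALSE]
    hit <- which(ms2$polarity == p$polarity &
                   abs(ms2$precursor_mz - p$mz) <=
                     .ppmTol(p$mz, cfg$precursor_ppm) &
                   abs(ms2$rt_min - p$rt_min) <= cfg$rt_window_min &
                   is.finite(ms2$ce_ev))
    if (!length(hit)) { n_uncovered <- n_uncovered + 1L; next }
    sub <- ms2[hit, , drop = FALSE]
    spectra <- list()
    for (ce in sort(unique(sub$ce_ev))) {
      cand <- sub[sub$ce_ev == ce, , drop = FALSE]
      spectra[[as.character(ce)]] <-
        cand[which.max(cand$tic), , drop = FALSE]
    }
    sets[[p$feature_id]] <- list(precursor = p, spectra = spectra)
  }
  if (n_uncovered > 0L)
    message(n_uncovered, " of ", nrow(precursors),
            " precursors had no MS/MS coverage")
  list(sets = sets, n_uncovered = n_uncovered)
}

#' Track fragment ions across collision energies
#'
#' Takes the top `cfg$top_n` most intense fragment peaks of each collision
#' energy's spectrum (peaks within `cfg$precursor_exclusion_da` of the
#' precursor m/z are excluded, so unfragmented precursor survival never
#' becomes a transition), then groups peaks across energies by iterative
#' matching against the running intensity-weighted group centroid within
#' `cfg$group_tol_da`, seeded in descending intensity.  Each group becomes
#' one collision-energy–intensity profile; a missing energy is recorded as
#' absent, not zero.  Profiles observed at three or more energies are
#' eligible for spline fitting; irregular profiles (see [flagIrregular()])
#' are excluded from quantifier candidacy.
#'
#' @param set one element of `buildSpectrumSets()$sets`.
#' @param cfg a [trackingConfig()].
#' @return data.frame with one row per fragment group: `group_mz`,
#'   `n_energies`, `eligible_for_spline`, `irregular`, and list-columns
#'   `ce_ev` / `intensity` holding the per-energy observations sorted by
#'   energy.
#' @export
trackFragments <- function(set, cfg = trackingConfig()) {
  prec_mz <- set$precursor$mz
  obs <- list()
  for (ce_name in names(set$spectra)) {
    sp <- set$spectra[[ce_name]]
    m <- sp$peaks[[1L]]
    if (is.null(m) || nrow(m) == 0L) next
    m <- m[abs(m[, 1L] - prec_mz) >= cfg$precursor_exclusion_da, ,
           drop = FALSE]
    if (nrow(m) == 0L) next
    m <- m[order(-m[, 2L]), , drop = FALSE]
    m <- m[seq_len(min(cfg$top_n, nrow(m))), , drop = FALSE]
    obs[[length(obs) + 1L]] <-
      data.frame(ce = as.numeric(ce_name), mz = m[, 1L], int = m[, 2L])
  }
  if (!length(obs)) return(.emptyProfileTable())
  obs <- do.call(rbind, obs)
  obs <- obs[order(-obs$int, obs$mz, obs$ce), , drop = FALSE]

  centroid <- numeric(0); wsum <- numeric(0)
  members <- list()
  for (r in seq_len(nrow(obs))) {
    mz <- obs$mz[r]; ce <- obs$ce[r]; int <- obs$int[r]
    g <- NA_integer_
    if (length(centroid)) {
      d <- abs(centroid - mz)
      cand <- which(d <= cfg$group_tol_da)
      # a group that already observed this energy cannot take a second
      # peak there; the later (less intense) peak seeds a new group
      cand <- cand[vapply(cand, function(k)
        !ce %in% members[[k]]$ce, logical(1))]
      if (length(cand)) g <- cand[which.min(d[cand])]
    }
    if (is.na(g)) {
      centroid <- c(centroid, mz); wsum <- c(wsum, int)
      members[[length(members) + 1L]] <-
        data.frame(ce = ce, mz = mz, int = int)
    } else {
      centroid[g] <- (centroid[g] * wsum[g] + mz * int) / (wsum[g] + int)
      wsum[g] <- wsum[g] + int
      members[[g]] <- rbind(members[[g]],
                            data.frame(ce = ce, mz = mz, int = int))
    }
  }

  out <- do.call(rbind, lapply(seq_along(members), function(k) {
    mm <- members[[k]][order(members[[k]]$ce), , drop = FALSE]
    data.frame(group_mz = centroid[k], n_energies = nrow(mm),
               eligible_for_spline = nrow(mm) >= 3L, irregular = FALSE,
               stringsAsFactors = FALSE)
  }))
  out$ce_ev <- lapply(members, function(mm) mm$ce[order(mm$ce)])
  out$intensity <- lapply(members, function(mm) mm$int[order(mm$ce)])
  out <- out[order(-vapply(out$intensity, max, numeric(1))), , drop = FALSE]
  rownames(out) <- NULL
  out$irregular <- vapply(seq_len(nrow(out)), function(k)
    flagIrregular(out[k, , drop = FALSE], cfg)$irregular, logical(1))
  out
}

.emptyProfileTable <- function() {
  out <- data.frame(group_mz = numeric(0), n_energies = integer(0),
                    eligible_for_spline = logical(0), irregular = logical(0),
                    stringsAsFactors = FALSE)
  out$ce_ev <- list(); out$intensity <- list()
  out
}

#' Flag discontinuous collision-energy profiles
#'
#' A profile is irregular when, ordered by collision energy, its intensity
#' falls below `trough_fraction` (default 0.1) of the profile maximum and a
#' later energy rebounds above `rebound_fraction` (default 0.5) of the
#' maximum — behaviour inconsistent with a smooth fragmentation-efficiency
#' curve.  Irregular profiles are excluded from quantifier candidacy but
#' still reported.  Profiles with fewer than three energies are left to the
#' low-coverage fallback and never flagged.
#'
#' @param profile one row of the [trackFragments()] table.
#' @param cfg a [trackingConfig()].
#' @return the row with `irregular` set.
#' @export
flagIrregular <- function(profile, cfg = trackingConfig()) {
  ints <- profile$intensity[[1L]]
  if (length(ints) < 3L) { profile$irregular <- FALSE; return(profile) }
  mx <- max(ints)
  seen_high <- FALSE   # profile has been above the trough level before
  fallen <- FALSE      # ... and has since dropped below it
  irregular <- FALSE
  for (v in ints) {
    if (fallen && v > cfg$rebound_fraction * mx) { irregular <- TRUE; break }
    if (seen_high && v < cfg$trough_fraction * mx) fallen <- TRUE
    if (v >= cfg$trough_fraction * mx) seen_high <- TRUE
  }
  profile$irregular <- irregular
  profile
}
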