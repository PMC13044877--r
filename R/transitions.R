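#' Select quantifier and qualifier transitions for one precursor
#'
#' The quantifier is the most intense *stable* fragment: highest predicted
#' maximum intensity among profiles that are spline-eligible (observed at
#' three or more energies) and not irregular, at least
#' `cfg$min_precursor_gap_da` (2.0 Da) away from the precursor m/z.  Ties
#' are broken by higher energy coverage, then lower fragment m/z.
#' Qualifiers are the next `cfg$n_qualifiers` fragments by intensity
#' meeting the same reproducibility and separation rules.  When no
#' spline-eligible profile exists, low-coverage fallback profiles may still
#' supply a single quantifier (flagged `single_transition`); a compound
#' with no usable profile at all is dropped with a diagnostic.
#'
#' @param precursor one curated feature row.
#' @param predictions [predictCE()] output for that precursor.
#' @param cfg a [selectionConfig()].
#' @return a `compoundTransitions` list (`precursor`, `quantifier`,
#'   `qualifiers`, `rt_min`, `rt_window_min`, `mode`, `single_transition`,
#'   `candidates`), or `NULL` when the compound is dropped.
#' @export
selectTransitions <- function(precursor, predictions,
                              cfg = selectionConfig()) {
  if (nrow(predictions) == 0L) {
    message("compound at m/z ", round(precursor$mz, 4),
            " dropped: no fragment profiles")
    return(NULL)
  }
  sep_ok <- abs(predictions$group_mz - precursor$mz) >=
    cfg$min_precursor_gap_da
  eligible <- which(sep_ok & predictions$eligible_for_spline &
                      !predictions$irregular)
  fallback <- which(sep_ok & !predictions$eligible_for_spline &
                      !predictions$irregular)
  rank <- function(idx)
    idx[order(-predictions$predicted_max_intensity[idx],
              -predictions$n_energies[idx], predictions$group_mz[idx])]
  single <- FALSE
  if (length(eligible)) {
    eligible <- rank(eligible)
    quant <- eligible[1L]
    quals <- utils::head(eligible[-1L], cfg$n_qualifiers)
    if (!length(quals)) single <- TRUE
  } else if (length(fallback)) {
    quant <- rank(fallback)[1L]
    quals <- integer(0)
    single <- TRUE
  } else {
    message("compound at m/z ", round(precursor$mz, 4),
            " dropped: all fragment profiles irregular or too close ",
            "to the precursor")
    return(NULL)
  }
  asRow <- function(k)
    data.frame(fragment_mz = predictions$group_mz[k],
               ce_ev = predictions$ce_opt_ev[k],
               intensity = predictions$predicted_max_intensity[k],
               n_energies = predictions$n_energies[k],
               stringsAsFactors = FALSE)
  structure(list(precursor = precursor,
                 quantifier = asRow(quant),
                 qualifiers = if (length(quals))
                   do.call(rbind, lapply(quals, asRow)) else asRow(quant)[0, ],
                 rt_min = precursor$rt_min,
                 rt_window_min = cfg$rt_window_min,
                 mode = "empirical",
                 single_transition = single,
                 candidates = predictions),
            class = "compoundTransitions")
}

#' Reference-guided quantifier initialization
#'
#' When a previously validated transition table is available, its fragment
#' assignments serve as an initial guide while empirical collision-energy
#' modelling still decides the energy.  A reference quantifier matching the
#' compound's precursor (ppm, polarity) and one of its observed fragment
#' groups within `match_tol_da` is promoted to quantifier; its collision
#' energy is replaced by the empirically modelled one.  Unmatched reference
#' fragments are ignored and the compound stays fully empirical.
#'
#' @param compound a `compoundTransitions` list.
#' @param reference data.frame in the transition CSV schema.
#' @param cfg a [selectionConfig()].
#' @param ppm precursor matching tolerance.
#' @param match_tol_da fragment matching tolerance (Da).
#' @return the (possibly updated) `compoundTransitions`; `mode` becomes
#'   `"reference_guided"` when a promotion occurred.
#' @export
applyReferenceGuide <- function(compound, reference,
                                cfg = selectionConfig(), ppm = 10,
                                match_tol_da = 0.5) {
  if (is.null(compound) || nrow(reference) == 0L) return(compound)
  p <- compound$precursor
  ref <- reference[reference$polarity == p$polarity &
                     abs(reference$precursor_mz - p$mz) <=
                       .ppmTol(p$mz, ppm) &
                     reference$role == "quantifier", , drop = FALSE]
  if (nrow(ref) == 0L) return(compound)
  cand <- compound$candidates
  usable <- which(!cand$irregular &
                    abs(cand$group_mz - p$mz) >= cfg$min_precursor_gap_da)
  for (r in seq_len(nrow(ref))) {
    d <- abs(cand$group_mz[usable] - ref$fragment_mz[r])
    hit <- usable[d <= match_tol_da]
    if (!length(hit)) next
    k <- hit[which.min(abs(cand$group_mz[hit] - ref$fragment_mz[r]))]
    promoted <- data.frame(fragment_mz = cand$group_mz[k],
                           ce_ev = cand$ce_opt_ev[k],
                           intensity = cand$predicted_max_intensity[k],
                           n_energies = cand$n_energies[k],
                           stringsAsFactors = FALSE)
    if (abs(promoted$fragment_mz - compound$quantifier$fragment_mz) >
        1e-9) {
      # former quantifier becomes the leading qualifier
      compound$qualifiers <- unique(rbind(compound$quantifier,
                                          compound$qualifiers))
      keep <- abs(compound$qualifiers$fragment_mz -
                    promoted$fragment_mz) > 1e-9
      compound$qualifiers <-
        utils::head(compound$qualifiers[keep, , drop = FALSE],
                    cfg$n_qualifiers)
      compound$quantifier <- promoted
      compound$single_transition <- nrow(compound$qualifiers) == 0L
    }
    compound$mode <- "reference_guided"
    break
  }
  compound
}

#' Merge per-set transition selections into one scheduled MRM method
#'
#' Forms the union of compounds across experimental sets, collapsing
#' duplicates — same polarity, precursor m/z within `cfg$dedup_ppm`,
#' quantifier fragment within 0.5 Da, retention time within the scheduling
#' window — and keeping the instance whose quantifier has the higher
#' predicted intensity.  Transitions are scheduled within
#' `cfg$rt_window_min` (±0.3 min) of the pooled-sample retention time at a
#' constant `cfg$cycle_time_ms` (500 ms) cycle; polarity switching is
#' enabled when both polarities are present.
#'
#' @param sets list of lists of `compoundTransitions` (one list per
#'   experimental set).
#' @param cfg a [selectionConfig()].
#' @return an [MRMMethod-class].
#' @export
mergeExperimentSets <- function(sets, cfg = selectionConfig()) {
  all <- unlist(sets, recursive = FALSE)
  all <- Filter(Negate(is.null), all)
  kept <- list()
  for (cmp in all) {
    dup <- NA_integer_
    for (k in seq_along(kept)) {
      o <- kept[[k]]
      if (identical(o$precursor$polarity, cmp$precursor$polarity) &&
          abs(o$precursor$mz - cmp$precursor$mz) <=
            .ppmTol(cmp$precursor$mz, cfg$dedup_ppm) &&
          abs(o$quantifier$fragment_mz - cmp$quantifier$fragment_mz) <=
            0.5 &&
          abs(o$rt_min - cmp$rt_min) <= cfg$rt_window_min) {
        dup <- k; break
      }
    }
    if (is.na(dup)) {
      kept[[length(kept) + 1L]] <- cmp
    } else if (cmp$quantifier$intensity >
               kept[[dup]]$quantifier$intensity) {
      kept[[dup]] <- cmp
    }
  }
  rows <- do.call(rbind, lapply(kept, function(cmp) {
    label <- sprintf("M%.4fT%.2f%s", cmp$precursor$mz, cmp$rt_min,
                     if (cmp$precursor$polarity == "positive") "p" else "n")
    q <- data.frame(compound = label, precursor_mz = cmp$precursor$mz,
                    fragment_mz = cmp$quantifier$fragment_mz,
                    polarity = cmp$precursor$polarity,
                    ce_ev = cmp$quantifier$ce_ev, rt_min = cmp$rt_min,
                    rt_window_min = cfg$rt_window_min, role = "quantifier",
                    peak_area = NA_real_,
                    expected_ratio = 1,
                    stringsAsFactors = FALSE)
    if (nrow(cmp$qualifiers)) {
      ql <- data.frame(compound = label, precursor_mz = cmp$precursor$mz,
                       fragment_mz = cmp$qualifiers$fragment_mz,
                       polarity = cmp$precursor$polarity,
                       ce_ev = cmp$qualifiers$ce_ev, rt_min = cmp$rt_min,
                       rt_window_min = cfg$rt_window_min, role = "qualifier",
                       peak_area = NA_real_,
                       expected_ratio = cmp$qualifiers$intensity /
                         cmp$quantifier$intensity,
                       stringsAsFactors = FALSE)
      rbind(q, ql)
    } else q
  }))
  if (is.null(rows)) rows <- data.frame()
  pols <- unique(rows$polarity)
  methods::new("MRMMethod", transitions = rows,
               cycleTimeMs = cfg$cycle_time_ms,
               polaritySwitching = length(pols) > 1L)
}

#' Export a scheduled MRM method with start/stop retention times
#'
#' Writes the vendor-neutral "dynamic MRM" rendering of a method: the
#' standard transition columns plus `rt_start_min`/`rt_stop_min` derived
#' from the scheduling window.
#'
#' @param method an [MRMMethod-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDynamicMRMCSV <- function(method, path) {
  tr <- transitions(method)
  tr$rt_start_min <- pmax(0, tr$rt_min - tr$rt_window_min)
  tr$rt_stop_min <- tr$rt_min + tr$rt_window_min
  out <- tr[, c("compound", "precursor_mz", "fragment_mz", "polarity",
                "ce_ev", "rt_start_min", "rt_stop_min", "role")]
  for (nm in c("precursor_mz", "fragment_mz"))
    out[[nm]] <- sprintf("%.4f", out[[nm]])
  out$ce_ev <- sprintf("%.1f", out$ce_ev)
  for (nm in c("rt_start_min", "rt_stop_min"))
    out[[nm]] <- sprintf("%.2f", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
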