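#' Build a scheduled MRM method from discovery data
#'
#' End-to-end pipeline: read inputs, consolidate isotopologues, group
#' adducts, remove in-source-fragment-derived features, associate curated
#' precursors with their stepped-energy MS/MS spectra, track fragments and
#' fit collision-energy splines, select quantifier/qualifier transitions,
#' and merge everything into one scheduled method.  Stage-wise counts of
#' MS/MS-bearing features (input, after isotope consolidation, after adduct
#' grouping, after ISF removal) are recorded in the run object and in the
#' run log; they are non-increasing by construction.
#'
#' @param features feature table path (CSV) or data.frame
#'   ([readFeatureTable()] schema).
#' @param ms2 mzML path or spectrum table ([readMzML()] schema).
#' @param config a [runConfig()].
#' @param reference optional reference transition table (path or
#'   data.frame) for reference-guided quantifier initialization.
#' @param outdir optional output directory; when given, the transition CSV,
#'   dynamic-MRM export, ISF assignments and a JSON run log (stage counts
#'   plus the serialized configuration) are written there.
#' @return an [MRMRun-class].
#' @export
#' @examples
#' run <- generateRun(generatorSpec(n_compounds = 5, n_isf = 2,
#'                                  noise = NULL), seed = 7)
#' res <- buildMRM(run$features, run$spectra, runConfig())
#' stageCounts(res)
buildMRM <- function(features, ms2, config = runConfig(),
                     reference = NULL, outdir = NULL) {
  if (is.character(features)) features <- readFeatureTable(features)
  if (is.character(ms2)) ms2 <- readMzML(ms2)
  if (is.character(reference)) reference <- readTransitionCSV(reference)
  features <- features[, intersect(c("feature_id", "mz", "rt_min",
                                     "intensity", "polarity", "charge"),
                                   names(features)), drop = FALSE]

  hasMS2 <- function(f) {
    if (nrow(f) == 0L) return(character(0))
    s <- suppressMessages(buildSpectrumSets(f, ms2, config$tracking))
    names(s$sets)
  }
  ms2_ids <- hasMS2(features)

  perPolarity <- function(pol) {
    f <- features[features$polarity == pol, , drop = FALSE]
    if (nrow(f) == 0L) return(NULL)
    de <- deisotope(f, config$curation)
    ad <- groupAdducts(de$features, config$curation)
    isf <- filterISF(ad$features, ms2, config$isf)
    list(deiso = de$features, adduct = ad$features,
         curated = isf$retained, assignments = isf$assignments)
  }
  stages <- Filter(Negate(is.null),
                   lapply(c("positive", "negative"), perPolarity))
  bindStage <- function(nm) {
    out <- do.call(rbind, lapply(stages, `[[`, nm))
    if (is.null(out)) features[0, , drop = FALSE] else out
  }
  deiso <- bindStage("deiso"); adduct <- bindStage("adduct")
  curated <- bindStage("curated")
  assignments <- do.call(rbind, lapply(stages, `[[`, "assignments"))
  if (is.null(assignments))
    assignments <- filterISF(features[0, , drop = FALSE], ms2,
                             config$isf)$assignments

  sets <- suppressMessages(
    buildSpectrumSets(curated, ms2, config$tracking))
  compounds <- list()
  for (id in names(sets$sets)) {
    set <- sets$sets[[id]]
    profiles <- trackFragments(set, config$tracking)
    preds <- predictCE(profiles, config$spline)
    cmp <- selectTransitions(set$precursor, preds, config$selection)
    if (!is.null(cmp) && !is.null(reference))
      cmp <- applyReferenceGuide(cmp, reference, config$selection)
    if (!is.null(cmp)) compounds[[length(compounds) + 1L]] <- cmp
  }
  method <- mergeExperimentSets(list(compounds), config$selection)

  counts <- c(features_total = nrow(features),
              features_with_ms2 = length(ms2_ids),
              after_isotope_consolidation =
                sum(deiso$feature_id %in% ms2_ids),
              after_adduct_grouping = sum(adduct$feature_id %in% ms2_ids),
              after_isf_removal = sum(curated$feature_id %in% ms2_ids),
              curated_precursors = nrow(curated),
              compounds_with_spectra = length(sets$sets),
              compounds_emitted = length(compounds),
              transitions = length(method))
  run <- methods::new("MRMRun", method = method, compounds = compounds,
                      isfAssignments = assignments,
                      stageCounts = as.integer(counts) |>
                        stats::setNames(names(counts)),
                      curated = curated)
  if (!is.null(outdir)) .writeRunOutputs(run, config, outdir)
  run
}

.writeRunOutputs <- function(run, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (length(run@method) > 0L) {
    writeTransitionCSV(run@method, file.path(outdir, "transitions.csv"))
    writeDynamicMRMCSV(run@method, file.path(outdir, "dynamic_mrm.csv"))
  } else {
    writeLines(paste(.TRANSITION_COLS, collapse = ","),
               file.path(outdir, "transitions.csv"))
  }
  utils::write.csv(run@isfAssignments,
                   file.path(outdir, "isf_assignments.csv"),
                   row.names = FALSE)
  cfg <- rapply(unclass(config),
                function(x) if (is.function(x)) NULL else x,
                how = "replace")
  jsonlite::write_json(
    list(stage_counts = as.list(stageCounts(run)), config = cfg),
    file.path(outdir, "run_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null", force = TRUE)
  invisible(outdir)
}

#' Benchmark a predicted transition table against a reference
#'
#' Matches compounds between two transition tables (precursor m/z within
#' `ppm`, same polarity) and reports fragment m/z agreement within
#' `match_tol_da` (±0.5 Da), the collision-energy error distribution
#' (median signed ΔCE, median |ΔCE|, % within ±5 and ±10 eV), and
#' quantifier/qualifier overlap.  Optionally stratifies by a grouping
#' column present in the reference table.
#'
#' @param predicted,reference transition tables (paths or data.frames in
#'   the standard schema).
#' @param ppm precursor matching tolerance.
#' @param match_tol_da fragment matching tolerance (Da).
#' @param group_col optional name of a reference column to stratify by.
#' @return list of metrics; `ok` is FALSE when no compounds matched.
#' @export
benchTransitions <- function(predicted, reference, ppm = 10,
                             match_tol_da = 0.5, group_col = NULL) {
  if (is.character(predicted)) predicted <- readTransitionCSV(predicted)
  if (is.character(reference)) {
    ref_raw <- utils::read.csv(reference, stringsAsFactors = FALSE)
    reference <- readTransitionCSV(reference)
    if (!is.null(group_col) && group_col %in% names(ref_raw))
      reference[[group_col]] <- ref_raw[[group_col]]
  }
  refq <- reference[reference$role == "quantifier", , drop = FALSE]
  one <- function(refsub) {
    delta <- numeric(0); fmatch <- logical(0)
    q_overlap <- logical(0); qual_overlap <- logical(0)
    matched <- 0L
    for (r in seq_len(nrow(refsub))) {
      rq <- refsub[r, ]
      prows <- predicted[predicted$polarity == rq$polarity &
                           abs(predicted$precursor_mz - rq$precursor_mz) <=
                             .ppmTol(rq$precursor_mz, ppm), , drop = FALSE]
      if (!nrow(prows)) next
      matched <- matched + 1L
      refrows <- reference[reference$compound == rq$compound, , drop = FALSE]
      for (i in seq_len(nrow(refrows))) {
        d <- abs(prows$fragment_mz - refrows$fragment_mz[i])
        hit <- which.min(d)
        ok <- d[hit] <= match_tol_da
        fmatch <- c(fmatch, ok)
        if (ok) delta <- c(delta, prows$ce_ev[hit] - refrows$ce_ev[i])
      }
      pq <- prows$fragment_mz[prows$role == "quantifier"]
      q_overlap <- c(q_overlap, length(pq) > 0 &&
                       abs(pq[1L] - rq$fragment_mz) <= match_tol_da)
      rql <- refrows$fragment_mz[refrows$role == "qualifier"]
      pql <- prows$fragment_mz[prows$role == "qualifier"]
      if (length(rql))
        qual_overlap <- c(qual_overlap, vapply(rql, function(m)
          any(abs(pql - m) <= match_tol_da), logical(1)))
    }
    list(n_reference_compounds = nrow(refsub),
         n_matched_compounds = matched,
         fragment_match_rate = if (length(fmatch)) mean(fmatch) else NA_real_,
         median_delta_ce = if (length(delta)) stats::median(delta) else NA_real_,
         median_abs_delta_ce = if (length(delta)) stats::median(abs(delta))
           else NA_real_,
         pct_within_5ev = if (length(delta)) 100 * mean(abs(delta) <= 5)
           else NA_real_,
         pct_within_10ev = if (length(delta)) 100 * mean(abs(delta) <= 10)
           else NA_real_,
         quantifier_overlap = if (length(q_overlap)) mean(q_overlap)
           else NA_real_,
         qualifier_overlap = if (length(qual_overlap)) mean(qual_overlap)
           else NA_real_)
  }
  out <- one(refq)
  out$ok <- out$n_matched_compounds > 0L
  if (!is.null(group_col) && group_col %in% names(refq))
    out$by_group <- lapply(split(refq, refq[[group_col]]), one)
  out
}
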