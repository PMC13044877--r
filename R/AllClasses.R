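#' @import methods
NULL

#' Scheduled MRM method
#'
#' Container for a scheduled (dynamic) MRM acquisition method: a transition
#' table plus the instrument-level scheduling parameters a triple-quadrupole
#' method editor needs.  Transitions are stored in the package's standard
#' schema (see [writeTransitionCSV()]): one quantifier per compound, zero or
#' more qualifiers, retention-time windows as half-widths.
#'
#' @slot transitions data.frame of transitions (columns `compound`,
#'   `precursor_mz`, `fragment_mz`, `polarity`, `ce_ev`, `rt_min`,
#'   `rt_window_min`, `role`, `peak_area`).
#' @slot cycleTimeMs constant cycle time in milliseconds (default 500).
#' @slot polaritySwitching whether the method interleaves positive and
#'   negative transitions.
#'
#' @aliases MRMMethod-class
#' @export
setClass("MRMMethod",
  representation(transitions = "data.frame",
                 cycleTimeMs = "numeric",
                 polaritySwitching = "logical"),
  prototype(transitions = data.frame(),
            cycleTimeMs = 500,
            polaritySwitching = FALSE))

setValidity("MRMMethod", function(object) {
  tr <- object@transitions
  if (nrow(tr) == 0L) return(TRUE)
  msgs <- character(0)
  need <- c("compound", "precursor_mz", "fragment_mz", "polarity", "ce_ev",
            "rt_min", "rt_window_min", "role")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    msgs <- c(msgs, paste("missing transition columns:",
                          paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    if (any(tr$ce_ev < 5 - 1e-9))
      msgs <- c(msgs, "collision energies below the 5 eV floor")
    if (any(tr$rt_window_min <= 0))
      msgs <- c(msgs, "non-positive RT windows")
    nq <- tapply(tr$role == "quantifier", tr$compound, sum)
    if (any(nq != 1L))
      msgs <- c(msgs, "every compound must have exactly one quantifier")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MRMMethod number of transitions
#' @param x,object an `MRMMethod`
#' @export
setMethod("length", "MRMMethod", function(x) nrow(x@transitions))

#' @describeIn MRMMethod transition table accessor
#' @export
setGeneric("transitions", function(object) standardGeneric("transitions"))

#' @rdname MRMMethod-class
#' @export
setMethod("transitions", "MRMMethod", function(object) object@transitions)

#' @describeIn MRMMethod cycle time accessor (milliseconds)
#' @export
setGeneric("cycleTime", function(object) standardGeneric("cycleTime"))

#' @rdname MRMMethod-class
#' @export
setMethod("cycleTime", "MRMMethod", function(object) object@cycleTimeMs)

setMethod("show", "MRMMethod", function(object) {
  tr <- object@transitions
  ncomp <- if (nrow(tr)) length(unique(tr$compound)) else 0L
  cat("MRMMethod with", nrow(tr), "transitions for", ncomp, "compounds\n")
  if (nrow(tr)) {
    cat("  polarity:", paste(sort(unique(tr$polarity)), collapse = "/"),
        if (object@polaritySwitching) "(switching)\n" else "\n")
    cat(sprintf("  RT window half-width: %.2f min; cycle time: %d ms\n",
                stats::median(tr$rt_window_min), as.integer(object@cycleTimeMs)))
    cat(sprintf("  CE range: %.1f-%.1f eV\n", min(tr$ce_ev), max(tr$ce_ev)))
  }
  invisible(NULL)
})

#' Ground truth of a synthetic run
#'
#' Planted composition of a simulated pooled-sample run: the compounds, their
#' fragments with continuous collision-energy response parameters, every
#' emitted MS1 feature with its provenance (monoisotopic, isotopologue,
#' adduct, in-source fragment), and the seed.  Fully determines the emitted
#' files; serializable with [writeManifest()].
#'
#' @slot compounds data.frame: one row per planted compound.
#' @slot fragments data.frame: one row per planted fragment with Gaussian
#'   response parameters (`mu_ev`, `sigma_ev`, `amplitude`).
#' @slot features data.frame: every MS1 feature with `kind` in
#'   monoisotopic/isotopologue/adduct/isf and its parent compound.
#' @slot seed integer seed the run was generated from.
#' @slot spec list: the generator specification used.
#'
#' @aliases GroundTruth-class
#' @export
setClass("GroundTruth",
  representation(compounds = "data.frame", fragments = "data.frame",
                 features = "data.frame", seed = "integer", spec = "list"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@compounds), "compounds,",
      nrow(object@fragments), "fragments,",
      nrow(object@features), "MS1 features (",
      sum(object@features$kind == "isf"), "planted ISFs ), seed",
      object@seed, "\n")
  invisible(NULL)
})

#' Result of an end-to-end pipeline run
#'
#' Bundles the stage-wise intermediates of [buildMRM()]: curated feature
#' tables, in-source-fragment assignments, per-compound transition
#' selections, the final [MRMMethod-class], and the stage-count accounting
#' (features with MS/MS, after isotope consolidation, after ISF removal).
#'
#' @slot method the final `MRMMethod`.
#' @slot compounds list of per-precursor transition selections.
#' @slot isfAssignments data.frame of in-source-fragment assignments.
#' @slot stageCounts named integer vector of per-stage feature counts.
#' @slot curated data.frame of curated precursor features.
#'
#' @aliases MRMRun-class
#' @export
setClass("MRMRun",
  representation(method = "MRMMethod", compounds = "list",
                 isfAssignments = "data.frame", stageCounts = "integer",
                 curated = "data.frame"))

setMethod("show", "MRMRun", function(object) {
  cat("MRMRun\n  stage counts:\n")
  sc <- object@stageCounts
  for (nm in names(sc)) cat(sprintf("    %-28s %d\n", nm, sc[[nm]]))
  cat("  transitions:", length(object@method), "\n")
  invisible(NULL)
})

#' @describeIn MRMRun extract the final MRM method
#' @param object an `MRMRun`
#' @export
setGeneric("mrmMethod", function(object) standardGeneric("mrmMethod"))

#' @rdname MRMRun-class
#' @export
setMethod("mrmMethod", "MRMRun", function(object) object@method)

#' @describeIn MRMRun per-stage feature counts
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))

#' @rdname MRMRun-class
#' @export
setMethod("stageCounts", "MRMRun", function(object) object@stageCounts)
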