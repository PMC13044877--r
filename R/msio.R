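#' Read an mzML run into a spectrum table
#'
#' Parses an mzML file (optionally gzip-compressed) into a data.frame with
#' one row per spectrum and a list-column of centroided peaks.  MS2 rows
#' carry the precursor m/z and, when encoded in the file, the collision
#' energy of the scan.  Spectra are returned in acquisition (retention-time)
#' order.  MS2 spectra lacking a precursor m/z are skipped with a warning;
#' MS1 spectra are never dropped.
#'
#' @param path path to an mzML file.
#' @return data.frame with columns `scan_id`, `ms_level`, `rt_min`,
#'   `polarity` ("positive"/"negative"), `precursor_mz`, `ce_ev`, `tic`, and
#'   list-column `peaks` (two-column matrix `mz`, `intensity`, sorted
#'   ascending in m/z).
#' @export
#' @seealso [writeMzMLRun()] for the writer used by the synthetic generator.
readMzML <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  if (nrow(hdr) == 0L) return(.emptySpectrumTable())
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  pk <- lapply(pk, function(m) {
    m <- m[order(m[, 1L]), , drop = FALSE]
    colnames(m) <- c("mz", "intensity")
    m
  })
  tab <- data.frame(
    scan_id = as.character(hdr$spectrumId),
    ms_level = as.integer(hdr$msLevel),
    rt_min = hdr$retentionTime / 60,
    polarity = ifelse(hdr$polarity == 1L, "positive", "negative"),
    precursor_mz = ifelse(hdr$msLevel >= 2L, hdr$precursorMZ, NA_real_),
    ce_ev = ifelse(hdr$msLevel >= 2L, hdr$collisionEnergy, NA_real_),
    tic = hdr$totIonCurrent,
    stringsAsFactors = FALSE)
  tab$peaks <- pk
  bad <- tab$ms_level >= 2L & !is.finite(tab$precursor_mz)
  if (any(bad)) {
    warning(sum(bad), " MS2 spectra lack a precursor m/z and were skipped")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab <- tab[order(tab$rt_min), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

.emptySpectrumTable <- function() {
  tab <- data.frame(scan_id = character(0), ms_level = integer(0),
                    rt_min = numeric(0), polarity = character(0),
                    precursor_mz = numeric(0), ce_ev = numeric(0),
                    tic = numeric(0), stringsAsFactors = FALSE)
  tab$peaks <- list()
  tab
}

#' Write spectra to a minimal mzML file
#'
#' Serializes a spectrum table (the format produced by [readMzML()]) to
#' standards-conformant centroid mzML, recording precursor m/z and collision
#' energy per MS2 scan.  Used by the synthetic-run generator; re-reading the
#' file reproduces the in-memory table.
#'
#' @param spectra spectrum table as returned by [readMzML()].
#' @param path output file path (`.mzML`).
#' @return `path`, invisibly.
#' @export
writeMzMLRun <- function(spectra, path) {
  n <- nrow(spectra)
  if (n == 0L) stop("cannot write an mzML file with zero spectra")
  pk <- lapply(spectra$peaks, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  npk <- vapply(pk, nrow, integer(1))
  bp <- function(m, col) if (nrow(m)) m[which.max(m[, 2L]), col] else NA_real_
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(spectra$ms_level),
    polarity = ifelse(spectra$polarity == "positive", 1L, 0L),
    peaksCount = npk,
    totIonCurrent = vapply(pk, function(m) sum(m[, 2L]), numeric(1)),
    retentionTime = spectra$rt_min * 60,
    basePeakMZ = vapply(pk, bp, numeric(1), col = 1L),
    basePeakIntensity = vapply(pk, bp, numeric(1), col = 2L),
    collisionEnergy = ifelse(spectra$ms_level >= 2L, spectra$ce_ev, NA_real_),
    ionisationEnergy = 0,
    lowMZ = vapply(pk, function(m) if (nrow(m)) min(m[, 1L]) else 0, numeric(1)),
    highMZ = vapply(pk, function(m) if (nrow(m)) max(m[, 1L]) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(spectra$ms_level >= 2L, spectra$precursor_mz, NA_real_),
    precursorCharge = ifelse(spectra$ms_level >= 2L, 1L, 0L),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = spectra$scan_id,
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(spectra$ms_level >= 2L,
                                     spectra$precursor_mz, NA_real_),
    isolationWindowLowerOffset = ifelse(spectra$ms_level >= 2L, 0.5, NA_real_),
    isolationWindowUpperOffset = ifelse(spectra$ms_level >= 2L, 0.5, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  suppressWarnings(
    mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml"))
  invisible(path)
}

#' Read an MS1 feature table
#'
#' Reads a centroided MS1 feature table from CSV.  Column names are mapped
#' through `mapping` (vendor exports vary); rows violating the feature
#' invariants (m/z > 0, RT >= 0, intensity > 0, known polarity) are rejected
#' with row-numbered diagnostics.
#'
#' @param path CSV path.
#' @param mapping named character vector mapping the canonical names
#'   `mz`, `rt`, `intensity`, `polarity` (and optionally `feature_id`,
#'   `charge`) to the file's column names.
#' @return data.frame with columns `feature_id`, `mz`, `rt_min`,
#'   `intensity`, `polarity`, `charge`.
#' @export
readFeatureTable <- function(path,
                             mapping = c(mz = "mz", rt = "rt",
                                         intensity = "intensity",
                                         polarity = "polarity")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("mz", "rt", "intensity", "polarity")
  for (nm in need) {
    col <- if (nm %in% names(mapping)) mapping[[nm]] else nm
    if (!col %in% names(raw))
      stop("feature table is missing mandatory column '", col,
           "' (mapped from '", nm, "')")
  }
  col <- function(nm, default = NULL) {
    src <- if (nm %in% names(mapping)) mapping[[nm]] else nm
    if (src %in% names(raw)) raw[[src]] else default
  }
  n <- nrow(raw)
  feat <- data.frame(
    feature_id = as.character(col("feature_id",
                                  default = sprintf("F%04d", seq_len(n)))),
    mz = as.numeric(col("mz")),
    rt_min = as.numeric(col("rt")),
    intensity = as.numeric(col("intensity")),
    polarity = as.character(col("polarity")),
    charge = {
      ch <- col("charge", default = rep(NA_integer_, n))
      suppressWarnings(as.integer(ch))
    },
    stringsAsFactors = FALSE)
  if (n == 0L) return(feat)
  ok <- is.finite(feat$mz) & feat$mz > 0 &
    is.finite(feat$rt_min) & feat$rt_min >= 0 &
    is.finite(feat$intensity) & feat$intensity > 0 &
    feat$polarity %in% c("positive", "negative")
  if (any(!ok)) {
    for (i in which(!ok))
      message("feature table row ", i, " rejected: ",
              "mz=", raw[[mapping[["mz"]]]][i],
              " intensity=", raw[[mapping[["intensity"]]]][i])
    feat <- feat[ok, , drop = FALSE]
    rownames(feat) <- NULL
  }
  feat
}

.TRANSITION_COLS <- c("compound", "precursor_mz", "fragment_mz", "polarity",
                      "ce_ev", "rt_min", "rt_window_min", "role", "peak_area")

.validateTransitions <- function(rows) {
  msgs <- character(0)
  miss <- setdiff(setdiff(.TRANSITION_COLS, "peak_area"), names(rows))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(rows) == 0L) return(character(0))
  bad <- which(rows$ce_ev < 5 - 1e-9)
  if (length(bad))
    msgs <- c(msgs, paste("rows with CE below 5 eV:",
                          paste(bad, collapse = ", ")))
  bad <- which(rows$rt_window_min <= 0)
  if (length(bad))
    msgs <- c(msgs, paste("rows with non-positive RT window:",
                          paste(bad, collapse = ", ")))
  bad <- which(!rows$role %in% c("quantifier", "qualifier"))
  if (length(bad))
    msgs <- c(msgs, paste("rows with unknown role:",
                          paste(bad, collapse = ", ")))
  nq <- tapply(rows$role == "quantifier", rows$compound, sum)
  off <- names(nq)[nq != 1L]
  if (length(off))
    msgs <- c(msgs, paste("compounds without exactly one quantifier:",
                          paste(off, collapse = ", ")))
  msgs
}

#' Write a transition table to CSV
#'
#' Emits the vendor-agnostic transition CSV in the fixed column order
#' `compound, precursor_mz, fragment_mz, polarity, ce_ev, rt_min,
#' rt_window_min, role, peak_area`, formatting m/z at 4 decimal places,
#' retention times at 2 and collision energies at 1 (triple-quadrupole
#' method-editor precision).  Rows must satisfy the transition invariants
#' (CE >= 5 eV, positive RT windows, exactly one quantifier per compound);
#' violations abort with a listing of the offending rows.
#'
#' @param rows data.frame of transitions, or an [MRMMethod-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTransitionCSV <- function(rows, path) {
  if (is(rows, "MRMMethod")) rows <- transitions(rows)
  msgs <- .validateTransitions(rows)
  if (length(msgs))
    stop("invalid transition rows:\n  ", paste(msgs, collapse = "\n  "))
  if (!"peak_area" %in% names(rows)) rows$peak_area <- NA_real_
  out <- data.frame(
    compound = rows$compound,
    precursor_mz = sprintf("%.4f", rows$precursor_mz),
    fragment_mz = sprintf("%.4f", rows$fragment_mz),
    polarity = rows$polarity,
    ce_ev = sprintf("%.1f", rows$ce_ev),
    rt_min = sprintf("%.2f", rows$rt_min),
    rt_window_min = sprintf("%.2f", rows$rt_window_min),
    role = rows$role,
    peak_area = ifelse(is.na(rows$peak_area), "",
                       sprintf("%.1f", rows$peak_area)),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transition table from CSV
#'
#' Inverse of [writeTransitionCSV()]; also accepts user-supplied reference
#' transition tables in the same schema (the `role` column identifies the
#' reference quantifier).
#'
#' @param path CSV path.
#' @return data.frame in the standard transition schema.
#' @export
readTransitionCSV <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(.TRANSITION_COLS, "peak_area"), names(tab))
  if (length(miss))
    stop("transition CSV is missing columns: ", paste(miss, collapse = ", "))
  if (!"peak_area" %in% names(tab)) tab$peak_area <- NA_real_
  tab$peak_area <- suppressWarnings(as.numeric(tab$peak_area))
  for (nm in c("precursor_mz", "fragment_mz", "ce_ev", "rt_min",
               "rt_window_min"))
    tab[[nm]] <- as.numeric(tab[[nm]])
  tab[, .TRANSITION_COLS]
}

#' Validate a transition CSV
#'
#' Schema check used by the command-line `validate` subcommand.
#'
#' @param path CSV path.
#' @return invisibly, a character vector of problems (empty when valid).
#' @export
validateTransitionCSV <- function(path) {
  tab <- tryCatch(readTransitionCSV(path), error = function(e) e$message)
  if (is.character(tab)) return(invisible(tab))
  invisible(.validateTransitions(tab))
}
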