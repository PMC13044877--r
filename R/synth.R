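#' Specification for a synthetic pooled-sample run
#'
#' Describes the composition of a simulated discovery experiment: compounds
#' with Gaussian per-fragment collision-energy response curves sampled at
#' 0/10/20/40 eV, isotope envelopes with geometric decay, optional sodium
#' (formate in negative mode) adduct features, and coeluting in-source
#' fragments that mirror a fragment present in the parent's 0 eV spectrum.
#' The defaults are the package's reference study conditions; noiseless
#' runs are obtained with `noise = NULL`.
#'
#' @param n_compounds number of planted compounds.
#' @param n_isf number of planted in-source-fragment features (each
#'   attached to a distinct compound; must not exceed `n_compounds`).
#' @param polarity "positive" or "negative".
#' @param mass_range neutral monoisotopic mass range (Da).
#' @param rt_range retention-time range (minutes).
#' @param n_fragments_range fragments planted per compound (inclusive range).
#' @param mu_range,sigma_range Gaussian response peak location and width
#'   ranges (eV); the continuous-curve argmax `mu` is the oracle for
#'   collision-energy recovery.
#' @param isotope_ratios intensities of the +1, +2, ... isotopologue
#'   features relative to the monoisotopic feature.
#' @param adduct_prob probability that a compound also yields a redundant
#'   adduct feature ([M+Na]+ positive, [M+HCOO]- negative).
#' @param min_peak_intensity MS/MS detection threshold (counts); response
#'   values below it are not observed, so narrow curves yield low-coverage
#'   profiles that exercise the fallback path.
#' @param noise list with `intensity_sdlog` (multiplicative log-normal on
#'   every intensity), `mz_jitter_ppm` (uniform m/z jitter) and
#'   `rt_jitter_min` (Gaussian RT jitter), or `NULL` for a noiseless run.
#' @return list of class `generatorSpec`.
#' @export
generatorSpec <- function(n_compounds = 100, n_isf = 60,
                          polarity = "positive",
                          mass_range = c(120, 900), rt_range = c(1, 14),
                          n_fragments_range = c(3, 8),
                          mu_range = c(5, 38), sigma_range = c(5, 15),
                          isotope_ratios = c(0.2, 0.04),
                          adduct_prob = 0.3,
                          min_peak_intensity = 1,
                          noise = list(intensity_sdlog = 0.2,
                                       mz_jitter_ppm = 3,
                                       rt_jitter_min = 0.01)) {
  if (n_compounds < 0) stop("n_compounds must be non-negative")
  if (n_isf > n_compounds)
    stop("n_isf must not exceed n_compounds: each planted in-source ",
         "fragment needs its own parent compound")
  stopifnot(polarity %in% c("positive", "negative"))
  structure(list(n_compounds = as.integer(n_compounds),
                 n_isf = as.integer(n_isf), polarity = polarity,
                 mass_range = mass_range, rt_range = rt_range,
                 n_fragments_range = as.integer(n_fragments_range),
                 mu_range = mu_range, sigma_range = sigma_range,
                 isotope_ratios = isotope_ratios,
                 adduct_prob = adduct_prob,
                 min_peak_intensity = min_peak_intensity,
                 noise = noise),
            class = "generatorSpec")
}

# Gaussian collision-energy response
.ceResponse <- function(ce, amplitude, mu, sigma)
  amplitude * exp(-(ce - mu)^2 / (2 * sigma^2))

.SAMPLED_CES <- c(0, 10, 20, 40)

#' Generate a synthetic pooled-sample run with ground truth
#'
#' Emits an MS1 feature table (monoisotopic + isotopologue + adduct +
#' in-source-fragment features), an mzML file with one MS2 spectrum per
#' (MS/MS-bearing feature, collision energy) whose fragment intensities
#' follow the planted response curves, and a ground-truth manifest.
#' Regeneration with the same seed is byte-identical.
#'
#' Planted fragment amplitudes are spaced so that, per compound, the
#' sampled-maximum intensities of successive fragments differ by at least
#' 25%; the planted quantifier (most intense stable fragment) is therefore
#' unambiguous and serves as an exact oracle for transition selection.
#'
#' @param spec a [generatorSpec()].
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @return list with paths `feature_table`, `mzml`, `manifest`, the
#'   [GroundTruth-class] object `truth`, and the in-memory `features` and
#'   `spectra` tables.
#' @export
generateRun <- function(spec = generatorSpec(), seed = 1L, outdir = tempfile()) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  nz <- spec$noise
  jmz <- function(mz) if (is.null(nz)) mz else
    mz * (1 + stats::runif(length(mz), -1, 1) * nz$mz_jitter_ppm * 1e-6)
  jrt <- function(rt) if (is.null(nz)) rt else
    rt + stats::rnorm(length(rt), 0, nz$rt_jitter_min)
  jint <- function(i) if (is.null(nz)) i else
    i * exp(stats::rnorm(length(i), 0, nz$intensity_sdlog))

  nc <- spec$n_compounds
  base_delta <- if (spec$polarity == "positive") .PROTON else -.PROTON
  add_delta <- if (spec$polarity == "positive") 22.989218 else 44.998201
  add_label <- if (spec$polarity == "positive") "[M+Na]+" else "[M+HCOO]-"

  compounds <- data.frame(compound_id = character(0), neutral_mass = numeric(0),
                          precursor_mz = numeric(0), rt_min = numeric(0),
                          abundance = numeric(0), has_adduct = logical(0),
                          stringsAsFactors = FALSE)
  fragments <- list(); features <- list(); spectra <- list()
  fid <- 0L; sid <- 0L
  newFid <- function() { fid <<- fid + 1L; sprintf("F%04d", fid) }

  if (nc > 0L) {
    neutral <- stats::runif(nc, spec$mass_range[1], spec$mass_range[2])
    rt <- stats::runif(nc, spec$rt_range[1], spec$rt_range[2])
    abund <- stats::rlnorm(nc, meanlog = log(1e6), sdlog = 0.5)
    has_add <- stats::runif(nc) < spec$adduct_prob
    isf_parents <- if (spec$n_isf > 0L)
      sort(sample.int(nc, spec$n_isf)) else integer(0)
    compounds <- data.frame(
      compound_id = sprintf("C%04d", seq_len(nc)), neutral_mass = neutral,
      precursor_mz = neutral + base_delta, rt_min = rt, abundance = abund,
      has_adduct = has_add, stringsAsFactors = FALSE)

    for (ci in seq_len(nc)) {
      prec_mz <- compounds$precursor_mz[ci]
      nfr <- sample(seq(spec$n_fragments_range[1], spec$n_fragments_range[2]),
                    1L)
      # fragment m/z at least 10 Da below the precursor, pairwise >= 2 Da
      fmz <- numeric(0)
      while (length(fmz) < nfr) {
        cand <- stats::runif(1, 50, prec_mz - 10)
        if (!length(fmz) || min(abs(fmz - cand)) >= 2) fmz <- c(fmz, cand)
      }
      mu <- stats::runif(nfr, spec$mu_range[1], spec$mu_range[2])
      sg <- stats::runif(nfr, spec$sigma_range[1], spec$sigma_range[2])
      amp <- compounds$abundance[ci] * stats::runif(nfr, 0.05, 1)
      is_isf_src <- rep(FALSE, nfr)
      if (ci %in% isf_parents) {
        # dedicated in-source-capable fragment: detectable at 0 eV and
        # persisting at higher energies by construction
        fmz_i <- NA_real_
        repeat {
          fmz_i <- stats::runif(1, 50, prec_mz - 10)
          if (min(abs(fmz - fmz_i)) >= 2) break
        }
        fmz <- c(fmz, fmz_i)
        mu <- c(mu, stats::runif(1, 5, 15))
        sg <- c(sg, stats::runif(1, 8, 15))
        amp <- c(amp, compounds$abundance[ci] * stats::runif(1, 0.3, 1))
        is_isf_src <- c(is_isf_src, TRUE)
        nfr <- nfr + 1L
      }
      # enforce >= 25% separation of sampled-maximum intensities so the
      # planted quantifier is unambiguous
      smax <- vapply(seq_len(nfr), function(j)
        max(.ceResponse(.SAMPLED_CES, amp[j], mu[j], sg[j])), numeric(1))
      ord <- order(-smax)
      for (r in seq_along(ord)[-1L]) {
        j <- ord[r]; jprev <- ord[r - 1L]
        if (smax[j] > 0.75 * smax[jprev]) {
          scale <- 0.7 * smax[jprev] / smax[j]
          amp[j] <- amp[j] * scale; smax[j] <- smax[j] * scale
        }
      }
      fragments[[ci]] <- data.frame(
        compound_id = compounds$compound_id[ci], fragment_mz = fmz,
        mu_ev = mu, sigma_ev = sg, amplitude = amp,
        is_isf_source = is_isf_src, stringsAsFactors = FALSE)
    }
    fragTab <- do.call(rbind, fragments)

    # --- MS1 features ------------------------------------------------------
    addFeature <- function(mz, rt, int, kind, compound_id, adduct = NA,
                           source_fragment_mz = NA_real_) {
      id <- newFid()
      features[[length(features) + 1L]] <<- data.frame(
        feature_id = id, mz = jmz(mz), rt_min = jrt(rt),
        intensity = jint(int), kind = kind, compound_id = compound_id,
        adduct = adduct, source_fragment_mz = source_fragment_mz,
        stringsAsFactors = FALSE)
      id
    }
    for (ci in seq_len(nc)) {
      with_c <- compounds[ci, ]
      base_id <- addFeature(with_c$precursor_mz, with_c$rt_min,
                            with_c$abundance, "monoisotopic",
                            with_c$compound_id,
                            adduct = if (spec$polarity == "positive")
                              "[M+H]+" else "[M-H]-")
      for (k in seq_along(spec$isotope_ratios))
        addFeature(with_c$precursor_mz + k * .C13_SPACING, with_c$rt_min,
                   with_c$abundance * spec$isotope_ratios[k],
                   "isotopologue", with_c$compound_id)
      if (with_c$has_adduct) {
        amz <- with_c$neutral_mass + add_delta
        aint <- with_c$abundance * stats::runif(1, 0.1, 0.45)
        addFeature(amz, with_c$rt_min, aint, "adduct", with_c$compound_id,
                   adduct = add_label)
        for (k in seq_along(spec$isotope_ratios))
          addFeature(amz + k * .C13_SPACING, with_c$rt_min,
                     aint * spec$isotope_ratios[k], "isotopologue",
                     with_c$compound_id)
      }
    }
    for (ci in isf_parents) {
      fr <- fragments[[ci]]
      src <- fr[fr$is_isf_source, , drop = FALSE][1L, ]
      addFeature(src$fragment_mz,
                 compounds$rt_min[ci] + stats::runif(1, -0.02, 0.02),
                 compounds$abundance[ci] * stats::runif(1, 0.05, 0.5),
                 "isf", compounds$compound_id[ci],
                 source_fragment_mz = src$fragment_mz)
    }
    featTab <- do.call(rbind, features)

    # --- MS2 spectra: monoisotopic and ISF features are triggered ---------
    addSpectrum <- function(prec_mz, rt, ce, peaks) {
      sid <<- sid + 1L
      keep <- peaks[, 2L] >= spec$min_peak_intensity
      peaks <- peaks[keep, , drop = FALSE]
      if (nrow(peaks) == 0L) return(invisible(NULL))
      peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
      colnames(peaks) <- c("mz", "intensity")
      spectra[[length(spectra) + 1L]] <<- list(
        scan_id = sprintf("scan=%d", sid), ms_level = 2L,
        rt_min = jrt(rt), polarity = spec$polarity,
        precursor_mz = prec_mz, ce_ev = ce,
        tic = sum(peaks[, 2L]), peaks = peaks)
      invisible(NULL)
    }
    monoFeat <- featTab[featTab$kind == "monoisotopic", , drop = FALSE]
    for (r in seq_len(nrow(monoFeat))) {
      ci <- match(monoFeat$compound_id[r], compounds$compound_id)
      fr <- fragments[[ci]]
      for (ce in .SAMPLED_CES) {
        ints <- jint(.ceResponse(ce, fr$amplitude, fr$mu_ev, fr$sigma_ev))
        pk <- cbind(jmz(fr$fragment_mz), ints)
        # residual unfragmented precursor, decaying with energy
        pk <- rbind(pk, c(monoFeat$mz[r],
                          jint(compounds$abundance[ci] * exp(-ce / 10))))
        addSpectrum(monoFeat$mz[r], monoFeat$rt_min[r], ce, pk)
      }
    }
    isfFeat <- featTab[featTab$kind == "isf", , drop = FALSE]
    for (r in seq_len(nrow(isfFeat))) {
      ci <- match(isfFeat$compound_id[r], compounds$compound_id)
      fr <- fragments[[ci]]
      sub <- fr[fr$fragment_mz < isfFeat$mz[r] - 2, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (ce in .SAMPLED_CES) {
        ints <- jint(.ceResponse(ce, sub$amplitude, sub$mu_ev, sub$sigma_ev))
        addSpectrum(isfFeat$mz[r], isfFeat$rt_min[r], ce,
                    cbind(jmz(sub$fragment_mz), ints))
      }
    }
  } else {
    fragTab <- data.frame(compound_id = character(0), fragment_mz = numeric(0),
                          mu_ev = numeric(0), sigma_ev = numeric(0),
                          amplitude = numeric(0), is_isf_source = logical(0),
                          stringsAsFactors = FALSE)
    featTab <- data.frame(feature_id = character(0), mz = numeric(0),
                          rt_min = numeric(0), intensity = numeric(0),
                          kind = character(0), compound_id = character(0),
                          adduct = character(0),
                          source_fragment_mz = numeric(0),
                          stringsAsFactors = FALSE)
  }

  specTab <- if (length(spectra)) {
    tab <- data.frame(
      scan_id = vapply(spectra, `[[`, character(1), "scan_id"),
      ms_level = vapply(spectra, `[[`, integer(1), "ms_level"),
      rt_min = vapply(spectra, `[[`, numeric(1), "rt_min"),
      polarity = vapply(spectra, `[[`, character(1), "polarity"),
      precursor_mz = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
      ce_ev = vapply(spectra, `[[`, numeric(1), "ce_ev"),
      tic = vapply(spectra, `[[`, numeric(1), "tic"),
      stringsAsFactors = FALSE)
    tab$peaks <- lapply(spectra, `[[`, "peaks")
    tab <- tab[order(tab$rt_min), , drop = FALSE]
    tab$scan_id <- sprintf("scan=%d", seq_len(nrow(tab)))
    rownames(tab) <- NULL
    tab
  } else .emptySpectrumTable()

  truth <- methods::new("GroundTruth", compounds = compounds,
                        fragments = fragTab, features = featTab,
                        seed = as.integer(seed), spec = unclass(spec))

  feature_csv <- file.path(outdir, "features.csv")
  ftab <- featTab[, c("feature_id", "mz", "rt_min", "intensity"),
                  drop = FALSE]
  names(ftab)[names(ftab) == "rt_min"] <- "rt"
  ftab$polarity <- rep(spec$polarity, nrow(ftab))
  utils::write.csv(ftab, feature_csv, row.names = FALSE, quote = FALSE)

  mzml <- NULL
  if (nrow(specTab)) {
    mzml <- file.path(outdir, "run.mzML")
    writeMzMLRun(specTab, mzml)
  }
  manifest <- file.path(outdir, "manifest.json")
  writeManifest(truth, manifest)
  list(feature_table = feature_csv, mzml = mzml, manifest = manifest,
       truth = truth, features = featTab, spectra = specTab)
}

#' Serialize / restore a ground-truth manifest
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON path.
#' @return `path` (write) or the restored `GroundTruth` (read).
#' @export
writeManifest <- function(truth, path) {
  jsonlite::write_json(
    list(seed = truth@seed, spec = truth@spec, compounds = truth@compounds,
         fragments = truth@fragments, features = truth@features),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  asDf <- function(x, tpl) if (is.data.frame(x) && nrow(x)) x else tpl
  methods::new("GroundTruth",
               compounds = asDf(m$compounds, data.frame()),
               fragments = asDf(m$fragments, data.frame()),
               features = asDf(m$features, data.frame()),
               seed = as.integer(m$seed), spec = as.list(m$spec))
}

#' Score a pipeline run against the planted ground truth
#'
#' Compares an end-to-end run with the generator's manifest and reports:
#' in-source-fragment recall and precision, true-precursor retention rate,
#' per-fragment collision-energy error (predicted minus the analytic argmax
#' of the planted continuous response curve), fragment m/z agreement within
#' ±0.5 Da, and the quantifier identity rate (emitted quantifier equals the
#' planted most intense stable fragment).  Summary statistics are the
#' median signed error, median absolute error, and the percentages within
#' ±5 and ±10 eV.
#'
#' @param run an [MRMRun-class] from [buildMRM()].
#' @param truth the matching [GroundTruth-class].
#' @param match_tol_da fragment matching tolerance (Da).
#' @param ppm precursor matching tolerance.
#' @return list of metrics; `delta_ce` holds the per-fragment errors.
#' @export
scoreAgainstTruth <- function(run, truth, match_tol_da = 0.5, ppm = 10) {
  feats <- truth@features
  planted_isf <- feats$feature_id[feats$kind == "isf"]
  removed <- run@isfAssignments$fragment_feature
  isf_recall <- if (length(planted_isf))
    mean(planted_isf %in% removed) else NA_real_
  isf_precision <- if (length(removed))
    mean(removed %in% planted_isf) else NA_real_

  mono_ids <- feats$feature_id[feats$kind == "monoisotopic"]
  retained_ids <- run@curated$feature_id
  retention <- if (length(mono_ids))
    mean(mono_ids %in% retained_ids) else NA_real_
  true_removed <- if (length(mono_ids))
    sum(mono_ids %in% removed) else 0L

  tr <- transitions(run@method)
  delta_ce <- numeric(0); frag_match <- logical(0)
  quant_hit <- logical(0)
  if (nrow(tr) && nrow(truth@compounds)) {
    for (ci in seq_len(nrow(truth@compounds))) {
      cmp <- truth@compounds[ci, ]
      rows <- tr[abs(tr$precursor_mz - cmp$precursor_mz) <=
                   .ppmTol(cmp$precursor_mz, ppm) +
                   cmp$precursor_mz * 4e-6 &   # generator m/z jitter margin
                   abs(tr$rt_min - cmp$rt_min) <= 0.3, , drop = FALSE]
      if (!nrow(rows)) next
      fr <- truth@fragments[truth@fragments$compound_id == cmp$compound_id, ]
      for (r in seq_len(nrow(rows))) {
        d <- abs(fr$fragment_mz - rows$fragment_mz[r])
        hit <- which.min(d)
        ok <- length(hit) && d[hit] <= match_tol_da
        frag_match <- c(frag_match, ok)
        if (ok) delta_ce <- c(delta_ce, rows$ce_ev[r] - fr$mu_ev[hit])
      }
      # planted quantifier: max sampled-peak intensity among fragments
      # detectable at >= 3 energies (the stability criterion)
      det <- vapply(seq_len(nrow(fr)), function(j)
        sum(.ceResponse(.SAMPLED_CES, fr$amplitude[j], fr$mu_ev[j],
                        fr$sigma_ev[j]) >=
              truth@spec$min_peak_intensity), numeric(1))
      stable <- which(det >= 3)
      if (length(stable)) {
        smax <- vapply(stable, function(j)
          max(.ceResponse(.SAMPLED_CES, fr$amplitude[j], fr$mu_ev[j],
                          fr$sigma_ev[j])), numeric(1))
        planted_q <- fr$fragment_mz[stable[which.max(smax)]]
        emitted_q <- rows$fragment_mz[rows$role == "quantifier"]
        if (length(emitted_q))
          quant_hit <- c(quant_hit,
                         abs(emitted_q[1L] - planted_q) <= match_tol_da)
      }
    }
  }
  list(isf_recall = isf_recall, isf_precision = isf_precision,
       precursor_retention = retention,
       true_precursors_removed = true_removed,
       n_fragments_scored = length(delta_ce),
       fragment_match_rate = if (length(frag_match)) mean(frag_match)
         else NA_real_,
       delta_ce = delta_ce,
       median_delta_ce = if (length(delta_ce)) stats::median(delta_ce)
         else NA_real_,
       median_abs_delta_ce = if (length(delta_ce))
         stats::median(abs(delta_ce)) else NA_real_,
       pct_within_5ev = if (length(delta_ce))
         100 * mean(abs(delta_ce) <= 5) else NA_real_,
       pct_within_10ev = if (length(delta_ce))
         100 * mean(abs(delta_ce) <= 10) else NA_real_,
       quantifier_identity_rate = if (length(quant_hit)) mean(quant_hit)
         else NA_real_)
}
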