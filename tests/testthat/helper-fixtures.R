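# Shared in-code fixtures for the test suite.

makeFeatures <- function(mz, rt, intensity, polarity = "positive",
                         id = sprintf("F%03d", seq_along(mz))) {
  data.frame(feature_id = id, mz = mz, rt_min = rt, intensity = intensity,
             polarity = rep(polarity, length.out = length(mz)),
             charge = rep(NA_integer_, length(mz)),
             stringsAsFactors = FALSE)
}

# spectrum table row(s) in the readMzML() schema
makeSpectra <- function(ms_level, rt, peaks, precursor_mz = NA_real_,
                        ce = NA_real_, polarity = "positive") {
  n <- length(ms_level)
  tab <- data.frame(
    scan_id = sprintf("scan=%d", seq_len(n)), ms_level = as.integer(ms_level),
    rt_min = rt, polarity = polarity,
    precursor_mz = precursor_mz, ce_ev = ce,
    tic = vapply(peaks, function(m) sum(m[, 2L]), numeric(1)),
    stringsAsFactors = FALSE)
  tab$peaks <- lapply(peaks, function(m) {
    m <- m[order(m[, 1L]), , drop = FALSE]
    colnames(m) <- c("mz", "intensity")
    m
  })
  tab
}

pk <- function(mz, int) cbind(mz, int)

# a single fragment profile row in the trackFragments() schema
makeProfile <- function(ce, intensity, mz = 150) {
  out <- data.frame(group_mz = mz, n_energies = length(ce),
                    eligible_for_spline = length(ce) >= 3L,
                    irregular = FALSE, stringsAsFactors = FALSE)
  out$ce_ev <- list(ce)
  out$intensity <- list(intensity)
  out
}

# stepped-energy MS2 spectra for one precursor whose fragments follow
# Gaussian CE-response curves; returns a spectrum table
gaussianSpectra <- function(prec_mz, rt, frag_mz, amplitude, mu, sigma,
                            ces = c(0, 10, 20, 40), polarity = "positive") {
  peaks <- lapply(ces, function(ce) {
    p <- pk(frag_mz, amplitude * exp(-(ce - mu)^2 / (2 * sigma^2)))
    p[p[, 2] >= 1, , drop = FALSE]        # detection threshold
  })
  keep <- vapply(peaks, nrow, integer(1)) > 0L
  makeSpectra(rep(2L, sum(keep)), rep(rt, sum(keep)), peaks[keep],
              precursor_mz = prec_mz, ce = ces[keep], polarity = polarity)
}

# valid transition rows for CSV tests
makeTransitionRows <- function(n_compounds = 2, n_qual = 1) {
  rows <- list()
  for (i in seq_len(n_compounds)) {
    prec <- 200 + i * 10.1234
    rt <- 2 + i * 0.37
    lbl <- sprintf("cmp%02d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      compound = lbl, precursor_mz = prec, fragment_mz = prec - 50.0213,
      polarity = "positive", ce_ev = 20.5, rt_min = rt,
      rt_window_min = 0.3, role = "quantifier", peak_area = NA_real_,
      stringsAsFactors = FALSE)
    for (q in seq_len(n_qual))
      rows[[length(rows) + 1L]] <- data.frame(
        compound = lbl, precursor_mz = prec,
        fragment_mz = prec - 80.1 - q, polarity = "positive",
        ce_ev = 15, rt_min = rt, rt_window_min = 0.3, role = "qualifier",
        peak_area = NA_real_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
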