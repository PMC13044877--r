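# predictions table for one precursor, built through the real spline path
predictionsFor <- function(prec_mz, frag_mz, amplitude, mu = NULL,
                           sigma = NULL, rt = 5) {
  n <- length(frag_mz)
  if (is.null(mu)) mu <- rep(20, n)
  if (is.null(sigma)) sigma <- rep(10, n)
  sp <- gaussianSpectra(prec_mz, rt, frag_mz, amplitude, mu, sigma)
  p <- makeFeatures(prec_mz, rt, 1e6)[1, , drop = FALSE]
  set <- buildSpectrumSets(p, sp, trackingConfig())$sets[[1]]
  list(precursor = p,
       predictions = predictCE(trackFragments(set, trackingConfig())))
}

test_that("the most intense stable fragment becomes the quantifier", {
  px <- predictionsFor(400.2, c(150.1, 220.3), c(1000, 400))
  cmp <- selectTransitions(px$precursor, px$predictions, selectionConfig())
  expect_equal(cmp$quantifier$fragment_mz, 150.1, tolerance = 1e-3)
  expect_equal(cmp$qualifiers$fragment_mz, 220.3, tolerance = 1e-3)
  expect_false(cmp$single_transition)
  expect_equal(cmp$mode, "empirical")
})

test_that("fragments closer than 2 Da to the precursor are never emitted", {
  px <- predictionsFor(400.2, c(398.7, 320.5, 150.1), c(1000, 800, 600))
  cmp <- selectTransitions(px$precursor, px$predictions, selectionConfig())
  # 398.7 (1.5 Da below) is excluded; next candidates promoted
  expect_equal(cmp$quantifier$fragment_mz, 320.5, tolerance = 1e-3)
  expect_equal(cmp$qualifiers$fragment_mz, 150.1, tolerance = 1e-3)
})

test_that("a single reproducible fragment yields a quantifier-only compound", {
  px <- predictionsFor(400.2, 150.1, 1000)
  cmp <- selectTransitions(px$precursor, px$predictions, selectionConfig())
  expect_equal(nrow(cmp$qualifiers), 0L)
  expect_true(cmp$single_transition)
})

test_that("fallback-only profiles still yield a flagged single transition", {
  # narrow response detected at one energy only
  px <- predictionsFor(400.2, 150.1, 1000, mu = 40, sigma = 2)
  expect_lt(px$predictions$n_energies[1], 3L)
  cmp <- selectTransitions(px$precursor, px$predictions, selectionConfig())
  expect_true(cmp$single_transition)
  expect_equal(nrow(cmp$qualifiers), 0L)
})

test_that("compounds with no usable profile are dropped with a diagnostic", {
  p <- makeFeatures(400.2, 5, 1e6)[1, , drop = FALSE]
  empty <- predictCE(trackFragments(
    buildSpectrumSets(p, makeSpectra(2L, 5, list(pk(399.5, 10)),
                                     precursor_mz = 400.2, ce = 20),
                      trackingConfig())$sets[[1]], trackingConfig()))
  expect_message(out <- selectTransitions(p, empty, selectionConfig()),
                 "dropped")
  expect_null(out)
})

test_that("reference fragments are promoted with empirically modelled CE", {
  px <- predictionsFor(400.2, c(150.1, 184.10), c(1000, 400))
  cmp <- selectTransitions(px$precursor, px$predictions, selectionConfig())
  expect_equal(cmp$quantifier$fragment_mz, 150.1, tolerance = 1e-3)
  ref <- data.frame(compound = "lib1", precursor_mz = 400.2,
                    fragment_mz = 184.07, polarity = "positive",
                    ce_ev = 35, rt_min = 5, rt_window_min = 0.3,
                    role = "quantifier", peak_area = NA_real_,
                    stringsAsFactors = FALSE)
  guided <- applyReferenceGuide(cmp, ref, selectionConfig())
  expect_equal(guided$mode, "reference_guided")
  expect_equal(guided$quantifier$fragment_mz, 184.10, tolerance = 1e-3)
  # CE comes from the spline model, not the reference table
  expect_false(isTRUE(all.equal(guided$quantifier$ce_ev, 35)))
  expect_equal(guided$quantifier$ce_ev,
               px$predictions$ce_opt_ev[
                 which.min(abs(px$predictions$group_mz - 184.10))],
               tolerance = 1e-6)
})

test_that("unmatched or empty references leave the compound empirical", {
  px <- predictionsFor(400.2, c(150.1, 220.3), c(1000, 400))
  cmp <- selectTransitions(px$precursor, px$predictions, selectionConfig())
  far <- data.frame(compound = "x", precursor_mz = 400.2,
                    fragment_mz = 260.0, polarity = "positive", ce_ev = 30,
                    rt_min = 5, rt_window_min = 0.3, role = "quantifier",
                    peak_area = NA_real_, stringsAsFactors = FALSE)
  expect_equal(applyReferenceGuide(cmp, far, selectionConfig())$mode,
               "empirical")
  expect_identical(applyReferenceGuide(cmp, far[0, ], selectionConfig()),
                   cmp)
})

test_that("merging unions sets and collapses duplicate compounds", {
  a <- selectTransitions(predictionsFor(400.2, c(150.1, 220.3),
                                        c(1000, 400))$precursor,
                         predictionsFor(400.2, c(150.1, 220.3),
                                        c(1000, 400))$predictions)
  b_px <- predictionsFor(400.2 * (1 + 3e-6), c(150.1, 220.3), c(2000, 500),
                         rt = 5.1)
  b <- selectTransitions(b_px$precursor, b_px$predictions)
  c_px <- predictionsFor(600.8, c(230.2, 410.0), c(900, 300), rt = 8)
  cc <- selectTransitions(c_px$precursor, c_px$predictions)

  m <- mergeExperimentSets(list(list(a), list(b, cc)), selectionConfig())
  tr <- transitions(m)
  expect_equal(length(unique(tr$compound)), 2L)   # a and b collapsed
  # the higher-intensity provenance wins
  dup <- tr[abs(tr$precursor_mz - 400.2) < 0.01 & tr$role == "quantifier", ]
  expect_equal(dup$precursor_mz, b_px$precursor$mz)
  expect_false(m@polaritySwitching)
  expect_equal(cycleTime(m), 500)
  expect_equal(unique(tr$rt_window_min), 0.3)
  # merge is order-insensitive
  m2 <- mergeExperimentSets(list(list(cc, b), list(a)), selectionConfig())
  key <- function(x) {
    tt <- transitions(x)
    tt <- tt[order(tt$precursor_mz, tt$fragment_mz), ]
    rownames(tt) <- NULL
    tt[, c("precursor_mz", "fragment_mz", "ce_ev", "role")]
  }
  expect_equal(key(m), key(m2))
})

test_that("method invariants hold on a full synthetic run", {
  run <- generateRun(generatorSpec(n_compounds = 15, n_isf = 5), seed = 21)
  res <- suppressMessages(buildMRM(run$feature_table, run$mzml, runConfig()))
  m <- mrmMethod(res)
  expect_true(validObject(m))
  tr <- transitions(m)
  expect_true(all(abs(tr$precursor_mz - tr$fragment_mz) >= 2.0))
  expect_true(all(tr$ce_ev >= 5 & tr$ce_ev <= 40))
  nq <- tapply(tr$role == "quantifier", tr$compound, sum)
  expect_true(all(nq == 1L))
})
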