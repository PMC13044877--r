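test_that("generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- generatorSpec(n_compounds = 8, n_isf = 3)
  r1 <- generateRun(spec, seed = 5, outdir = d1)
  r2 <- generateRun(spec, seed = 5, outdir = d2)
  for (f in c("feature_table", "mzml", "manifest"))
    expect_identical(unname(tools::md5sum(r1[[f]])),
                     unname(tools::md5sum(r2[[f]])))
  r3 <- generateRun(spec, seed = 6, outdir = withr::local_tempdir())
  expect_false(tools::md5sum(r1$feature_table) ==
                 tools::md5sum(r3$feature_table))
})

test_that("an empty specification produces empty outputs", {
  r <- generateRun(generatorSpec(n_compounds = 0, n_isf = 0),
                   seed = 1, outdir = withr::local_tempdir())
  expect_equal(nrow(readFeatureTable(r$feature_table)), 0L)
  expect_null(r$mzml)
  truth <- readManifest(r$manifest)
  expect_equal(nrow(truth@compounds), 0L)
})

test_that("infeasible specifications are rejected", {
  expect_error(generatorSpec(n_compounds = 5, n_isf = 10), "parent")
  expect_error(generatorSpec(n_compounds = -1), "non-negative")
})

test_that("the emitted mzML re-reads to the in-memory spectra", {
  r <- generateRun(generatorSpec(n_compounds = 6, n_isf = 2), seed = 13,
                   outdir = withr::local_tempdir())
  back <- readMzML(r$mzml)
  expect_equal(nrow(back), nrow(r$spectra))
  expect_equal(back$ms_level, r$spectra$ms_level)
  expect_equal(back$rt_min, r$spectra$rt_min, tolerance = 1e-6)
  expect_equal(back$precursor_mz, r$spectra$precursor_mz, tolerance = 1e-6)
  expect_equal(back$ce_ev, r$spectra$ce_ev)
  for (i in seq_len(nrow(back)))
    expect_equal(back$peaks[[i]][, "mz"], r$spectra$peaks[[i]][, "mz"],
                 tolerance = 1e-6)
})

test_that("the manifest fully reconstructs the ground truth", {
  r <- generateRun(generatorSpec(n_compounds = 5, n_isf = 2), seed = 17,
                   outdir = withr::local_tempdir())
  truth <- readManifest(r$manifest)
  expect_equal(truth@seed, 17L)
  expect_equal(truth@compounds$precursor_mz, r$truth@compounds$precursor_mz)
  expect_equal(truth@fragments$mu_ev, r$truth@fragments$mu_ev)
  expect_equal(truth@features$feature_id, r$truth@features$feature_id)
})

test_that("a perfect noiseless run scores perfectly", {
  r <- generateRun(generatorSpec(n_compounds = 12, n_isf = 6,
                                 noise = NULL), seed = 23,
                   outdir = withr::local_tempdir())
  res <- suppressMessages(buildMRM(r$feature_table, r$mzml, runConfig()))
  sc <- scoreAgainstTruth(res, r$truth)
  expect_equal(sc$isf_recall, 1)
  expect_equal(sc$isf_precision, 1)
  expect_equal(sc$precursor_retention, 1)
  expect_equal(sc$quantifier_identity_rate, 1)
  expect_equal(sc$fragment_match_rate, 1)
  expect_equal(sc$pct_within_10ev, 100)
})

test_that("benchmark arithmetic matches hand-computed expectations", {
  rows <- makeTransitionRows(10)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.csv"); writeTransitionCSV(rows, p1)
  # identity: all deltas zero
  bm <- benchTransitions(p1, p1)
  expect_true(bm$ok)
  expect_equal(bm$median_delta_ce, 0)
  expect_equal(bm$pct_within_5ev, 100)
  expect_equal(bm$quantifier_overlap, 1)
  # constant CE offset of -6 eV
  shifted <- rows; shifted$ce_ev <- shifted$ce_ev - 6
  p2 <- file.path(d, "b.csv"); writeTransitionCSV(shifted, p2)
  bm <- benchTransitions(p2, p1)
  expect_equal(bm$median_delta_ce, -6)
  expect_equal(bm$pct_within_5ev, 0)
  expect_equal(bm$pct_within_10ev, 100)
  # fragments 0.7 Da off never match
  off <- rows; off$fragment_mz <- off$fragment_mz + 0.7
  p3 <- file.path(d, "c.csv"); writeTransitionCSV(off, p3)
  bm <- benchTransitions(p3, p1)
  expect_equal(bm$fragment_match_rate, 0)
  expect_equal(bm$quantifier_overlap, 0)
  # |delta CE| = 4 counts as within +/-5
  four <- rows; four$ce_ev <- four$ce_ev + 4
  p4 <- file.path(d, "d.csv"); writeTransitionCSV(four, p4)
  bm <- benchTransitions(p4, p1)
  expect_equal(bm$median_abs_delta_ce, 4)
  expect_equal(bm$pct_within_5ev, 100)
  # disjoint tables: no overlap, flagged not ok
  far <- rows; far$precursor_mz <- far$precursor_mz + 100
  p5 <- file.path(d, "e.csv"); writeTransitionCSV(far, p5)
  expect_false(benchTransitions(p5, p1)$ok)
})
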