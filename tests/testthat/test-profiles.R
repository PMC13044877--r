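precursorRow <- function(mz = 400.2, rt = 6.0)
  makeFeatures(mz, rt, 1e5)[1, , drop = FALSE]

test_that("spectrum sets keep one spectrum per energy, highest TIC wins", {
  p <- precursorRow()
  sp <- makeSpectra(rep(2L, 5), rt = rep(6.0, 5),
                    peaks = list(pk(100, 10), pk(100, 10), pk(100, 50),
                                 pk(100, 10), pk(100, 10)),
                    precursor_mz = 400.2, ce = c(0, 10, 20, 20, 40))
  out <- buildSpectrumSets(p, sp, trackingConfig())
  set <- out$sets[[p$feature_id]]
  expect_named(set$spectra, c("0", "10", "20", "40"))
  expect_equal(set$spectra[["20"]]$tic, 50)   # higher-TIC duplicate kept
})

test_that("precursors without MS/MS are dropped and counted", {
  p <- rbind(precursorRow(400.2), precursorRow(500.9))
  p$feature_id <- c("A", "B")
  sp <- makeSpectra(2L, rt = 6.0, peaks = list(pk(100, 10)),
                    precursor_mz = 400.2, ce = 20)
  expect_message(out <- buildSpectrumSets(p, sp, trackingConfig()),
                 "no MS/MS coverage")
  expect_named(out$sets, "A")
  expect_equal(out$n_uncovered, 1L)
})

test_that("fragments within 0.5 Da group across energies; beyond they split", {
  p <- precursorRow()
  sp <- makeSpectra(rep(2L, 2), rt = rep(6, 2),
                    peaks = list(pk(c(150.10, 150.80), c(100, 40)),
                                 pk(150.45, 90)),
                    precursor_mz = 400.2, ce = c(10, 20))
  set <- buildSpectrumSets(p, sp, trackingConfig())$sets[[1]]
  prof <- trackFragments(set, trackingConfig())
  # 150.10 (10 eV) and 150.45 (20 eV) merge; 150.80 stays separate
  expect_equal(nrow(prof), 2L)
  merged <- prof[prof$n_energies == 2L, ]
  expect_equal(nrow(merged), 1L)
  expect_true(abs(merged$group_mz - 150.10) < 0.5)
  expect_false(merged$eligible_for_spline)
  single <- prof[prof$n_energies == 1L, ]
  expect_equal(single$group_mz, 150.80)
  expect_false(single$eligible_for_spline)
})

test_that("at most ten fragment peaks contribute per energy", {
  p <- precursorRow()
  many <- pk(seq(50, 190, by = 10) + 0.123, seq(15, 1))[1:15, ]
  sp <- makeSpectra(2L, rt = 6, peaks = list(many),
                    precursor_mz = 400.2, ce = 20)
  set <- buildSpectrumSets(p, sp, trackingConfig())$sets[[1]]
  prof <- trackFragments(set, trackingConfig())
  expect_equal(nrow(prof), 10L)
  # the ten most intense peaks are the ones kept
  expect_true(all(vapply(prof$intensity, max, numeric(1)) >= 6))
})

test_that("peaks near the precursor m/z never become profiles", {
  p <- precursorRow(400.2)
  sp <- makeSpectra(2L, rt = 6,
                    peaks = list(pk(c(398.9, 398.2, 200.1), c(500, 300, 50))),
                    precursor_mz = 400.2, ce = 20)
  set <- buildSpectrumSets(p, sp, trackingConfig())$sets[[1]]
  prof <- trackFragments(set, trackingConfig())
  # 398.9 is within 2.0 Da of the precursor and excluded; 398.2 survives
  expect_setequal(round(prof$group_mz, 1), c(398.2, 200.1))
  expect_true(all(abs(prof$group_mz - 400.2) >= 2.0))
})

test_that("grouping is invariant to spectrum peak order", {
  p <- precursorRow()
  peaks <- pk(c(120.1, 120.4, 250.2, 251.0), c(80, 60, 100, 20))
  scaled <- peaks; scaled[, 2] <- scaled[, 2] * 1.1
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3))) {
    sp <- makeSpectra(rep(2L, 2), rt = rep(6, 2),
                      peaks = list(peaks[perm, ], scaled[perm, ]),
                      precursor_mz = 400.2, ce = c(10, 20))
    set <- buildSpectrumSets(p, sp, trackingConfig())$sets[[1]]
    prof <- trackFragments(set, trackingConfig())
    if (perm[1] == 1L) base_mz <- sort(prof$group_mz)
    expect_equal(sort(prof$group_mz), base_mz, tolerance = 1e-6)
  }
})

test_that("irregularity flags trough-then-rebound profiles only", {
  smooth <- flagIrregular(makeProfile(c(0, 10, 20, 40), c(0, 100, 60, 20)))
  expect_false(smooth$irregular)
  rebound <- flagIrregular(makeProfile(c(0, 10, 20, 40), c(100, 2, 90, 5)))
  expect_true(rebound$irregular)
  rising <- flagIrregular(makeProfile(c(0, 10, 20, 40), c(1, 50, 100, 40)))
  expect_false(rising$irregular)   # a leading low value is not a trough
  two <- flagIrregular(makeProfile(c(0, 10), c(100, 2)))
  expect_false(two$irregular)      # low-coverage profiles are not judged
})

test_that("planted response curves are recovered exactly without noise", {
  run <- generateRun(generatorSpec(n_compounds = 10, n_isf = 0,
                                   noise = NULL), seed = 12)
  feats <- readFeatureTable(run$feature_table)
  mono <- run$truth@features
  mono <- mono[mono$kind == "monoisotopic", ]
  ms2 <- readMzML(run$mzml)
  sets <- suppressMessages(
    buildSpectrumSets(feats[feats$feature_id %in% mono$feature_id, ],
                      ms2, trackingConfig()))
  for (id in names(sets$sets)) {
    set <- sets$sets[[id]]
    prof <- trackFragments(set, trackingConfig())
    cid <- mono$compound_id[mono$feature_id == id]
    fr <- run$truth@fragments[run$truth@fragments$compound_id == cid, ]
    for (j in seq_len(nrow(fr))) {
      hits <- which(abs(prof$group_mz - fr$fragment_mz[j]) <= 0.5)
      expect_length(hits, 1L)       # exactly one recovered group
      obs <- prof$intensity[[hits]]
      ces <- prof$ce_ev[[hits]]
      planted <- fr$amplitude[j] *
        exp(-(ces - fr$mu_ev[j])^2 / (2 * fr$sigma_ev[j]^2))
      expect_equal(obs, planted, tolerance = 1e-4)
    }
  }
})
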