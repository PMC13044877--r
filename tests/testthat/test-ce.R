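# independent brute-force argmax over the fitted curve (0.01 eV grid)
gridArgmax <- function(ce, int, degree = 2, step = 0.01) {
  f <- mrmforge:::.interpSplineFun(ce, int, min(degree, length(ce) - 1L))
  g <- seq(min(ce), max(ce), by = step)
  g[which.max(f(g))]
}

test_that("monotone-decreasing profiles clamp to the 5 eV floor", {
  pr <- makeProfile(c(0, 10, 20, 40), c(100, 50, 20, 5))
  out <- fitCESpline(pr, splineConfig())
  expect_equal(out$ce_opt_ev, 5)
  expect_equal(out$method, "clamped_floor")
})

test_that("the spline interpolates exactly and the argmax matches a dense grid", {
  pr <- makeProfile(c(0, 10, 20, 40), c(0, 100, 80, 20))
  out <- fitCESpline(pr, splineConfig())
  # frozen from the 0.01 eV brute-force oracle over the quadratic
  # interpolant (independently reproduced by scipy's k=2 FITPACK spline)
  expect_equal(out$ce_opt_ev, 12.25, tolerance = 0.05)
  expect_equal(out$predicted_max_intensity, 103.4964, tolerance = 1e-3)
  expect_equal(out$method, "spline_argmax")
  # s = 0: the curve passes through every observed point
  f <- mrmforge:::.interpSplineFun(c(0, 10, 20, 40), c(0, 100, 80, 20), 2)
  expect_equal(f(c(0, 10, 20, 40)), c(0, 100, 80, 20), tolerance = 1e-9)
})

test_that("interpolation residuals vanish for random profiles, both degrees", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(3:4, 1)
    ce <- sort(sample(c(0, 10, 20, 40), n))
    int <- runif(n, 1, 1000)
    for (deg in 2:3) {
      f <- mrmforge:::.interpSplineFun(ce, int, min(deg, n - 1L))
      expect_equal(f(ce), int, tolerance = 1e-6 * max(int))
    }
  }
})

test_that("spline argmax agrees with the brute-force oracle", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(3:4, 1)
    ce <- sort(sample(c(0, 10, 20, 40), n))
    int <- runif(n, 1, 1000)
    pr <- makeProfile(ce, int)
    for (deg in 2:3) {
      out <- fitCESpline(pr, splineConfig(spline_degree = deg,
                                          ce_floor_ev = 0))
      expect_lt(abs(out$ce_opt_ev - gridArgmax(ce, int, deg)), 0.1)
    }
  }
})

test_that("the quadratic interpolant matches scipy's FITPACK spline", {
  set.seed(7)
  profiles <- lapply(1:12, function(i) {
    n <- if (i %% 2) 3L else 4L
    list(ce = sort(sample(c(0, 10, 20, 40), n)), int = runif(n, 1, 1000))
  })
  dir <- withr::local_tempdir()
  inp <- file.path(dir, "profiles.csv")
  writeLines(vapply(profiles, function(p)
    paste(c(length(p$ce), p$ce, p$int), collapse = ","), character(1)), inp)
  script <- file.path(dir, "oracle.py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "from scipy.interpolate import InterpolatedUnivariateSpline",
    "for line in open(sys.argv[1]):",
    "    v = [float(x) for x in line.strip().split(',')]",
    "    n = int(v[0]); x = np.array(v[1:1+n]); y = np.array(v[1+n:1+2*n])",
    "    s = InterpolatedUnivariateSpline(x, y, k=2)",
    "    g = np.arange(x[0], x[-1] + 1e-9, 0.01)",
    "    print(g[int(np.argmax(s(g)))], float(np.max(s(g))))"), script)
  res <- system2("python", c(script, inp), stdout = TRUE)
  expect_length(res, length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    ours <- fitCESpline(makeProfile(p$ce, p$int),
                        splineConfig(ce_floor_ev = min(p$ce)))
    ref <- as.numeric(strsplit(res[i], " ")[[1]])
    expect_lt(abs(ours$ce_opt_ev - ref[1]), 0.02)
    expect_equal(ours$predicted_max_intensity, ref[2], tolerance = 1e-3)
  }
})

test_that("a planted broad unimodal response peaking at 22 eV is recovered", {
  resp <- function(ce, mu) 1000 * exp(-(ce - mu)^2 / (2 * 12^2))
  out <- fitCESpline(makeProfile(c(0, 10, 20, 40), resp(c(0, 10, 20, 40), 22)))
  # brute-force 0.01 eV grid over the quadratic interpolant puts the
  # maximum at 23.63 eV for this sampling
  expect_equal(out$ce_opt_ev, 23.63, tolerance = 1e-3)
  expect_lt(abs(out$ce_opt_ev - 22), 2)
})

test_that("low-coverage fallback uses the observed optimum with flooring", {
  one40 <- fallbackCE(makeProfile(40, 500))
  expect_equal(one40$ce_opt_ev, 40)
  expect_equal(one40$method, "observed_fallback")
  two <- fallbackCE(makeProfile(c(0, 10), c(80, 100)))
  expect_equal(two$ce_opt_ev, 10)
  one0 <- fallbackCE(makeProfile(0, 500))
  expect_equal(one0$ce_opt_ev, 5)       # floor composition
  expect_error(fallbackCE(makeProfile(numeric(0), numeric(0))), "empty")
})

test_that("all emitted collision energies lie in [5, 40] eV", {
  set.seed(303)
  for (i in 1:50) {
    n <- sample(1:4, 1)
    ce <- sort(sample(c(0, 10, 20, 40), n))
    pr <- makeProfile(ce, runif(n, 1, 100))
    out <- predictCE(pr, splineConfig())
    expect_gte(out$ce_opt_ev, 5)
    expect_lte(out$ce_opt_ev, 40)
  }
})
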