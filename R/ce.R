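# Interpolating B-spline through (x, y): boundary knots repeated
# degree+1 times, interior knots at midpoints of the interior abscissae
# (the FITPACK interpolation rule for even degree).  Returns an evaluator
# restricted to [min(x), max(x)].
.interpSplineFun <- function(x, y, degree) {
  n <- length(x)
  stopifnot(n >= degree + 1L, !anyDuplicated(x))
  ord <- order(x); x <- x[ord]; y <- y[ord]
  n_inner <- n - degree - 1L
  inner <- if (n_inner > 0L) {
    if (degree %% 2L == 0L) {
      # even degree: midpoints between successive interior points
      (x[seq(2L, 1L + n_inner)] + x[seq(3L, 2L + n_inner)]) / 2
    } else {
      # odd degree: interior data points themselves
      x[seq(2L + (degree - 1L) / 2L, length.out = n_inner)]
    }
  } else numeric(0)
  knots <- c(rep(x[1L], degree + 1L), inner, rep(x[n], degree + 1L))
  B <- splines::splineDesign(knots, x, ord = degree + 1L)
  coef <- solve(B, y)
  lo <- x[1L]; hi <- x[n]
  function(t) {
    t <- pmin(pmax(t, lo), hi)
    drop(splines::splineDesign(knots, t, ord = degree + 1L) %*% coef)
  }
}

#' Fit a collision-energy spline and predict the optimal energy
#'
#' Fits an interpolating spline (default degree 2, smoothing 0 — the curve
#' passes exactly through every observed point) to the (collision energy,
#' intensity) observations of a fragment profile and locates the intensity
#' maximum by a dense grid search (`cfg$grid_step_ev`) refined by local
#' maximization.  The search is restricted to the sampled energy span;
#' extrapolated spline excursions are never trusted.  An argmax below
#' `cfg$ce_floor_ev` (5 eV, the operational floor of standard
#' triple-quadrupole instruments) is clamped to the floor.  Requires at
#' least three observed energies; use [fallbackCE()] otherwise.  With only
#' three points a cubic request falls back to the quadratic interpolant.
#'
#' @param profile one row of the [trackFragments()] table (`n_energies >= 3`).
#' @param cfg a [splineConfig()].
#' @return one-row data.frame: `ce_opt_ev`, `predicted_max_intensity`,
#'   `method` (`spline_argmax` or `clamped_floor`), `fitted` (TRUE),
#'   `n_energies`.
#' @export
#' @examples
#' pr <- data.frame(group_mz = 150, n_energies = 4L,
#'                  eligible_for_spline = TRUE, irregular = FALSE)
#' pr$ce_ev <- list(c(0, 10, 20, 40)); pr$intensity <- list(c(0, 100, 80, 20))
#' fitCESpline(pr)
fitCESpline <- function(profile, cfg = splineConfig()) {
  x <- profile$ce_ev[[1L]]
  y <- profile$intensity[[1L]]
  if (length(x) < 3L)
    stop("spline fitting requires observations at >= 3 collision energies")
  deg <- min(cfg$spline_degree, length(x) - 1L)
  f <- .interpSplineFun(x, y, deg)
  grid <- seq(min(x), max(x), by = cfg$grid_step_ev)
  if (grid[length(grid)] < max(x)) grid <- c(grid, max(x))
  v <- f(grid)
  k <- which.max(v)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  opt <- if (hi > lo) {
    o <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)
    if (o$objective >= v[k]) o$maximum else grid[k]
  } else grid[k]
  ce <- opt
  if (!is.null(cfg$adjust)) ce <- cfg$adjust(ce, profile)
  method <- "spline_argmax"
  if (ce < cfg$ce_floor_ev) { ce <- cfg$ce_floor_ev; method <- "clamped_floor" }
  if (ce > cfg$ce_ceiling_ev) ce <- cfg$ce_ceiling_ev
  data.frame(ce_opt_ev = ce, predicted_max_intensity = max(v, f(ce)),
             method = method, fitted = TRUE,
             n_energies = length(x), stringsAsFactors = FALSE)
}

#' Low-coverage collision-energy fallback
#'
#' Fragments observed at fewer than three energies cannot support spline
#' fitting but still yield a transition: the optimal energy is the observed
#' energy with maximal intensity, clamped to the instrument floor.
#'
#' @param profile one row of the [trackFragments()] table
#'   (`n_energies < 3`).
#' @param cfg a [splineConfig()].
#' @return one-row data.frame as in [fitCESpline()], `method =
#'   "observed_fallback"`, `fitted = FALSE`.
#' @export
fallbackCE <- function(profile, cfg = splineConfig()) {
  x <- profile$ce_ev[[1L]]
  y <- profile$intensity[[1L]]
  if (!length(x)) stop("cannot predict a collision energy from an empty profile")
  ce <- x[which.max(y)]
  ce <- min(max(ce, cfg$ce_floor_ev), cfg$ce_ceiling_ev)
  data.frame(ce_opt_ev = ce, predicted_max_intensity = max(y),
             method = "observed_fallback", fitted = FALSE,
             n_energies = length(x), stringsAsFactors = FALSE)
}

#' Predict optimal collision energies for a profile table
#'
#' Dispatches each fragment profile to [fitCESpline()] (three or more
#' energies) or [fallbackCE()] and binds the predictions onto the profile
#' table.
#'
#' @param profiles [trackFragments()] output.
#' @param cfg a [splineConfig()].
#' @return the profile table with prediction columns appended.
#' @export
predictCE <- function(profiles, cfg = splineConfig()) {
  if (nrow(profiles) == 0L) {
    profiles$ce_opt_ev <- numeric(0)
    profiles$predicted_max_intensity <- numeric(0)
    profiles$method <- character(0)
    profiles$fitted <- logical(0)
    return(profiles)
  }
  pred <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(k) {
    p <- profiles[k, , drop = FALSE]
    if (p$n_energies >= 3L) fitCESpline(p, cfg) else fallbackCE(p, cfg)
  }))
  profiles$ce_opt_ev <- pred$ce_opt_ev
  profiles$predicted_max_intensity <- pred$predicted_max_intensity
  profiles$method <- pred$method
  profiles$fitted <- pred$fitted
  profiles
}
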