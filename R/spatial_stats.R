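#' Time-ensemble mean squared displacement of cell tracks
#'
#' For each lag \eqn{\tau} (a multiple of the common sampling interval, up to
#' `max_lag`), the MSD is the mean of the squared planar displacement over
#' all tracks and all valid start times within each track (time-ensemble
#' averaging). For diffusive motion in 2D, MSD(\eqn{\tau}) = 4 D \eqn{\tau}.
#'
#' @param tracks A data frame with columns `track_id`, `time_min`, `x_um`,
#'   `y_um`; within each track the times must be strictly increasing with a
#'   constant spacing shared by all tracks.
#' @param max_lag Largest lag (minutes) to evaluate; defaults to the longest
#'   track span.
#' @return A tibble of class `msd_curve` with columns `lag_min`, `msd_um2`,
#'   `n_pairs` (displacements averaged per lag), including the `lag = 0` row.
#' @examples
#' tr <- gen_brownian_tracks(D = 5, n_tracks = 50, dt_min = 10,
#'                           duration_min = 200, seed = 1)
#' msd <- msd_time_ensemble(tr)
#' fit_diffusion(msd)
#' @export
msd_time_ensemble <- function(tracks, max_lag = NULL) {
  tracks <- tibble::as_tibble(tracks)
  need <- c("track_id", "time_min", "x_um", "y_um")
  if (!all(need %in% names(tracks)))
    stop("`tracks` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(tracks) == 0) stop("empty track set", call. = FALSE)
  by_track <- split(tracks[c("time_min", "x_um", "y_um")], tracks$track_id)
  by_track <- Filter(function(tr) nrow(tr) >= 2, by_track)
  if (length(by_track) == 0)
    stop("need at least one track with two or more points", call. = FALSE)
  dts <- unlist(lapply(by_track, function(tr) diff(sort(tr$time_min))))
  dt <- dts[1]
  if (any(dts <= 0) || any(abs(dts - dt) > 1e-8 * max(dt, 1)))
    stop("tracks must share a constant, positive sampling interval",
         call. = FALSE)
  max_pts <- max(vapply(by_track, nrow, 1L))
  if (is.null(max_lag)) max_lag <- (max_pts - 1) * dt
  n_lags <- min(max_pts - 1L, floor(max_lag / dt + 1e-9))
  if (n_lags < 1) stop("`max_lag` smaller than the sampling interval",
                       call. = FALSE)
  sums <- counts <- numeric(n_lags)
  for (tr in by_track) {
    o <- order(tr$time_min)
    x <- tr$x_um[o]
    y <- tr$y_um[o]
    np <- length(x)
    for (m in seq_len(min(n_lags, np - 1L))) {
      i <- seq_len(np - m)
      d2 <- (x[i + m] - x[i])^2 + (y[i + m] - y[i])^2
      sums[m] <- sums[m] + sum(d2)
      counts[m] <- counts[m] + length(d2)
    }
  }
  keep <- counts > 0
  out <- tibble::tibble(
    lag_min = c(0, dt * which(keep)),
    msd_um2 = c(0, sums[keep] / counts[keep]),
    n_pairs = c(NA_real_, counts[keep])
  )
  structure(out, class = c("msd_curve", class(out)),
            sampling_interval = dt)
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Fits a straight line through the origin to MSD(\eqn{\tau}) by unweighted
#' least squares over the first quarter of the available positive lags (at
#' least two), where the linear diffusive regime is cleanest, and returns
#' \eqn{D =} slope / 4 (two dimensions).
#'
#' @param msd An [msd_time_ensemble()] result (or any tibble with `lag_min`,
#'   `msd_um2`).
#' @return A `diffusion_fit` object with elements `D_um2_per_min`, `slope`,
#'   `residual_rms`, `n_lags_used`; see [tidy()]/[glance()].
#' @export
fit_diffusion <- function(msd) {
  pos <- msd[msd$lag_min > 0, , drop = FALSE]
  if (nrow(pos) < 2) stop("need at least two positive lags", call. = FALSE)
  n_use <- max(2L, ceiling(nrow(pos) / 4))
  use <- pos[seq_len(n_use), ]
  slope <- sum(use$msd_um2 * use$lag_min) / sum(use$lag_min^2)
  resid <- use$msd_um2 - slope * use$lag_min
  structure(
    list(D_um2_per_min = max(0, slope / 4), slope = slope,
         residual_rms = sqrt(mean(resid^2)), n_lags_used = n_use,
         lags_used = use$lag_min),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um^2/min (slope %.4g over %d lags, rms %.3g)\n",
              x$D_um2_per_min, x$slope, x$n_lags_used, x$residual_rms))
  invisible(x)
}

resolve_window <- function(points, window) {
  if (is.null(window)) window <- attr(points, "window")
  if (is.null(window))
    stop("supply `window = c(x0, y0, x1, y1)` (um)", call. = FALSE)
  window <- as.numeric(unlist(window))
  if (length(window) != 4 || window[3] <= window[1] || window[4] <= window[2])
    stop("`window` must be c(x0, y0, x1, y1) with positive extent",
         call. = FALSE)
  window
}

# Run `expr` under a fixed private RNG state, restoring the caller's stream.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pair-correlation function with a Monte-Carlo CSR reference
#'
#' Counts inter-point distances (non-periodic) in annuli of width
#' `bin_width` and divides by the expected count for a pattern of the same
#' size under complete spatial randomness (CSR) in the same window. The CSR
#' reference accounts for the window geometry and is estimated once by
#' Monte-Carlo sampling of uniform point pairs under a fixed private seed, so
#' results are deterministic and the caller's RNG stream is untouched.
#' `g(r) = 1` under CSR; `g(r) < 1` below the exclusion scale of a hardcore
#' (volume-excluding) pattern.
#'
#' @param points Data frame with columns `x_um`, `y_um` (n >= 2).
#' @param window Rectangle `c(x0, y0, x1, y1)` in um (taken from the
#'   `"window"` attribute of `points` when `NULL`).
#' @param bin_width Annulus width in um (default 4, roughly a tenth of a cell
#'   diameter).
#' @param r_max Largest distance evaluated; default half the shorter window
#'   side; must not exceed the window diagonal.
#' @param n_ref_pairs Monte-Carlo sample size for the CSR reference.
#' @return A tibble of class `pcf_result` with columns `r` (bin centre, um),
#'   `g`, `observed`, `expected`.
#' @export
pair_correlation <- function(points, window = NULL, bin_width = 4,
                             r_max = NULL, n_ref_pairs = 5e5) {
  window <- resolve_window(points, window)
  x <- points$x_um
  y <- points$y_um
  n <- length(x)
  if (n < 2) stop("need at least two points", call. = FALSE)
  wx <- window[3] - window[1]
  wy <- window[4] - window[2]
  if (is.null(r_max)) r_max <- min(wx, wy) / 2
  if (r_max > sqrt(wx^2 + wy^2))
    stop("`r_max` exceeds the window diagonal", call. = FALSE)
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  d <- stats::dist(cbind(x, y))
  obs <- graphics::hist(d[d <= r_max], breaks = breaks, plot = FALSE)$counts
  p_bin <- with_private_seed(987654L, {
    rx <- stats::runif(n_ref_pairs, window[1], window[3]) -
      stats::runif(n_ref_pairs, window[1], window[3])
    ry <- stats::runif(n_ref_pairs, window[2], window[4]) -
      stats::runif(n_ref_pairs, window[2], window[4])
    rd <- sqrt(rx^2 + ry^2)
    graphics::hist(rd[rd <= r_max], breaks = breaks,
                   plot = FALSE)$counts / n_ref_pairs
  })
  expected <- choose(n, 2) * p_bin
  out <- tibble::tibble(
    r = (breaks[-length(breaks)] + breaks[-1]) / 2,
    g = ifelse(expected > 0, obs / expected, NA_real_),
    observed = obs,
    expected = expected
  )
  structure(out, class = c("pcf_result", class(out)), window = window,
            n_points = n)
}

#' Berman Z1 test of complete spatial randomness
#'
#' Compares the sum of a spatial covariate evaluated at the points with its
#' expectation under CSR: \eqn{Z_1 = (S - n\mu_W) / \sqrt{n\sigma^2_W}},
#' where \eqn{\mu_W} and \eqn{\sigma^2_W} are the covariate's mean and
#' variance over the window (computed on a fine quadrature grid), and the
#' two-sided p-value comes from the standard normal. The default covariate is
#' the dorsoventral (x) coordinate.
#'
#' @param points Data frame with columns `x_um`, `y_um`.
#' @param window Rectangle `c(x0, y0, x1, y1)`; see [pair_correlation()].
#' @param covariate A function of `(x, y)` returning a numeric vector;
#'   default `function(x, y) x`.
#' @param grid_n Quadrature grid resolution per axis.
#' @return An `htest`-style list (`statistic`, `p.value`, `method`, `n`).
#' @export
berman_z1 <- function(points, window = NULL, covariate = NULL, grid_n = 201) {
  window <- resolve_window(points, window)
  if (is.null(covariate)) covariate <- function(x, y) x
  n <- nrow(points)
  if (n < 1) stop("need at least one point", call. = FALSE)
  gx <- seq(window[1], window[3], length.out = grid_n)
  gy <- seq(window[2], window[4], length.out = grid_n)
  zg <- outer(gx, gy, covariate)
  mu <- mean(zg)
  sig2 <- mean((zg - mu)^2)
  if (sig2 <= .Machine$double.eps * max(1, mu^2))
    stop("degenerate covariate: constant over the window", call. = FALSE)
  s <- sum(covariate(points$x_um, points$y_um))
  z1 <- (s - n * mu) / sqrt(n * sig2)
  structure(
    list(statistic = c(Z1 = z1),
         p.value = 2 * stats::pnorm(-abs(z1)),
         method = "Berman Z1 test of CSR",
         data.name = "point pattern", n = n),
    class = "htest"
  )
}

#' Kolmogorov-Smirnov test of orientation uniformity
#'
#' Tests a set of orientations (e.g. Feret angles of migrating cells) against
#' the uniform distribution on [0, 180) degrees; undirected migration gives
#' uniform orientations.
#'
#' @param angles Numeric vector of orientations in degrees, `[0, 180)`;
#'   at least 5 values.
#' @return The `htest` from [stats::ks.test()].
#' @export
angle_uniformity <- function(angles) {
  angles <- as.numeric(angles)
  if (length(angles) < 5) stop("need at least 5 angles", call. = FALSE)
  if (any(angles < 0 | angles >= 180))
    stop("orientations must lie in [0, 180)", call. = FALSE)
  suppressWarnings(stats::ks.test(angles, "punif", 0, 180))
}

#' Cell-cycle time from M-phase length and mitotic fraction
#'
#' For a time-lapse in which mitoses of duration `T_m` are visible and a
#' fraction `P_mc` of cells is mitotic at any instant, the cell-cycle time is
#' `T_c = T_m / P_mc`.
#'
#' @param T_m_min M-phase duration in minutes (> 0).
#' @param P_mc Proportion of mitotic cells, in (0, 1].
#' @return A one-row tibble of class `cell_cycle_estimate` with columns
#'   `T_m_min`, `P_mc`, `T_c_min`.
#' @examples
#' cell_cycle_estimate(30, 0.05) # T_c = 600 min
#' @export
cell_cycle_estimate <- function(T_m_min, P_mc) {
  if (T_m_min <= 0) stop("`T_m_min` must be positive", call. = FALSE)
  if (P_mc <= 0 || P_mc > 1)
    stop("`P_mc` must lie in (0, 1]; a zero mitotic fraction leaves the ",
         "cell-cycle time undefined", call. = FALSE)
  out <- tibble::tibble(T_m_min = T_m_min, P_mc = P_mc,
                        T_c_min = T_m_min / P_mc)
  structure(out, class = c("cell_cycle_estimate", class(out)))
}
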