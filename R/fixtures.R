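#' Synthetic cell tracks with known ground truth
#'
#' `gen_brownian_tracks()` draws independent 2D Gaussian increments with
#' per-axis variance `2 * D * dt` (so the true MSD is exactly `4 D tau`);
#' `gen_ballistic_tracks()` produces straight-line motion with speed
#' `(vx, vy)` um/min (true MSD `(vx^2 + vy^2) tau^2`). Both are oracles for
#' the MSD and diffusion estimators.
#'
#' @param D Diffusion coefficient, um^2/min (>= 0).
#' @param vx,vy Velocity components, um/min.
#' @param n_tracks Number of tracks.
#' @param dt_min Sampling interval, minutes.
#' @param duration_min Track length, minutes.
#' @param seed Optional integer seed.
#' @return A tibble with columns `track_id`, `time_min`, `x_um`, `y_um`.
#' @export
gen_brownian_tracks <- function(D, n_tracks, dt_min, duration_min,
                                seed = NULL) {
  if (D < 0) stop("`D` must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  np <- floor(duration_min / dt_min) + 1L
  sd_inc <- sqrt(2 * D * dt_min)
  purrr::map_dfr(seq_len(n_tracks), function(id) {
    tibble::tibble(
      track_id = id,
      time_min = (seq_len(np) - 1) * dt_min,
      x_um = cumsum(c(0, stats::rnorm(np - 1L, 0, sd_inc))),
      y_um = cumsum(c(0, stats::rnorm(np - 1L, 0, sd_inc)))
    )
  })
}

#' @rdname gen_brownian_tracks
#' @export
gen_ballistic_tracks <- function(vx, vy, n_tracks, dt_min, duration_min,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  np <- floor(duration_min / dt_min) + 1L
  purrr::map_dfr(seq_len(n_tracks), function(id) {
    t <- (seq_len(np) - 1) * dt_min
    tibble::tibble(track_id = id, time_min = t, x_um = vx * t, y_um = vy * t)
  })
}

#' Synthetic planar point patterns
#'
#' `gen_csr_pattern()` draws `n` i.i.d. uniform points in the window
#' (complete spatial randomness); `gen_hardcore_pattern()` adds a minimum
#' pairwise separation `r_min` by dart throwing (points violating the
#' separation are rejected; generation fails after `max_attempts`), emulating
#' volume exclusion at the scale of a single cell.
#'
#' @param n Number of points (>= 0).
#' @param window Rectangle `c(x0, y0, x1, y1)` in um (default the 256 x 256
#'   um analysis window used for the imaging data).
#' @param r_min Hardcore radius, um.
#' @param max_attempts Dart-throwing budget.
#' @param seed Optional integer seed.
#' @return A tibble with columns `x_um`, `y_um` and a `"window"` attribute.
#' @export
gen_csr_pattern <- function(n, window = c(0, 0, 256, 256), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- tibble::tibble(
    x_um = stats::runif(n, window[1], window[3]),
    y_um = stats::runif(n, window[2], window[4])
  )
  attr(out, "window") <- as.numeric(window)
  out
}

#' @rdname gen_csr_pattern
#' @export
gen_hardcore_pattern <- function(n, r_min, window = c(0, 0, 256, 256),
                                 max_attempts = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xs <- ys <- numeric(0)
  attempts <- 0
  while (length(xs) < n) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("hardcore packing infeasible within the attempt budget",
           call. = FALSE)
    px <- stats::runif(1, window[1], window[3])
    py <- stats::runif(1, window[2], window[4])
    if (length(xs) == 0 || all((xs - px)^2 + (ys - py)^2 >= r_min^2)) {
      xs <- c(xs, px)
      ys <- c(ys, py)
    }
  }
  out <- tibble::tibble(x_um = xs, y_um = ys)
  attr(out, "window") <- as.numeric(window)
  out
}

#' Fully occupied grid with perfect dorsoventral stripes
#'
#' Builds a fully occupied `domain_state` whose two colour labels alternate
#' in axial blocks (`n_stripes` blocks of length `ceiling(L_y / n_stripes)`,
#' the last block truncated when `n_stripes` does not divide `L_y`). A
#' known-periodicity oracle for [stripe_intensity()]: the clonal signal is a
#' square wave.
#'
#' @param n_sites_dv,n_sites_axial Lattice extent.
#' @param n_stripes Number of alternating colour blocks (>= 1).
#' @return A `domain_state` with every site occupied.
#' @export
gen_striped_grid <- function(n_sites_dv, n_sites_axial, n_stripes) {
  if (n_stripes < 1 || n_stripes > n_sites_axial)
    stop("`n_stripes` must lie in 1..n_sites_axial", call. = FALSE)
  block <- ceiling(n_sites_axial / n_stripes)
  pos <- expand.grid(site_dv = seq_len(n_sites_dv),
                     site_ax = seq_len(n_sites_axial))
  stripe <- (pos$site_ax - 1L) %/% block
  agents <- tibble::tibble(
    agent_id = seq_len(nrow(pos)), lineage = seq_len(nrow(pos)),
    colour = ifelse(stripe %% 2L == 0L, 1L, -1L),
    rare_mark = 0L,
    site_dv = as.integer(pos$site_dv), site_ax = as.integer(pos$site_ax)
  )
  domain_state(n_sites_dv, n_sites_axial, agents)
}

#' Synthetic density-diffusion table with known movement rate
#'
#' Runs the periodic density sweep at a known movement rate and optionally
#' perturbs the diffusion coefficients with Gaussian noise; a round-trip
#' input for [fit_movement_rate()].
#'
#' @param true_pm The generating movement rate (> 0).
#' @param densities Agent counts.
#' @param reps Realizations per density.
#' @param noise_sd Standard deviation of additive Gaussian noise on D
#'   (um^2/min).
#' @param seed Optional integer seed (also seeds the sweep).
#' @inheritParams periodic_density_sweep
#' @return A `density_diffusion_table` tibble.
#' @export
gen_density_D_table <- function(true_pm, densities, reps = 20, noise_sd = 0,
                                n_sites = 17, lattice_spacing_um = 38,
                                seed = NULL) {
  if (true_pm <= 0) stop("`true_pm` must be positive", call. = FALSE)
  if (length(densities) == 0) stop("`densities` must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  base_seed <- sample.int(1e6, 1)
  tab <- periodic_density_sweep(
    move_rate_per_min = true_pm, densities = densities, reps = reps,
    n_sites = n_sites, lattice_spacing_um = lattice_spacing_um,
    base_seed = base_seed
  )
  if (noise_sd > 0) {
    tab$D_um2_per_min <- pmax(0, tab$D_um2_per_min +
                                stats::rnorm(nrow(tab), 0, noise_sd))
  }
  tab
}
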