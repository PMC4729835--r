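#' Emergent diffusion versus density on a periodic domain
#'
#' Measures the model's density-dependent effective diffusion coefficient.
#' For each agent count, agents are placed uniformly on a 17 x 17-site
#' (646 x 646 um) lattice with periodic boundary conditions and allowed to
#' move - but not proliferate, so the density stays constant - for 400
#' minutes; this is repeated `reps` times. Tracks are truncated at their
#' first boundary crossing (as a cell leaving the field of view would be
#' lost), pooled, and the diffusion coefficient is fitted from the
#' time-ensemble MSD. Volume exclusion makes D fall monotonically with
#' density, from the free-walk value \eqn{P_m \Delta^2 / 4} towards zero at
#' full occupancy.
#'
#' @param move_rate_per_min Movement attempt rate P_m.
#' @param densities Agent counts to test (each in 1..`n_sites`^2).
#' @param duration_min Run length per realization (default 400).
#' @param reps Realizations per density (default 100).
#' @param n_sites Periodic lattice side (default 17).
#' @param lattice_spacing_um Site spacing (default 38 um).
#' @param track_interval Track sampling interval, minutes.
#' @param base_seed Seed base; realization `r` at density index `i` uses
#'   `base_seed + 1000 * i + r`.
#' @return A tibble of class `density_diffusion_table` with columns
#'   `n_agents`, `density_cells_per_mm2`, `D_um2_per_min`, `n_reps`.
#' @export
periodic_density_sweep <- function(move_rate_per_min = 0.2,
                                   densities = c(1, 30, 60, 120, 200, 289),
                                   duration_min = 400,
                                   reps = 100,
                                   n_sites = 17,
                                   lattice_spacing_um = 38,
                                   track_interval = 20,
                                   base_seed = 1) {
  densities <- as.integer(densities)
  if (length(densities) == 0 || any(densities < 1))
    stop("`densities` must be positive agent counts", call. = FALSE)
  if (any(densities > n_sites^2))
    stop("density exceeds the number of lattice sites", call. = FALSE)
  area_mm2 <- (n_sites * lattice_spacing_um / 1000)^2
  rows <- purrr::imap(densities, function(n, i) {
    tracks <- purrr::map_dfr(seq_len(reps), function(r) {
      set.seed(base_seed + 1000 * i + r)
      sim <- periodic_run(
        n_agents = n, move_rate_per_min = move_rate_per_min,
        duration_min = duration_min, n_sites = n_sites,
        lattice_spacing_um = lattice_spacing_um,
        track_interval = track_interval
      )
      dplyr::mutate(sim$tracks, track_id = .data$track_id + r * 1e6)
    })
    d <- if (all(tapply(tracks$time_min, tracks$track_id, length) < 2)) {
      0
    } else {
      fit_diffusion(msd_time_ensemble(tracks))$D_um2_per_min
    }
    tibble::tibble(
      n_agents = n, density_cells_per_mm2 = n / area_mm2,
      D_um2_per_min = d, n_reps = reps
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("density_diffusion_table", class(out)))
}

#' Fit the movement rate to an empirical density-diffusion table
#'
#' Emulates the calibration of P_m against time-lapse measurements: for each
#' candidate movement rate, the periodic density sweep is run at the agent
#' counts matching the empirical densities, and the candidate minimizing the
#' squared-error (l2) distance between model and empirical diffusion
#' coefficients is returned (ties broken towards the smallest rate). All
#' candidates share the same stream of realization seeds (common random
#' numbers), which stabilizes the argmin against sweep sampling noise.
#'
#' @param empirical A data frame with columns `density_cells_per_mm2` and
#'   `D_um2_per_min` (e.g. a [periodic_density_sweep()] result or a CSV of
#'   microscopy measurements).
#' @param pm_grid Candidate movement rates (min^-1), ascending.
#' @param reps Realizations per density per candidate.
#' @inheritParams periodic_density_sweep
#' @return A `movement_rate_fit`: list with `P_m` (the argmin), `sse` (tibble
#'   of candidate rates and squared errors).
#' @export
fit_movement_rate <- function(empirical, pm_grid, reps = 20,
                              duration_min = 400, n_sites = 17,
                              lattice_spacing_um = 38, track_interval = 20,
                              base_seed = 1) {
  empirical <- tibble::as_tibble(empirical)
  if (nrow(empirical) == 0) stop("empirical table is empty", call. = FALSE)
  if (!all(c("density_cells_per_mm2", "D_um2_per_min") %in% names(empirical)))
    stop("`empirical` needs columns density_cells_per_mm2, D_um2_per_min",
         call. = FALSE)
  area_mm2 <- (n_sites * lattice_spacing_um / 1000)^2
  n_agents <- as.integer(round(empirical$density_cells_per_mm2 * area_mm2))
  if (any(n_agents < 1 | n_agents > n_sites^2))
    stop("empirical densities outside the representable range", call. = FALSE)
  pm_grid <- sort(as.numeric(pm_grid))
  sse <- vapply(seq_along(pm_grid), function(j) {
    tab <- periodic_density_sweep(
      move_rate_per_min = pm_grid[j], densities = n_agents,
      duration_min = duration_min, reps = reps, n_sites = n_sites,
      lattice_spacing_um = lattice_spacing_um,
      track_interval = track_interval,
      base_seed = base_seed
    )
    sum((tab$D_um2_per_min - empirical$D_um2_per_min)^2)
  }, numeric(1))
  structure(
    list(P_m = pm_grid[which.min(sse)],
         sse = tibble::tibble(P_m = pm_grid, sse = sse)),
    class = "movement_rate_fit"
  )
}

#' @export
print.movement_rate_fit <- function(x, ...) {
  cat(sprintf("<movement_rate_fit> P_m = %.4g min^-1 (best of %d candidates)\n",
              x$P_m, nrow(x$sse)))
  invisible(x)
}

#' Emergent cell-cycle time versus density
#'
#' With proliferation enabled on the periodic calibration domain, volume
#' exclusion aborts a growing fraction of division attempts as density
#' rises, lengthening the effective cell-cycle time above its unconstrained
#' minimum \eqn{1/P_p}. The effective cell-cycle time at each density is the
#' mean inter-division time per agent: observed agent-minutes divided by
#' successful divisions, over a window short enough that the density change
#' stays modest.
#'
#' @param densities Initial agent counts (each in 1..`n_sites`^2).
#' @param proliferation_rate_per_min Attempt rate P_p.
#' @param move_rate_per_min Attempt rate P_m.
#' @param window_min Observation window (default 240 min).
#' @param reps Realizations pooled per density.
#' @inheritParams periodic_density_sweep
#' @return A tibble with columns `n_agents`, `density_cells_per_mm2`,
#'   `divisions`, `agent_minutes`, `T_c_min` (`NA` and `undefined = TRUE`
#'   when no division occurred).
#' @export
emergent_cell_cycle <- function(densities,
                                proliferation_rate_per_min = log(2) / 420,
                                move_rate_per_min = 0.2,
                                window_min = 240,
                                reps = 10,
                                n_sites = 17,
                                lattice_spacing_um = 38,
                                base_seed = 1) {
  densities <- as.integer(densities)
  if (length(densities) == 0 || any(densities < 1) ||
      any(densities > n_sites^2))
    stop("`densities` must be agent counts in 1..n_sites^2", call. = FALSE)
  area_mm2 <- (n_sites * lattice_spacing_um / 1000)^2
  rows <- purrr::imap(densities, function(n, i) {
    div <- am <- 0
    for (r in seq_len(reps)) {
      set.seed(base_seed + 1000 * i + r)
      sim <- periodic_run(
        n_agents = n, move_rate_per_min = move_rate_per_min,
        proliferation_rate_per_min = proliferation_rate_per_min,
        duration_min = window_min, n_sites = n_sites,
        lattice_spacing_um = lattice_spacing_um,
        track_interval = window_min
      )
      div <- div + sim$counts$proliferate_exec
      am <- am + sim$agent_minutes
    }
    tibble::tibble(
      n_agents = n, density_cells_per_mm2 = n / area_mm2,
      divisions = div, agent_minutes = am,
      T_c_min = if (div > 0) am / div else NA_real_,
      undefined = div == 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Population doubling-time assay
#'
#' Measures the unconstrained population doubling time: founders are placed
#' well separated on a large non-growing lattice so crowding stays
#' negligible, the ensemble-mean population curve is recorded, and an
#' exponential is fitted by least squares on the log scale. At the default
#' proliferation rate `log(2)/420` min^-1 the assay returns ~7 hours.
#'
#' @param proliferation_rate_per_min Attempt rate P_p (> 0).
#' @param move_rate_per_min Attempt rate P_m.
#' @param reps Number of realizations (default 100).
#' @param duration_min Assay length (default 840 min = 14 h).
#' @param n_founders Number of well-separated founders.
#' @param lattice_sites Side length of the square assay lattice.
#' @param sample_every Sampling interval for the population curve, minutes.
#' @param base_seed Seed base; replicate `r` uses `base_seed + r`.
#' @return A `doubling_assay`: list with `doubling_time_h`, `rate_per_min`,
#'   and `curve` (tibble `time_min`, `mean_n`).
#' @export
doubling_time_assay <- function(proliferation_rate_per_min = log(2) / 420,
                                move_rate_per_min = 0.2,
                                reps = 100,
                                duration_min = 840,
                                n_founders = 21,
                                lattice_sites = 180,
                                sample_every = 60,
                                base_seed = 1) {
  lattice_sites <- as.integer(lattice_sites)
  side <- ceiling(sqrt(n_founders))
  sp <- floor(lattice_sites / side)
  if (sp < 8)
    stop("lattice too small to separate the founders", call. = FALSE)
  pos <- expand.grid(site_dv = as.integer(seq(sp %/% 2, by = sp, length.out = side)),
                     site_ax = as.integer(seq(sp %/% 2, by = sp, length.out = side)))
  pos <- pos[seq_len(n_founders), ]
  agents <- tibble::tibble(
    agent_id = seq_len(n_founders), lineage = seq_len(n_founders),
    colour = NA_integer_, rare_mark = 0L,
    site_dv = pos$site_dv, site_ax = pos$site_ax
  )
  init <- domain_state(lattice_sites, lattice_sites, agents)
  times <- seq(0, duration_min, by = sample_every)
  params <- sim_params(
    move_rate_per_min = move_rate_per_min,
    proliferation_rate_per_min = proliferation_rate_per_min,
    growth_rate_axial_per_min = 0, growth_rate_dv_per_min = 0,
    initial_sites_dv = lattice_sites, initial_sites_axial = lattice_sites,
    duration_min = duration_min, n_founders = n_founders
  )
  counts <- purrr::map(seq_len(reps), function(r) {
    params$rng_seed <- as.integer(base_seed + r)
    sim <- simulate_colonization(params, scenario = "wildtype",
                                 init_state = init, sample_times = times)
    dplyr::count(sim$snapshots, .data$time_min)$n
  })
  mean_n <- Reduce(`+`, counts) / reps
  if (stats::var(log(mean_n)) < 1e-12)
    stop("population did not grow; cannot fit a doubling time", call. = FALSE)
  fit <- stats::lm(log(mean_n) ~ times)
  rate <- unname(stats::coef(fit)[2])
  if (rate <= 0)
    stop("population did not grow; cannot fit a doubling time", call. = FALSE)
  structure(
    list(doubling_time_h = log(2) / rate / 60, rate_per_min = rate,
         curve = tibble::tibble(time_min = times, mean_n = mean_n),
         reps = reps),
    class = "doubling_assay"
  )
}

#' @export
print.doubling_assay <- function(x, ...) {
  cat(sprintf("<doubling_assay> doubling time %.2f h (rate %.4g min^-1, %d reps)\n",
              x$doubling_time_h, x$rate_per_min, x$reps))
  invisible(x)
}

#' Colonization sensitivity to diffusion and cell-cycle time
#'
#' Sweeps the movement rate (as multipliers of the default, i.e. of the
#' baseline diffusion coefficient D0, since D is proportional to P_m at
#' fixed spacing) against the cell-cycle time T_c (hours; the proliferation
#' rate is `log(2)/(60 T_c)`), running `reps` full wildtype colonization
#' simulations per grid cell and reporting the fraction that fully colonize
#' the domain ([colonization_status()]). Colonization is markedly more
#' sensitive to T_c than to diffusion over matched relative ranges.
#'
#' @param pm_multipliers Multipliers of `params$move_rate_per_min` (the D/D0
#'   axis).
#' @param tc_hours Cell-cycle times in hours.
#' @param reps Replicates per grid cell (>= 10).
#' @param params Baseline [sim_params()].
#' @param min_area_sites Belly-spot calling threshold.
#' @param base_seed Seed base.
#' @return A tibble of class `sweep_result` with columns `pm_multiplier`,
#'   `Tc_hours`, `colonization_probability`, `reps`.
#' @export
sensitivity_sweep <- function(pm_multipliers = c(0.5, 1, 2),
                              tc_hours = c(7, 10, 14),
                              reps = 20,
                              params = sim_params(),
                              min_area_sites = 5,
                              base_seed = 1) {
  if (length(pm_multipliers) == 0 || length(tc_hours) == 0)
    stop("sweep grids must be non-empty", call. = FALSE)
  if (reps < 10) stop("`reps` must be at least 10", call. = FALSE)
  grid <- expand.grid(pm_multiplier = pm_multipliers, Tc_hours = tc_hours)
  rows <- purrr::map(seq_len(nrow(grid)), function(g) {
    p <- params
    p$move_rate_per_min <- params$move_rate_per_min * grid$pm_multiplier[g]
    p$proliferation_rate_per_min <- proliferation_rate_from_tc(grid$Tc_hours[g])
    ok <- vapply(seq_len(reps), function(r) {
      p$rng_seed <- as.integer(base_seed + 1000 * g + r)
      sim <- simulate_colonization(p, scenario = "wildtype")
      colonization_status(sim$final_state, min_area_sites = min_area_sites)
    }, logical(1))
    tibble::tibble(
      pm_multiplier = grid$pm_multiplier[g], Tc_hours = grid$Tc_hours[g],
      colonization_probability = mean(ok), reps = reps
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("sweep_result", class(out)))
}
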