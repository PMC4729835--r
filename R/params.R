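#' Simulation parameters for the lattice colonization model
#'
#' Bundles all rates and geometry of the volume-excluding lattice model of
#' melanoblast colonization. Defaults reproduce the wildtype embryonic-trunk
#' conditions: a lattice spacing of 38 micrometres (one cell diameter), an
#' initial domain of 31 dorsoventral by 43 axial sites (1,178 x 1,634 um),
#' constant stochastic growth rates of 0.0246 per minute (dorsoventral) and
#' 0.00526 per minute (axial) so mean domain growth is linear, 21 founder
#' cells, and a 5-day (7,200 min) simulated colonization window.
#'
#' The default proliferation rate is `log(2)/420` per minute, i.e. an
#' unconstrained population doubling time of 7 hours (the fastest doubling
#' compatible with dermal melanoblast counts over E10.5-E11.5). The default
#' movement rate of 0.2 per minute (free-agent diffusion coefficient
#' \eqn{P_m \Delta^2 / 4 \approx 72} um^2/min) is anchored so the model
#' reproduces the observed colonization behaviour - robust full colonization
#' at a 7 h cell cycle, ventral belly spots at 10 h; it can be re-fitted
#' against empirical density-diffusion data with [fit_movement_rate()].
#'
#' @param lattice_spacing_um Lattice spacing Delta in micrometres (> 0).
#' @param move_rate_per_min Per-agent movement attempt rate P_m (>= 0, min^-1).
#' @param proliferation_rate_per_min Per-agent proliferation attempt rate P_p
#'   (>= 0, min^-1).
#' @param growth_rate_axial_per_min Rate P_ga of axial domain-growth events
#'   (>= 0, min^-1).
#' @param growth_rate_dv_per_min Rate P_gd of dorsoventral domain-growth
#'   events (>= 0, min^-1).
#' @param initial_sites_dv Initial dorsoventral lattice extent L_x(0) (>= 1).
#' @param initial_sites_axial Initial axial lattice extent L_y(0) (>= 1).
#' @param duration_min Simulated duration in minutes (>= 0).
#' @param n_founders Number of founder agents (>= 1).
#' @param rng_seed Optional integer seed; when set, [simulate_colonization()]
#'   seeds R's RNG so a realization is bit-reproducible.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params()
#' domain_extent_um(p)
#' @export
sim_params <- function(lattice_spacing_um = 38,
                       move_rate_per_min = 0.2,
                       proliferation_rate_per_min = log(2) / 420,
                       growth_rate_axial_per_min = 0.00526,
                       growth_rate_dv_per_min = 0.0246,
                       initial_sites_dv = 31L,
                       initial_sites_axial = 43L,
                       duration_min = 7200,
                       n_founders = 21L,
                       rng_seed = NULL) {
  p <- list(
    lattice_spacing_um = as.numeric(lattice_spacing_um),
    move_rate_per_min = as.numeric(move_rate_per_min),
    proliferation_rate_per_min = as.numeric(proliferation_rate_per_min),
    growth_rate_axial_per_min = as.numeric(growth_rate_axial_per_min),
    growth_rate_dv_per_min = as.numeric(growth_rate_dv_per_min),
    initial_sites_dv = as.integer(initial_sites_dv),
    initial_sites_axial = as.integer(initial_sites_axial),
    duration_min = as.numeric(duration_min),
    n_founders = as.integer(n_founders),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  scalar_ok <- function(x) length(x) == 1L && is.finite(x)
  if (!scalar_ok(p$lattice_spacing_um) || p$lattice_spacing_um <= 0)
    stop("`lattice_spacing_um` must be a single positive number", call. = FALSE)
  for (nm in c("move_rate_per_min", "proliferation_rate_per_min",
               "growth_rate_axial_per_min", "growth_rate_dv_per_min")) {
    if (!scalar_ok(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("`%s` must be a single non-negative rate", nm), call. = FALSE)
  }
  for (nm in c("initial_sites_dv", "initial_sites_axial", "n_founders")) {
    if (!scalar_ok(p[[nm]]) || p[[nm]] < 1L)
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
  }
  if (!scalar_ok(p$duration_min) || p$duration_min < 0)
    stop("`duration_min` must be a single non-negative time", call. = FALSE)
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  lattice: %d x %d sites, spacing %.4g um\n",
              x$initial_sites_dv, x$initial_sites_axial, x$lattice_spacing_um))
  cat(sprintf("  rates (min^-1): P_m = %.4g, P_p = %.4g, P_gd = %.4g, P_ga = %.4g\n",
              x$move_rate_per_min, x$proliferation_rate_per_min,
              x$growth_rate_dv_per_min, x$growth_rate_axial_per_min))
  cat(sprintf("  duration: %.4g min, founders: %d, seed: %s\n",
              x$duration_min, x$n_founders,
              if (is.null(x$rng_seed)) "none" else x$rng_seed))
  invisible(x)
}

#' Geometric constants implied by the lattice spacing
#'
#' `excluded_area_um2()` is the area excluded by a single agent (one lattice
#' site, Delta^2). `full_lattice_density()` is the cell density of a fully
#' occupied domain in cells per square millimetre. `domain_extent_um()` gives
#' the initial physical extent of the domain in micrometres (dorsoventral,
#' axial).
#'
#' @param params A [sim_params()] object.
#' @return A number (or a named length-2 vector for `domain_extent_um`).
#' @examples
#' excluded_area_um2(sim_params()) # 1444 um^2 per cell
#' full_lattice_density(sim_params()) # ~692 cells / mm^2
#' @export
excluded_area_um2 <- function(params) {
  params$lattice_spacing_um^2
}

#' @rdname excluded_area_um2
#' @export
full_lattice_density <- function(params) {
  1e6 / params$lattice_spacing_um^2
}

#' @rdname excluded_area_um2
#' @export
domain_extent_um <- function(params) {
  c(dorsoventral = params$initial_sites_dv * params$lattice_spacing_um,
    axial = params$initial_sites_axial * params$lattice_spacing_um)
}

#' Doubling time from two population counts under exponential growth
#'
#' Given counts `n0` at time 0 and `n1` after `dt_hours` of exponential
#' growth, returns the implied population doubling time
#' `dt_hours * log(2) / log(n1 / n0)` in hours. With the extreme dermal
#' melanoblast counts (lower 95% CI at E10.5, 20.32 - 5.95 = 14.37 cells;
#' upper 95% CI at E11.5, 151.09 + 27.95 = 179.04 cells; 24 h apart) this
#' gives the 6.6 h dermal bound that motivates the model's 7 h cap.
#'
#' @param n0,n1 Positive counts at the start and end of the interval.
#' @param dt_hours Interval length in hours (> 0).
#' @return Doubling time in hours.
#' @examples
#' doubling_time_from_counts(20.32 - 5.95, 151.09 + 27.95, 24)
#' @export
doubling_time_from_counts <- function(n0, n1, dt_hours) {
  if (n0 <= 0 || n1 <= 0 || dt_hours <= 0)
    stop("counts and interval must be positive", call. = FALSE)
  if (n1 <= n0) stop("`n1` must exceed `n0` for a doubling time", call. = FALSE)
  dt_hours * log(2) / log(n1 / n0)
}

#' Convert a cell-cycle time to the model's proliferation rate
#'
#' The model's proliferation attempt rate is `log(2) / (T_c * 60)` per minute
#' for a cell-cycle time `T_c` in hours, so that the unconstrained population
#' doubling time equals `T_c`.
#'
#' @param tc_hours Cell-cycle time in hours (> 0).
#' @return Rate in min^-1.
#' @export
proliferation_rate_from_tc <- function(tc_hours) {
  if (any(tc_hours <= 0)) stop("`tc_hours` must be positive", call. = FALSE)
  log(2) / (tc_hours * 60)
}
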