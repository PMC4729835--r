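#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Broom-style tidiers for simulation and estimator objects
#'
#' `tidy()` returns the per-unit table of an object (final agents of a
#' simulation, spectrum bins, clone sizes, MSD lags); `glance()` returns a
#' one-row summary.
#'
#' @param x A `melano_sim`, `diffusion_fit`, `spectrum_result`,
#'   `lineage_stats`, `belly_spot`, `movement_rate_fit` or `doubling_assay`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.melano_sim <- function(x, ...) {
  as_tibble(x$final_state)
}

#' @rdname tidiers
#' @export
glance.melano_sim <- function(x, ...) {
  fs <- x$final_state
  spacing <- x$params$lattice_spacing_um
  tibble::tibble(
    scenario = x$scenario,
    n_agents = nrow(fs$agents),
    n_sites_dv = fs$n_sites_dv,
    n_sites_axial = fs$n_sites_axial,
    occupancy = nrow(fs$agents) / (fs$n_sites_dv * fs$n_sites_axial),
    density_cells_per_mm2 = nrow(fs$agents) /
      (fs$n_sites_dv * fs$n_sites_axial * (spacing / 1000)^2),
    duration_min = x$params$duration_min,
    early_stop = x$early_stop
  )
}

#' @rdname tidiers
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = "D_um2_per_min", estimate = x$D_um2_per_min)
}

#' @rdname tidiers
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(D_um2_per_min = x$D_um2_per_min, slope = x$slope,
                 residual_rms = x$residual_rms, n_lags_used = x$n_lags_used)
}

#' @rdname tidiers
#' @export
tidy.spectrum_result <- function(x, ...) {
  x$spectrum
}

#' @rdname tidiers
#' @export
glance.spectrum_result <- function(x, ...) {
  tibble::tibble(dominant_frequency = x$dominant_frequency,
                 stripe_intensity = x$stripe_intensity,
                 n_signals = x$n_signals, signal_length = x$signal_length)
}

#' @rdname tidiers
#' @export
tidy.lineage_stats <- function(x, ...) {
  x$clone_sizes
}

#' @rdname tidiers
#' @export
glance.lineage_stats <- function(x, ...) {
  tibble::tibble(total = x$total, n_lineages = nrow(x$clone_sizes),
                 k = x$k, top_k_share = x$top_k_share)
}

#' @rdname tidiers
#' @export
tidy.belly_spot <- function(x, ...) {
  x$sites
}

#' @rdname tidiers
#' @export
glance.belly_spot <- function(x, ...) {
  tibble::tibble(present = x$present, area_sites = x$area_sites,
                 area_um2 = x$area_um2)
}

#' @rdname tidiers
#' @export
tidy.movement_rate_fit <- function(x, ...) {
  x$sse
}

#' @rdname tidiers
#' @export
glance.movement_rate_fit <- function(x, ...) {
  tibble::tibble(P_m = x$P_m)
}

#' @rdname tidiers
#' @export
glance.doubling_assay <- function(x, ...) {
  tibble::tibble(doubling_time_h = x$doubling_time_h,
                 rate_per_min = x$rate_per_min, reps = x$reps)
}

#' @rdname tidiers
#' @export
tidy.doubling_assay <- function(x, ...) {
  x$curve
}
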