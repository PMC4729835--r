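#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: domain
#' renders (one tile per site, dorsal left / ventral right, as one side of
#' the embryo is drawn), MSD curves with the fitted diffusion line,
#' pair-correlation functions with the CSR reference, clonal signals,
#' amplitude spectra, density-diffusion tables, and colonization sweep
#' heatmaps.
#'
#' @param object The object to plot.
#' @param fit For `autoplot.msd_curve`: an optional [fit_diffusion()] result
#'   whose line is overlaid.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-melanosim
NULL

#' @rdname autoplot-melanosim
#' @export
autoplot.domain_state <- function(object, ...) {
  ag <- object$agents
  ag$class <- dplyr::case_when(
    ag$rare_mark == 1L ~ "rare clone",
    is.na(ag$colour) ~ "agent",
    ag$colour > 0 ~ "colour +1",
    TRUE ~ "colour -1"
  )
  ggplot2::ggplot(ag, ggplot2::aes(x = .data$site_dv, y = .data$site_ax,
                                   fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      "agent" = "grey40", "colour +1" = "grey75", "colour -1" = "black",
      "rare clone" = "red3"
    )) +
    ggplot2::coord_fixed(xlim = c(0.5, object$n_sites_dv + 0.5),
                         ylim = c(0.5, object$n_sites_axial + 0.5)) +
    ggplot2::labs(x = "dorsoventral site (dorsal -> ventral)",
                  y = "axial site", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-melanosim
#' @export
autoplot.msd_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_min,
                                            y = .data$msd_um2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag (min)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(slope = fit$slope, intercept = 0,
                                  colour = "red")
  }
  p
}

#' @rdname autoplot-melanosim
#' @export
autoplot.pcf_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 1, colour = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "r (um)", y = "g(r)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-melanosim
#' @export
autoplot.clonal_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$site_ax, y = .data$signal)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "axial site", y = "clonal signal") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-melanosim
#' @export
autoplot.spectrum_result <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$frequency, y = .data$amplitude)) +
    ggplot2::geom_col(width = 0.8 / object$signal_length) +
    ggplot2::labs(x = "frequency (cycles / site)", y = "mean amplitude") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-melanosim
#' @export
autoplot.density_diffusion_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$density_cells_per_mm2,
                                       y = .data$D_um2_per_min)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(density ~ (cells / mm^2)),
                  y = expression(D ~ (mu * m^2 / min))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-melanosim
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$Tc_hours),
                                       y = factor(.data$pm_multiplier),
                                       fill = .data$colonization_probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "blue", high = "red",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = expression(T[c] ~ (h)), y = expression(D / D[0]),
                  fill = "P(colonized)") +
    ggplot2::theme_minimal()
}
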