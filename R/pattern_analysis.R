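#' Clonal signal of a two-colour labelled domain
#'
#' Assigns +1 to sites holding one colour, -1 to the other and 0 to empty
#' sites, then averages over the dorsoventral extent of each axial row. The
#' resulting axial profile measures the local colour balance; periodic sign
#' changes indicate dorsoventral stripes.
#'
#' @param state A `domain_state` whose agents carry two-colour labels
#'   (+1/-1), e.g. from the chimera scenario of [simulate_colonization()].
#' @return A tibble of class `clonal_signal` with columns `site_ax`,
#'   `signal` (each value in \[-1, 1\]).
#' @export
clonal_signal <- function(state) {
  cols <- state$agents$colour
  if (nrow(state$agents) > 0) {
    uc <- unique(cols)
    if (anyNA(uc))
      stop("all agents need a colour label; run the chimera scenario or ",
           "assign_chimera_labels() first", call. = FALSE)
    if (length(setdiff(uc, c(-1L, 1L))) > 0)
      stop("more than two colours present; collapse to +1/-1 labels first",
           call. = FALSE)
  }
  val <- matrix(0, state$n_sites_dv, state$n_sites_axial)
  if (nrow(state$agents) > 0)
    val[cbind(state$agents$site_dv, state$agents$site_ax)] <- cols
  out <- tibble::tibble(site_ax = seq_len(state$n_sites_axial),
                        signal = colMeans(val))
  structure(out, class = c("clonal_signal", class(out)))
}

#' Stripe intensity via the averaged discrete Fourier transform
#'
#' Computes the two-sided amplitude spectrum `|DFFT(signal)| / N` of each
#' clonal signal, averages the spectra across the ensemble, and locates the
#' dominant non-zero frequency (DC is excluded; the search runs up to the
#' Nyquist frequency). The amplitude at the dominant frequency is the
#' "stripe intensity": large when replicates share a coherent axial
#' periodicity (stripes), small when colours are well mixed. Signals from
#' replicates whose domains grew to different lengths are truncated to the
#' shortest length before averaging.
#'
#' @param signals A single [clonal_signal()] (or numeric vector) or a list of
#'   them; all of length >= 4 after truncation.
#' @return A `spectrum_result`: list with `spectrum` (tibble `frequency`
#'   cycles/site, `amplitude`), `dominant_frequency`, `stripe_intensity`,
#'   `n_signals`, `signal_length`.
#' @export
stripe_intensity <- function(signals) {
  if (is.data.frame(signals) || is.numeric(signals)) signals <- list(signals)
  vecs <- lapply(signals, function(s) {
    if (is.data.frame(s)) as.numeric(s$signal) else as.numeric(s)
  })
  n <- min(lengths(vecs))
  if (n < 4) stop("signals must have length >= 4", call. = FALSE)
  vecs <- lapply(vecs, function(v) v[seq_len(n)])
  amps <- vapply(vecs, function(v) Mod(stats::fft(v)) / n, numeric(n))
  avg <- rowMeans(amps)
  nyq <- floor(n / 2)
  freq <- (seq_len(nyq)) / n
  amp_pos <- avg[2:(nyq + 1)]
  k <- which.max(amp_pos)
  structure(
    list(
      spectrum = tibble::tibble(frequency = freq, amplitude = amp_pos),
      full_spectrum = tibble::tibble(frequency = (0:(n - 1)) / n,
                                     amplitude = avg),
      dominant_frequency = freq[k],
      stripe_intensity = amp_pos[k],
      n_signals = length(vecs),
      signal_length = n
    ),
    class = "spectrum_result"
  )
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> %d signal(s) of length %d: stripe intensity %.4g at %.4g cycles/site\n",
              x$n_signals, x$signal_length, x$stripe_intensity,
              x$dominant_frequency))
  invisible(x)
}

#' Stripe intensity across clonal ratios
#'
#' For each clonal ratio `k` (number of the 21 founders labelled +1, the
#' remaining founders -1), runs `reps` chimeric colonization simulations to
#' completion, computes each realization's clonal signal, and reports the
#' stripe intensity of the ensemble-averaged spectrum. Balanced labelling
#' (`k` of 10 or 11, effectively two subtypes) yields the strongest stripes;
#' intensity falls as the effective number of subtypes rises (small `k`).
#'
#' @param params A [sim_params()] object (its `rng_seed` is ignored).
#' @param k_values Clonal ratios to test (each in 1..n_founders-1).
#' @param reps Replicates per ratio (>= 10 for a stable average).
#' @param base_seed Integer; replicate `r` of ratio index `i` is seeded with
#'   `base_seed + 1000 * i + r`.
#' @return A tibble of class `clonal_ratio_sweep` with columns `k`,
#'   `stripe_intensity`, `dominant_frequency`, `reps`.
#' @export
clonal_ratio_sweep <- function(params, k_values = 1:10, reps = 100,
                               base_seed = 1) {
  if (reps < 10) stop("`reps` must be at least 10", call. = FALSE)
  rows <- purrr::imap(k_values, function(k, i) {
    sigs <- purrr::map(seq_len(reps), function(r) {
      p <- params
      p$rng_seed <- as.integer(base_seed + 1000 * i + r)
      sim <- simulate_colonization(p, scenario = "chimera", chimera_k = k)
      clonal_signal(sim$final_state)
    })
    sp <- stripe_intensity(sigs)
    tibble::tibble(k = k, stripe_intensity = sp$stripe_intensity,
                   dominant_frequency = sp$dominant_frequency, reps = reps)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("clonal_ratio_sweep", class(out)))
}

#' Lineage (clone) size statistics
#'
#' Tallies the size of every lineage (all descendants of one founder share
#' its immutable label) and the share of the population contributed by the
#' `k` largest lineages.
#'
#' @param state A `domain_state`.
#' @param k Number of top lineages to pool (default 2).
#' @return A `lineage_stats` object: list with `clone_sizes` (tibble
#'   `lineage`, `n`, `share`, size-sorted), `total`, `k`, `top_k_share`.
#' @export
lineage_stats <- function(state, k = 2) {
  if (nrow(state$agents) == 0) stop("no agents present", call. = FALSE)
  sizes <- state$agents |>
    dplyr::count(.data$lineage, sort = TRUE) |>
    dplyr::mutate(share = .data$n / sum(.data$n))
  if (k > nrow(sizes))
    stop("`k` exceeds the number of lineages present", call. = FALSE)
  structure(
    list(clone_sizes = sizes, total = nrow(state$agents), k = k,
         top_k_share = sum(sizes$share[seq_len(k)])),
    class = "lineage_stats"
  )
}

#' @export
print.lineage_stats <- function(x, ...) {
  cat(sprintf("<lineage_stats> %d agents in %d lineages; top-%d share %.1f%%\n",
              x$total, nrow(x$clone_sizes), x$k, 100 * x$top_k_share))
  invisible(x)
}

#' @rdname lineage_stats
#' @return `top_lineage_share()`: the top-`k` share as a single number.
#' @export
top_lineage_share <- function(state, k = 2) {
  lineage_stats(state, k)$top_k_share
}

# 4-connected components of a logical matrix; returns an integer label matrix.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  stack <- integer(max(1L, sum(mask)))
  cur <- 0L
  visit <- function(nb) { # grow the current component (depth-first)
    if (mask[nb] && lab[nb] == 0L) {
      lab[nb] <<- cur
      top <<- top + 1L
      stack[top] <<- nb
    }
  }
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (top > 0L) {
      cell <- stack[top]
      top <- top - 1L
      i <- (cell - 1L) %% nr + 1L
      if (i > 1L) visit(cell - 1L)
      if (i < nr) visit(cell + 1L)
      if (cell > nr) visit(cell - nr)
      if (cell <= (nc - 1L) * nr) visit(cell + nr)
    }
  }
  lab
}

#' Detect a ventral belly spot
#'
#' A belly spot is operationalized as the largest 4-connected component of
#' empty lattice sites that touches the ventral boundary (dorsoventral index
#' `L_x`) and covers at least `min_area_sites` sites. Slowed proliferation
#' (e.g. a 10 h instead of 7 h cell-cycle time) leaves such a ventral
#' unpopulated patch at the end of the 5-day run, the in-silico analogue of
#' the depigmented belly spot of Kit mutant mice.
#'
#' @param state A `domain_state` (typically a final state).
#' @param min_area_sites Minimum component size to call a spot (default 5).
#' @param lattice_spacing_um Site spacing for the area conversion.
#' @return A `belly_spot` object: list with `present`, `area_sites`,
#'   `area_um2` (= `area_sites * spacing^2`), and `sites` (tibble of the
#'   component's `site_dv`, `site_ax`).
#' @export
belly_spot <- function(state, min_area_sites = 5, lattice_spacing_um = 38) {
  empty <- state$occupancy == 0L
  lab <- label_components(empty)
  ventral_labels <- setdiff(unique(lab[state$n_sites_dv, ]), 0L)
  best <- 0L
  best_n <- 0L
  for (l in ventral_labels) {
    n <- sum(lab == l)
    if (n > best_n) {
      best <- l
      best_n <- n
    }
  }
  present <- best_n >= min_area_sites
  sites <- if (present) {
    w <- which(lab == best, arr.ind = TRUE)
    tibble::tibble(site_dv = as.integer(w[, 1]), site_ax = as.integer(w[, 2]))
  } else {
    tibble::tibble(site_dv = integer(), site_ax = integer())
  }
  area <- if (present) best_n else 0L
  structure(
    list(present = present, area_sites = area,
         area_um2 = area * lattice_spacing_um^2, sites = sites),
    class = "belly_spot"
  )
}

#' @export
print.belly_spot <- function(x, ...) {
  if (x$present) {
    cat(sprintf("<belly_spot> present: %d sites (%.0f um^2)\n",
                x$area_sites, x$area_um2))
  } else {
    cat("<belly_spot> absent\n")
  }
  invisible(x)
}

#' Cell density in the central portion of the domain
#'
#' Mean occupancy of the central region of the lattice (the middle `fraction`
#' of both axes), converted to cells per square millimetre. This mirrors
#' mid-trunk density measurements away from the advancing ventral front; a
#' fully occupied region returns `1e6 / spacing^2` (~692 cells/mm^2 at 38 um).
#'
#' @param state A `domain_state`.
#' @param lattice_spacing_um Site spacing in um.
#' @param fraction Central fraction of each axis to average over.
#' @return Density in cells per mm^2.
#' @export
mid_domain_density <- function(state, lattice_spacing_um = 38,
                               fraction = 1 / 3) {
  ix <- seq(floor(state$n_sites_dv * (1 - fraction) / 2) + 1,
            ceiling(state$n_sites_dv * (1 + fraction) / 2))
  iy <- seq(floor(state$n_sites_axial * (1 - fraction) / 2) + 1,
            ceiling(state$n_sites_axial * (1 + fraction) / 2))
  occ <- mean(state$occupancy[ix, iy] > 0)
  occ * 1e6 / lattice_spacing_um^2
}

#' Colonization status of a final state
#'
#' The domain counts as colonized when no ventral belly spot remains (see
#' [belly_spot()]).
#'
#' @inheritParams belly_spot
#' @return Logical flag.
#' @export
colonization_status <- function(state, min_area_sites = 5) {
  !belly_spot(state, min_area_sites = min_area_sites)$present
}
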