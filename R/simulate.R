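#' Simulate melanoblast colonization of the growing trunk
#'
#' Runs one exact Gillespie (stochastic simulation algorithm) realization of
#' the volume-excluding lattice model. The total event propensity is
#' \eqn{R = N (P_m + P_p) + P_{ga} + P_{gd}} for the current agent count
#' \eqn{N}; waiting times are exponential with rate \eqn{R}; the event class
#' is chosen proportionally to its propensity; for movement/proliferation the
#' agent and one of the four lattice directions are chosen uniformly.
#' Attempts into occupied or off-lattice sites are aborted but still consume
#' the sampled event (zero-flux boundaries, volume exclusion).
#'
#' Scenarios:
#' \describe{
#'   \item{`wildtype`}{21 weighted founders ([sample_founders()]), default
#'     growth; the standard 5-day colonization run.}
#'   \item{`chimera`}{wildtype founders given two-colour labels with
#'     [assign_chimera_labels()] (balanced 10/11 split, or `chimera_k`
#'     founders +1).}
#'   \item{`rare_clone`}{wildtype run in which one living agent, chosen
#'     uniformly at a time drawn uniformly on (0, duration), is marked; all
#'     its progeny inherit the mark.}
#'   \item{`cheeseman`}{fixed 50 x 50 lattice with the 10 dorsal-most columns
#'     fully occupied by 500 distinct lineages; domain growth is switched off
#'     for this scenario.}
#' }
#'
#' @param params A [sim_params()] object. If `params$rng_seed` is set the RNG
#'   is seeded, making the realization bit-reproducible.
#' @param scenario One of `"wildtype"`, `"chimera"`, `"rare_clone"`,
#'   `"cheeseman"`.
#' @param sample_times Times (minutes) at which to snapshot the full agent
#'   table; `0` is always included and times must not exceed the duration.
#'   Default: start and end only.
#' @param chimera_k For the chimera scenario: number of founders labelled +1
#'   (`NULL` for a balanced 10/11 split).
#' @param record_events Keep a per-event audit log (time, kind, executed
#'   flag, agent, sites). Only advisable for short runs.
#' @param init_state Optional `domain_state` overriding the scenario's
#'   initial condition.
#' @param track_interval If not `NULL`, record the (boundary-unwrapped)
#'   positions of the initial agents every `track_interval` minutes; used by
#'   the periodic calibration runs.
#' @param periodic Use periodic instead of zero-flux boundaries (calibration
#'   runs only; requires zero growth rates).
#' @param truncate_at_wrap For tracked periodic runs: truncate each track at
#'   its first boundary crossing (see [periodic_run()]).
#' @param mark_time For the rare-clone scenario: override the uniformly drawn
#'   marking time with a fixed time in `[0, duration_min]`.
#'
#' @return A `melano_sim` object: a list with `snapshots` (tibble of agent
#'   records per sample time), `final_state` (a [domain_state()] including the
#'   occupancy matrix), `counts` (executed/aborted event tallies),
#'   `agent_minutes` (integral of the agent count over time), `events`
#'   (tibble or `NULL`), `tracks`, `marked_agent`/`marked_at`, `early_stop`,
#'   `params` and `scenario`.
#' @examples
#' p <- sim_params(duration_min = 60, rng_seed = 1)
#' sim <- simulate_colonization(p)
#' glance(sim)
#' @export
simulate_colonization <- function(params,
                                  scenario = c("wildtype", "chimera",
                                               "rare_clone", "cheeseman"),
                                  sample_times = NULL,
                                  chimera_k = NULL,
                                  record_events = FALSE,
                                  init_state = NULL,
                                  track_interval = NULL,
                                  periodic = FALSE,
                                  truncate_at_wrap = TRUE,
                                  mark_time = NULL) {
  validate_sim_params(params)
  scenario <- match.arg(scenario)
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)

  pga <- params$growth_rate_axial_per_min
  pgd <- params$growth_rate_dv_per_min
  if (!is.null(mark_time) && scenario != "rare_clone")
    stop("`mark_time` applies to the rare_clone scenario only", call. = FALSE)

  if (is.null(init_state)) {
    init_state <- switch(scenario,
      wildtype = sample_founders(params),
      chimera = assign_chimera_labels(sample_founders(params),
                                      balanced = is.null(chimera_k),
                                      k = chimera_k),
      rare_clone = sample_founders(params),
      cheeseman = cheeseman_init()
    )
  }
  if (scenario == "cheeseman") pga <- pgd <- 0
  if (scenario == "rare_clone") {
    if (is.null(mark_time)) mark_time <- stats::runif(1) * params$duration_min
    if (mark_time < 0 || mark_time > params$duration_min)
      stop("`mark_time` must lie in [0, duration_min]", call. = FALSE)
  } else {
    mark_time <- -1
  }
  if (periodic && (pga > 0 || pgd > 0))
    stop("periodic boundaries require zero growth rates", call. = FALSE)

  if (is.null(sample_times)) sample_times <- c(0, params$duration_min)
  sample_times <- sort(unique(c(0, as.numeric(sample_times))))
  if (any(sample_times < 0 | sample_times > params$duration_min))
    stop("`sample_times` must lie in [0, duration_min]", call. = FALSE)

  ag <- init_state$agents
  res <- .engine_run(
    Lx = init_state$n_sites_dv, Ly = init_state$n_sites_axial,
    site_dv = as.integer(ag$site_dv), site_ax = as.integer(ag$site_ax),
    lineage = as.integer(ag$lineage),
    colour = ifelse(is.na(ag$colour), 0L, as.integer(ag$colour)),
    rare = as.integer(ag$rare_mark),
    pm = params$move_rate_per_min, pp = params$proliferation_rate_per_min,
    pga = pga, pgd = pgd,
    t_end = params$duration_min,
    sample_times = sample_times,
    periodic = periodic,
    mark_time = mark_time,
    record_events = record_events,
    track = !is.null(track_interval),
    track_interval = if (is.null(track_interval)) 0 else track_interval
  )

  snapshots <- purrr::map_dfr(res$snapshots, function(s) {
    tibble::tibble(
      time_min = s$time_min, agent_id = s$agent_id,
      lineage = s$lineage, colour = restore_na_colour(s$colour),
      rare_mark = s$rare_mark,
      site_dv = s$site_dv, site_ax = s$site_ax,
      n_sites_dv = s$n_sites_dv, n_sites_axial = s$n_sites_axial
    )
  })

  fin <- res$final
  final_agents <- tibble::tibble(
    agent_id = fin$agent_id, lineage = fin$lineage,
    colour = restore_na_colour(fin$colour), rare_mark = fin$rare_mark,
    site_dv = fin$site_dv, site_ax = fin$site_ax
  )
  final_state <- domain_state(fin$n_sites_dv, fin$n_sites_axial, final_agents,
                              fin$time_min)

  events <- NULL
  if (record_events) {
    ev <- res$events
    events <- tibble::tibble(
      time_min = ev$time_min,
      kind = c("move", "proliferate", "grow_dv", "grow_ax",
               "mark")[ev$kind + 1L],
      executed = ev$executed == 1L,
      agent_id = ev$agent_id,
      x1 = ev$x1, y1 = ev$y1, x2 = ev$x2, y2 = ev$y2
    )
  }

  tracks <- NULL
  if (!is.null(track_interval)) {
    tracks <- tracks_from_engine(res$tracks, params$lattice_spacing_um,
                                 truncate_at_wrap)
  }

  structure(
    list(
      snapshots = snapshots, final_state = final_state,
      counts = tibble::as_tibble(res$counts),
      agent_minutes = res$agent_minutes,
      events = events, tracks = tracks,
      marked_agent = res$marked_agent, marked_at = res$marked_at,
      early_stop = res$early_stop,
      params = params, scenario = scenario
    ),
    class = "melano_sim"
  )
}

restore_na_colour <- function(col) {
  col[col == 0L] <- NA_integer_
  col
}

# Engine track matrices -> tidy TrackSet, truncated at the first boundary
# crossing (samples strictly after the first wrap are dropped, emulating the
# loss of a cell that leaves the microscope field of view).
tracks_from_engine <- function(trk, spacing_um, truncate_at_wrap = TRUE) {
  xs <- trk$x_sites
  ys <- trk$y_sites
  dt <- trk$sample_interval
  times <- (seq_len(ncol(xs)) - 1) * dt
  purrr::map_dfr(seq_len(nrow(xs)), function(a) {
    keep <- if (truncate_at_wrap) times <= trk$first_wrap_time[a]
            else rep(TRUE, length(times))
    tibble::tibble(
      track_id = a,
      time_min = times[keep],
      x_um = (xs[a, keep] - 0.5) * spacing_um,
      y_um = (ys[a, keep] - 0.5) * spacing_um
    )
  })
}

#' @export
print.melano_sim <- function(x, ...) {
  cat(sprintf("<melano_sim> scenario '%s': %d agents on %d x %d sites after %.4g min\n",
              x$scenario, nrow(x$final_state$agents),
              x$final_state$n_sites_dv, x$final_state$n_sites_axial,
              x$final_state$time_min))
  invisible(x)
}

#' Move-only or proliferating run on a small periodic lattice
#'
#' Initializes `n_agents` at distinct uniform sites of an `n_sites` x
#' `n_sites` lattice with periodic boundary conditions (default 17 x 17 =
#' 646 x 646 um, the microscope field of view) and evolves movement (and
#' optionally proliferation) for `duration_min`. Positions of the initial
#' agents are recorded every `track_interval` minutes as boundary-unwrapped
#' coordinates, and each track is truncated at its first boundary crossing,
#' as a tracked cell leaving the field of view would be.
#'
#' @param n_agents Number of agents (1 to `n_sites^2`).
#' @param move_rate_per_min,proliferation_rate_per_min Attempt rates.
#' @param duration_min Run length (default 400 min).
#' @param n_sites Lattice side length (default 17).
#' @param lattice_spacing_um Site spacing (default 38 um).
#' @param track_interval Sampling interval for tracks, minutes.
#' @param truncate_at_wrap Drop the portion of each track after its first
#'   boundary crossing (the default, matching the experimental loss of
#'   boundary-crossing cells; note this biases fitted diffusion coefficients
#'   slightly downwards). Set `FALSE` to keep the full unwrapped walks, e.g.
#'   for comparison with the free-walk value \eqn{P_m \Delta^2 / 4}.
#' @return A `melano_sim` with a `tracks` tibble
#'   (`track_id,time_min,x_um,y_um`).
#' @export
periodic_run <- function(n_agents,
                         move_rate_per_min = 0.2,
                         proliferation_rate_per_min = 0,
                         duration_min = 400,
                         n_sites = 17,
                         lattice_spacing_um = 38,
                         track_interval = 20,
                         truncate_at_wrap = TRUE) {
  n_sites <- as.integer(n_sites)
  if (n_agents < 1 || n_agents > n_sites^2)
    stop("`n_agents` must lie in 1..n_sites^2", call. = FALSE)
  cells <- sample.int(n_sites^2, n_agents)
  agents <- tibble::tibble(
    agent_id = seq_len(n_agents), lineage = seq_len(n_agents),
    colour = NA_integer_, rare_mark = 0L,
    site_dv = as.integer((cells - 1L) %% n_sites + 1L),
    site_ax = as.integer((cells - 1L) %/% n_sites + 1L)
  )
  init <- domain_state(n_sites, n_sites, agents)
  params <- sim_params(
    lattice_spacing_um = lattice_spacing_um,
    move_rate_per_min = move_rate_per_min,
    proliferation_rate_per_min = proliferation_rate_per_min,
    growth_rate_axial_per_min = 0, growth_rate_dv_per_min = 0,
    initial_sites_dv = n_sites, initial_sites_axial = n_sites,
    duration_min = duration_min, n_founders = n_agents
  )
  simulate_colonization(params, scenario = "wildtype", init_state = init,
                        track_interval = track_interval, periodic = TRUE,
                        truncate_at_wrap = truncate_at_wrap)
}
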