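#' Lattice domain state
#'
#' A `domain_state` is the simulator's world at one instant: an occupancy
#' matrix (rows = dorsoventral sites, columns = axial sites; `0` = empty,
#' otherwise the occupying agent's id) plus a tibble of agents with their
#' heritable lineage label, optional chimera colour label (+1/-1), rare-clone
#' mark, and site coordinates. Site indices are 1-based; dorsoventral index 1
#' is dorsal-most and `n_sites_dv` is ventral-most.
#'
#' @param n_sites_dv,n_sites_axial Lattice extent (>= 1).
#' @param agents A tibble with columns `agent_id`, `lineage`, `colour`,
#'   `rare_mark`, `site_dv`, `site_ax` (may have zero rows).
#' @param time_min Simulation time of this state.
#' @return An object of class `domain_state`.
#' @export
domain_state <- function(n_sites_dv, n_sites_axial, agents = empty_agents(),
                         time_min = 0) {
  n_sites_dv <- as.integer(n_sites_dv)
  n_sites_axial <- as.integer(n_sites_axial)
  if (n_sites_dv < 1L || n_sites_axial < 1L)
    stop("lattice extents must be >= 1", call. = FALSE)
  agents <- tibble::as_tibble(agents)
  occ <- matrix(0L, n_sites_dv, n_sites_axial)
  if (nrow(agents) > 0) {
    if (any(agents$site_dv < 1L | agents$site_dv > n_sites_dv |
            agents$site_ax < 1L | agents$site_ax > n_sites_axial))
      stop("agent sites fall outside the lattice", call. = FALSE)
    ij <- cbind(agents$site_dv, agents$site_ax)
    if (anyDuplicated(ij))
      stop("volume exclusion violated: two agents share a site", call. = FALSE)
    occ[ij] <- agents$agent_id
  }
  structure(
    list(occupancy = occ, agents = agents, time_min = as.numeric(time_min),
         n_sites_dv = n_sites_dv, n_sites_axial = n_sites_axial),
    class = "domain_state"
  )
}

empty_agents <- function() {
  tibble::tibble(agent_id = integer(), lineage = integer(), colour = integer(),
                 rare_mark = integer(), site_dv = integer(), site_ax = integer())
}

#' @export
print.domain_state <- function(x, ...) {
  cat(sprintf("<domain_state> %d x %d sites, %d agents, t = %.4g min\n",
              x$n_sites_dv, x$n_sites_axial, nrow(x$agents), x$time_min))
  invisible(x)
}

#' @export
as_tibble.domain_state <- function(x, ...) {
  dplyr::mutate(x$agents, time_min = x$time_min)
}

#' Initialize an empty growing domain
#'
#' Builds the initial rectangular lattice (default 31 dorsoventral by 43
#' axial sites, i.e. 1,178 x 1,634 um at 38 um spacing) with no agents and
#' time zero.
#'
#' @param params A [sim_params()] object.
#' @return A `domain_state` with empty occupancy.
#' @examples
#' init_domain(sim_params())
#' @export
init_domain <- function(params) {
  validate_sim_params(params)
  domain_state(params$initial_sites_dv, params$initial_sites_axial)
}

#' Place founder melanoblasts with the weighted embryonic distribution
#'
#' Samples `n_founders` distinct sites reflecting the observed E10.5
#' melanoblast distribution: axially, one-third of the probability mass is
#' uniform on sites 12-32 (mid-trunk) and two-thirds uniform on sites 1-11
#' and 33-43; dorsoventrally, 95% of the mass is uniform on sites 8-17 and
#' the rest on sites 18-19, so every founder lies on dorsoventral sites 8-19.
#' Collisions are resampled; founders receive distinct lineage labels
#' `1..n_founders`. Uses R's RNG (seed with `set.seed()` or via
#' `params$rng_seed` inside [simulate_colonization()]).
#'
#' @param params A [sim_params()] object; the lattice must be at least 19
#'   sites dorsoventrally and 43 axially for the default placement weights.
#' @return A `domain_state` holding the founders at time 0.
#' @export
sample_founders <- function(params) {
  validate_sim_params(params)
  if (params$initial_sites_dv < 19L || params$initial_sites_axial < 43L)
    stop("lattice too small for the weighted founder placement ",
         "(needs >= 19 dorsoventral and >= 43 axial sites)", call. = FALSE)
  n <- params$n_founders
  taken <- character(0)
  site_dv <- site_ax <- integer(n)
  for (a in seq_len(n)) {
    repeat {
      ax <- if (stats::runif(1) < 1 / 3) {
        sample(12:32, 1)
      } else {
        sample(c(1:11, 33:43), 1)
      }
      dv <- if (stats::runif(1) < 0.95) sample(8:17, 1) else sample(18:19, 1)
      key <- paste(dv, ax)
      if (!key %in% taken) break
    }
    taken <- c(taken, key)
    site_dv[a] <- dv
    site_ax[a] <- ax
  }
  agents <- tibble::tibble(
    agent_id = seq_len(n), lineage = seq_len(n), colour = NA_integer_,
    rare_mark = 0L, site_dv = site_dv, site_ax = site_ax
  )
  domain_state(params$initial_sites_dv, params$initial_sites_axial, agents)
}

#' Densely packed initial condition of Cheeseman and colleagues
#'
#' A fixed 50 x 50 lattice whose 10 left-most (dorsal-most) columns are fully
#' occupied by 500 agents carrying distinct lineage labels. Used to contrast
#' lineage dominance under crowded initial conditions with the sparse
#' embryonic founder distribution; runs of this scenario use no domain
#' growth.
#'
#' @return A `domain_state` with 500 agents at time 0.
#' @export
cheeseman_init <- function() {
  pos <- expand.grid(site_dv = 1:10, site_ax = 1:50)
  agents <- tibble::tibble(
    agent_id = seq_len(nrow(pos)), lineage = seq_len(nrow(pos)),
    colour = NA_integer_, rare_mark = 0L,
    site_dv = as.integer(pos$site_dv), site_ax = as.integer(pos$site_ax)
  )
  domain_state(50L, 50L, agents)
}

#' Assign chimera colour labels to founders
#'
#' Labels founders with +1/-1 colours (or unique colours) at time zero.
#' With `n_colours = 2` and `balanced = TRUE`, 10 or 11 randomly selected
#' founders (chosen at random for 21 founders) are labelled +1 and the rest
#' -1, emulating a balanced aggregation chimera. With `n_colours = 2` and an
#' explicit `k`, exactly `k` random founders get +1 (a "clonal ratio" of k
#' versus n-k). With `n_colours` equal to the number of founders, each
#' founder's colour equals its lineage label.
#'
#' @param state A `domain_state` at time 0 (founders only).
#' @param n_colours Number of colour classes (2 or the founder count).
#' @param balanced For two colours: split approximately in half at random.
#' @param k For two colours with `balanced = FALSE`: number of +1 founders.
#' @return The state with the `colour` column filled.
#' @export
assign_chimera_labels <- function(state, n_colours = 2, balanced = TRUE,
                                  k = NULL) {
  n <- nrow(state$agents)
  if (n_colours > n)
    stop("`n_colours` exceeds the number of founders", call. = FALSE)
  if (n_colours == n) {
    state$agents$colour <- state$agents$lineage
  } else if (n_colours == 2) {
    if (balanced && is.null(k)) {
      k <- floor(n / 2) + stats::rbinom(1, 1, 0.5) * (n %% 2)
    }
    if (k < 0 || k > n) stop("`k` must lie in 0..n_founders", call. = FALSE)
    plus <- sample.int(n, k)
    state$agents$colour <- ifelse(seq_len(n) %in% plus, 1L, -1L)
  } else {
    stop("only 2-colour or one-colour-per-founder labelling is supported",
         call. = FALSE)
  }
  domain_state(state$n_sites_dv, state$n_sites_axial, state$agents,
               state$time_min)
}

dir_offsets <- function(direction) {
  switch(direction,
    "+dv" = c(1L, 0L), "-dv" = c(-1L, 0L),
    "+ax" = c(0L, 1L), "-ax" = c(0L, -1L),
    stop("direction must be one of '+dv', '-dv', '+ax', '-ax'", call. = FALSE)
  )
}

#' Single lattice events (reference implementations)
#'
#' Pure-R, single-step versions of the model's events, used for unit testing
#' and for constructing states by hand; the Gillespie engine executes the
#' same semantics in compiled code. `attempt_move()` relocates an agent to an
#' adjacent site if that site is inside the lattice and empty, otherwise the
#' attempt is aborted and the state is unchanged (zero-flux boundaries,
#' volume exclusion). `attempt_proliferate()` instead creates a new agent at
#' the target site; progeny inherit the parent's lineage label, colour label
#' and rare-clone mark. Both return the updated state together with an
#' `executed` flag, since aborted attempts still consume their sampled event
#' in the Gillespie loop.
#'
#' @param state A `domain_state`.
#' @param agent_id Id of an existing agent.
#' @param direction One of `"+dv"`, `"-dv"`, `"+ax"`, `"-ax"`.
#' @return A list with elements `state` (the possibly updated
#'   `domain_state`) and `executed` (logical).
#' @export
attempt_move <- function(state, agent_id, direction) {
  i <- match(agent_id, state$agents$agent_id)
  if (is.na(i)) stop("unknown agent id: ", agent_id, call. = FALSE)
  d <- dir_offsets(direction)
  tx <- state$agents$site_dv[i] + d[1]
  ty <- state$agents$site_ax[i] + d[2]
  ok <- tx >= 1L && tx <= state$n_sites_dv &&
    ty >= 1L && ty <= state$n_sites_axial &&
    state$occupancy[tx, ty] == 0L
  if (ok) {
    state$occupancy[state$agents$site_dv[i], state$agents$site_ax[i]] <- 0L
    state$occupancy[tx, ty] <- state$agents$agent_id[i]
    state$agents$site_dv[i] <- tx
    state$agents$site_ax[i] <- ty
  }
  list(state = state, executed = ok)
}

#' @rdname attempt_move
#' @export
attempt_proliferate <- function(state, agent_id, direction) {
  i <- match(agent_id, state$agents$agent_id)
  if (is.na(i)) stop("unknown agent id: ", agent_id, call. = FALSE)
  d <- dir_offsets(direction)
  tx <- state$agents$site_dv[i] + d[1]
  ty <- state$agents$site_ax[i] + d[2]
  ok <- tx >= 1L && tx <= state$n_sites_dv &&
    ty >= 1L && ty <= state$n_sites_axial &&
    state$occupancy[tx, ty] == 0L
  if (ok) {
    child <- state$agents[i, ]
    child$agent_id <- max(state$agents$agent_id) + 1L
    child$site_dv <- tx
    child$site_ax <- ty
    state$agents <- dplyr::bind_rows(state$agents, child)
    state$occupancy[tx, ty] <- child$agent_id
  }
  list(state = state, executed = ok)
}

#' Pushing domain growth
#'
#' `grow_dorsoventral()` inserts one new empty site into every axial row at
#' an independently, uniformly chosen dorsoventral index; the contents at and
#' beyond that index shift one site ventrally, agents moving with their
#' sites, so the dorsoventral extent increases by one and no agent is created
#' or destroyed. `grow_axial()` is the mirror image (one new empty site per
#' dorsoventral column). Pass `insert_at` to make the insertion positions
#' deterministic (one index per row/column, each in `1..L`).
#'
#' @param state A `domain_state`.
#' @param insert_at Optional integer vector of insertion indices, one per
#'   axial row (`grow_dorsoventral`) or per dorsoventral column
#'   (`grow_axial`); drawn uniformly at random when `NULL`.
#' @return The grown `domain_state`.
#' @export
grow_dorsoventral <- function(state, insert_at = NULL) {
  Lx <- state$n_sites_dv
  Ly <- state$n_sites_axial
  if (is.null(insert_at)) insert_at <- sample.int(Lx, Ly, replace = TRUE)
  if (length(insert_at) != Ly || any(insert_at < 1L | insert_at > Lx))
    stop("`insert_at` needs one index in 1..L_x per axial row", call. = FALSE)
  ag <- state$agents
  shift <- ag$site_dv >= insert_at[ag$site_ax]
  ag$site_dv[shift] <- ag$site_dv[shift] + 1L
  domain_state(Lx + 1L, Ly, ag, state$time_min)
}

#' @rdname grow_dorsoventral
#' @export
grow_axial <- function(state, insert_at = NULL) {
  Lx <- state$n_sites_dv
  Ly <- state$n_sites_axial
  if (is.null(insert_at)) insert_at <- sample.int(Ly, Lx, replace = TRUE)
  if (length(insert_at) != Lx || any(insert_at < 1L | insert_at > Ly))
    stop("`insert_at` needs one index in 1..L_y per dorsoventral column",
         call. = FALSE)
  ag <- state$agents
  shift <- ag$site_ax >= insert_at[ag$site_dv]
  ag$site_ax[shift] <- ag$site_ax[shift] + 1L
  domain_state(Lx, Ly + 1L, ag, state$time_min)
}
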