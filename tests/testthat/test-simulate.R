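test_that("zero rates leave the initial state untouched and flag early stop", {
  p <- sim_params(move_rate_per_min = 0, proliferation_rate_per_min = 0,
                  growth_rate_axial_per_min = 0, growth_rate_dv_per_min = 0,
                  duration_min = 500, rng_seed = 1)
  sim <- simulate_colonization(p)
  expect_true(sim$early_stop)
  init <- dplyr::filter(sim$snapshots, time_min == 0)
  fin <- sim$final_state$agents
  expect_equal(fin$site_dv, init$site_dv)
  expect_equal(fin$site_ax, init$site_ax)
  expect_equal(sim$final_state$n_sites_dv, 31L)
})

test_that("identical seed and parameters give bit-identical realizations", {
  p <- quick_params(seed = 99)
  times <- seq(0, 200, by = 50)
  a <- simulate_colonization(p, sample_times = times)
  b <- simulate_colonization(p, sample_times = times)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$final_state$agents, b$final_state$agents)
  expect_identical(a$counts, b$counts)
  c <- simulate_colonization(sim_params(duration_min = 200, rng_seed = 100),
                             sample_times = times)
  expect_false(identical(a$final_state$agents, c$final_state$agents))
})

test_that("exclusion, containment and monotone growth hold along a run", {
  p <- sim_params(duration_min = 1500, rng_seed = 5)
  sim <- simulate_colonization(p, sample_times = seq(0, 1500, by = 150))
  snaps <- split(sim$snapshots, sim$snapshots$time_min)
  n_prev <- 0
  lx_prev <- 0
  for (s in snaps) {
    expect_no_site_clash(s)
    expect_true(all(s$site_dv >= 1 & s$site_dv <= s$n_sites_dv[1]))
    expect_true(all(s$site_ax >= 1 & s$site_ax <= s$n_sites_axial[1]))
    expect_gte(nrow(s), n_prev)            # no death process
    expect_gte(s$n_sites_dv[1], lx_prev)   # domain never shrinks
    n_prev <- nrow(s)
    lx_prev <- s$n_sites_dv[1]
  }
  # final agent count is the founder count plus executed divisions
  expect_equal(nrow(sim$final_state$agents),
               21 + sim$counts$proliferate_exec)
})

test_that("the event log is time-ordered and matches the tallies", {
  p <- sim_params(duration_min = 300, rng_seed = 11)
  sim <- simulate_colonization(p, record_events = TRUE)
  ev <- sim$events
  expect_true(all(diff(ev$time_min) >= 0))
  expect_equal(sum(ev$kind == "move" & ev$executed), sim$counts$move_exec)
  expect_equal(sum(ev$kind == "move" & !ev$executed), sim$counts$move_abort)
  expect_equal(sum(ev$kind == "proliferate" & ev$executed),
               sim$counts$proliferate_exec)
  expect_equal(sum(ev$kind == "grow_dv"), sim$counts$grow_dv)
  # executed moves are unit steps in one of four directions
  mv <- dplyr::filter(ev, kind == "move", executed)
  step <- abs(mv$x2 - mv$x1) + abs(mv$y2 - mv$y1)
  expect_true(all(step == 1))
  # the simulator is isotropic: executed low-density moves spread evenly
  # over the four directions
  dirs <- paste(mv$x2 - mv$x1, mv$y2 - mv$y1)
  expect_gt(stats::chisq.test(table(dirs))$p.value, 0.01)
})

test_that("domain growth events are Poisson with the configured rates", {
  # movement/proliferation off isolates the growth process
  p <- sim_params(move_rate_per_min = 0, proliferation_rate_per_min = 0,
                  duration_min = 7200, n_founders = 1)
  counts <- t(sapply(1:40, function(r) {
    p$rng_seed <- 2000 + r
    sim <- simulate_colonization(p)
    c(dv = sim$counts$grow_dv, ax = sim$counts$grow_ax,
      lx = sim$final_state$n_sites_dv, ly = sim$final_state$n_sites_axial)
  }))
  m_dv <- 0.0246 * 7200   # 177.1 expected insertions
  m_ax <- 0.00526 * 7200  # 37.9
  expect_lt(abs(mean(counts[, "dv"]) - m_dv), 3 * sqrt(m_dv / 40))
  expect_lt(abs(mean(counts[, "ax"]) - m_ax), 3 * sqrt(m_ax / 40))
  # mean-field linear growth of the lattice extents
  expect_lt(abs(mean(counts[, "lx"]) - (31 + m_dv)), 3 * sqrt(m_dv / 40))
  expect_lt(abs(mean(counts[, "ly"]) - (43 + m_ax)), 3 * sqrt(m_ax / 40))
})

test_that("sparse populations double exponentially at the attempt rate", {
  # 21 well-separated founders, no domain growth, 14 h: mean-field
  # prediction 21 * 2^(14/7) = 84 agents with negligible crowding
  p <- sim_params(growth_rate_axial_per_min = 0, growth_rate_dv_per_min = 0,
                  initial_sites_dv = 150, initial_sites_axial = 150,
                  duration_min = 840)
  n_final <- sapply(1:60, function(r) {
    p$rng_seed <- 3000 + r
    nrow(simulate_colonization(p, init_state = sparse_init())$final_state$agents)
  })
  # Yule-process variance per founder: 2^t'(2^t' - 1) with t' = 2 doublings
  se <- sqrt(21 * 4 * 3 / 60)
  expect_lt(abs(mean(n_final) - 84), 3 * se + 2) # +2 for residual crowding
})

test_that("rare-clone marking is heritable and bounded by the mark time", {
  # mark at the final instant: exactly one agent carries the mark
  p <- sim_params(duration_min = 300, rng_seed = 21)
  sim <- simulate_colonization(p, scenario = "rare_clone", mark_time = 300)
  expect_equal(sum(sim$final_state$agents$rare_mark), 1L)
  expect_equal(sim$marked_at, 300)
  # mark the single founder at t = 0: every descendant carries the mark
  p2 <- sim_params(move_rate_per_min = 0,
                   growth_rate_axial_per_min = 0, growth_rate_dv_per_min = 0,
                   initial_sites_dv = 60, initial_sites_axial = 60,
                   duration_min = 840, n_founders = 1, rng_seed = 22)
  init <- domain_state(60, 60, tibble::tibble(
    agent_id = 1L, lineage = 1L, colour = NA_integer_, rare_mark = 0L,
    site_dv = 30L, site_ax = 30L
  ))
  sim2 <- simulate_colonization(p2, scenario = "rare_clone",
                                init_state = init, mark_time = 0)
  expect_gt(nrow(sim2$final_state$agents), 1L)
  expect_true(all(sim2$final_state$agents$rare_mark == 1L))
  # marked agents all descend from the marked founder's lineage
  expect_equal(unique(sim2$final_state$agents$lineage), 1L)
  expect_error(
    simulate_colonization(p, scenario = "rare_clone", mark_time = 301),
    "mark_time"
  )
})

test_that("sample-time validation and snapshot bookkeeping work", {
  p <- quick_params()
  expect_error(simulate_colonization(p, sample_times = c(0, 500)),
               "sample_times")
  sim <- simulate_colonization(p, sample_times = c(100, 200))
  expect_equal(sort(unique(sim$snapshots$time_min)), c(0, 100, 200))
})
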