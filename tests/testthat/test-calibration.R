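test_that("a free agent diffuses at P_m * spacing^2 / 4 on the lattice", {
  # untruncated unwrapped walks are an exact 2D lattice walk: MSD slope
  # P_m * Delta^2, so D = P_m * Delta^2 / 4 = 72.2 um^2/min at the default
  set.seed(31)
  tracks <- purrr::map_dfr(1:80, function(r) {
    s <- periodic_run(1, duration_min = 400, truncate_at_wrap = FALSE)
    dplyr::mutate(s$tracks, track_id = r)
  })
  d_hat <- fit_diffusion(msd_time_ensemble(tracks))$D_um2_per_min
  expect_lt(abs(d_hat - 72.2) / 72.2, 0.05)
})

test_that("field-of-view truncation biases the fitted D downwards, not up", {
  set.seed(32)
  tr_cut <- purrr::map_dfr(1:60, function(r) {
    s <- periodic_run(1, duration_min = 400, truncate_at_wrap = TRUE)
    dplyr::mutate(s$tracks, track_id = r)
  })
  d_cut <- fit_diffusion(msd_time_ensemble(tr_cut))$D_um2_per_min
  expect_lt(d_cut, 72.2)
  expect_gt(d_cut, 0.7 * 72.2)
})

test_that("the density sweep conserves agents and hits the exact endpoints", {
  # a fully occupied periodic lattice can never execute a move
  tab <- periodic_density_sweep(densities = 289, reps = 3, base_seed = 41)
  expect_equal(tab$D_um2_per_min, 0)
  expect_equal(tab$density_cells_per_mm2, 289 / (17 * 0.038)^2)
  # move-only dynamics keep the agent count constant
  set.seed(42)
  s <- periodic_run(60, duration_min = 200)
  expect_equal(nrow(s$final_state$agents), 60L)
  expect_equal(s$counts$proliferate_exec, 0)
  expect_error(periodic_density_sweep(densities = integer(0)), "positive")
  expect_error(periodic_density_sweep(densities = 300), "exceeds")
})

test_that("crowding slows diffusion monotonically", {
  tab <- periodic_density_sweep(densities = c(20, 150, 270), reps = 12,
                                base_seed = 43)
  expect_true(all(diff(tab$D_um2_per_min) < 0))
  # bracketing: 0 <= D(rho) <= free-walk value
  expect_true(all(tab$D_um2_per_min >= 0))
  expect_true(all(tab$D_um2_per_min <= 72.2))
})

test_that("movement-rate fitting recovers the generating rate", {
  tab <- gen_density_D_table(true_pm = 0.2, densities = c(30, 120),
                             reps = 10, seed = 51)
  fit <- fit_movement_rate(tab, pm_grid = c(0.1, 0.2, 0.4), reps = 10,
                           base_seed = 61)
  expect_equal(fit$P_m, 0.2)
  # measurement noise of a few um^2/min still lands within 10% of the truth
  noisy <- gen_density_D_table(true_pm = 0.2, densities = c(30, 100, 200),
                               reps = 15, noise_sd = 2, seed = 52)
  fit2 <- fit_movement_rate(noisy, pm_grid = c(0.1, 0.15, 0.2, 0.25, 0.4),
                            reps = 15, base_seed = 62)
  expect_lt(abs(fit2$P_m - 0.2) / 0.2, 0.1)
  # degenerate two-point table still returns a well-defined grid point
  tiny <- tibble::tibble(density_cells_per_mm2 = c(100, 500),
                         D_um2_per_min = c(50, 10))
  fit3 <- fit_movement_rate(tiny, pm_grid = c(0.1, 0.2), reps = 5,
                            base_seed = 63)
  expect_true(fit3$P_m %in% c(0.1, 0.2))
  expect_error(fit_movement_rate(tiny[0, ], pm_grid = 0.1), "empty")
})

test_that("the effective cell cycle lengthens with density", {
  tab <- emergent_cell_cycle(densities = c(10, 150, 250), reps = 40,
                             base_seed = 71)
  # near-zero density: the exponential-clock value 1/P_p = 606 min
  # (40 reps x ~10 agents give ~150+ divisions, so sampling error is small)
  expect_lt(abs(tab$T_c_min[1] - 420 / log(2)) / (420 / log(2)), 0.1)
  expect_true(all(diff(tab$T_c_min) > 0))
  # a full domain admits no division at all
  full <- emergent_cell_cycle(densities = 289, window_min = 60, reps = 2,
                              base_seed = 72)
  expect_true(full$undefined)
  expect_true(is.na(full$T_c_min))
})

test_that("proliferation success tracks free space when well mixed", {
  # mean-field: a division attempt succeeds with probability ~ (1 - rho);
  # short window (one tenth of a cycle) keeps the density almost constant
  for (rho in c(0.1, 0.2)) {
    n <- round(rho * 51^2)
    exec <- abort <- 0
    for (r in 1:10) {
      set.seed(810 + 10 * rho * 10 + r)
      s <- periodic_run(n, proliferation_rate_per_min = log(2) / 420,
                        duration_min = 60, n_sites = 51)
      exec <- exec + s$counts$proliferate_exec
      abort <- abort + s$counts$proliferate_abort
    }
    succ <- exec / (exec + abort)
    expect_lt(abs(succ - (1 - rho)) / (1 - rho), 0.1)
  }
})

test_that("the doubling-time assay measures the attempt-rate doubling time", {
  da <- doubling_time_assay(reps = 40, base_seed = 91)
  expect_lt(abs(da$doubling_time_h - 7) / 7, 0.05)
  # doubling the rate halves the doubling time
  da2 <- doubling_time_assay(proliferation_rate_per_min = 2 * log(2) / 420,
                             reps = 40, base_seed = 92)
  expect_lt(abs(da2$doubling_time_h - 3.5) / 3.5, 0.05)
  expect_error(doubling_time_assay(proliferation_rate_per_min = 0, reps = 5,
                                   base_seed = 93),
               "did not grow")
})
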