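test_that("clonal signal averages colour values over each axial row", {
  # fully occupied single-colour grid
  all_plus <- gen_striped_grid(4, 8, n_stripes = 1)
  expect_true(all(clonal_signal(all_plus)$signal == 1))
  # empty lattice contributes zeros
  empty <- domain_state(4, 8)
  expect_true(all(clonal_signal(empty)$signal == 0))
  # alternating full rows of +1 / -1
  alt <- gen_striped_grid(4, 4, n_stripes = 4)
  expect_equal(clonal_signal(alt)$signal, c(1, -1, 1, -1))
  # unlabelled or >2-colour states are rejected
  st <- diag3_state()
  expect_error(clonal_signal(st), "colour label")
  st$agents$colour <- c(1L, 2L, 3L)
  st2 <- domain_state(3, 3, st$agents)
  expect_error(clonal_signal(st2), "two colours")
})

test_that("spectrum amplitudes follow the two-sided DFFT convention", {
  n <- 64
  sig <- cos(2 * pi * 3 * (0:(n - 1)) / n)
  sp <- stripe_intensity(sig)
  expect_equal(sp$dominant_frequency, 3 / n)
  expect_equal(sp$stripe_intensity, 0.5, tolerance = 1e-10)
  # constant signal has no non-zero-frequency power
  flat <- stripe_intensity(rep(0.7, 32))
  expect_lt(flat$stripe_intensity, 1e-12)
  # Parseval: sum of squared amplitudes over all frequencies (incl. DC)
  # equals the mean squared signal
  set.seed(8)
  s <- stats::rnorm(50)
  spr <- stripe_intensity(s)
  expect_equal(sum(spr$full_spectrum$amplitude^2), mean(s^2))
  expect_error(stripe_intensity(c(1, -1, 1)), "length")
})

test_that("stripe intensity is invariant to a global colour swap", {
  set.seed(9)
  sigs <- replicate(5, stats::runif(40, -1, 1), simplify = FALSE)
  a <- stripe_intensity(sigs)
  b <- stripe_intensity(lapply(sigs, function(s) -s))
  expect_equal(a$stripe_intensity, b$stripe_intensity)
  expect_equal(a$dominant_frequency, b$dominant_frequency)
})

test_that("striped grids put their power at the block frequency", {
  # two stripes across 40 axial sites: square wave of period 40
  g2 <- stripe_intensity(clonal_signal(gen_striped_grid(5, 40, 2)))
  expect_equal(g2$dominant_frequency, 1 / 40)
  expect_equal(g2$stripe_intensity, 2 / pi, tolerance = 0.02)
  # alternating rows: power at the Nyquist frequency
  gn <- stripe_intensity(clonal_signal(gen_striped_grid(5, 40, 40)))
  expect_equal(gn$dominant_frequency, 0.5)
  # replicate signals of different lengths are truncated before averaging
  mix <- stripe_intensity(list(stats::runif(45, -1, 1),
                               stats::runif(40, -1, 1)))
  expect_equal(mix$signal_length, 40)
})

test_that("lineage statistics rank clones and pool the top k", {
  ag <- tibble::tibble(
    agent_id = 1:100, lineage = rep(c(1L, 2L, 3L), c(50, 30, 20)),
    colour = NA_integer_, rare_mark = 0L,
    site_dv = rep(1:10, 10), site_ax = rep(1:10, each = 10)
  )
  st <- domain_state(10, 10, ag)
  ls <- lineage_stats(st, k = 2)
  expect_equal(ls$top_k_share, 0.8)
  expect_equal(ls$clone_sizes$n, c(50, 30, 20))
  expect_equal(sum(ls$clone_sizes$n), ls$total)
  expect_equal(top_lineage_share(st, 3), 1)
  expect_error(lineage_stats(st, k = 4), "exceeds")
  # single founder owns the whole population
  single <- domain_state(2, 2, tibble::tibble(
    agent_id = 1L, lineage = 1L, colour = NA_integer_, rare_mark = 0L,
    site_dv = 1L, site_ax = 1L
  ))
  expect_equal(top_lineage_share(single, 1), 1)
})

test_that("belly spots are ventral-touching empty components above threshold", {
  # fully occupied: no spot, colonized
  full <- gen_striped_grid(6, 6, 2)
  bs <- belly_spot(full)
  expect_false(bs$present)
  expect_equal(bs$area_sites, 0L)
  expect_true(colonization_status(full))
  # 3 x 4 empty block touching the ventral edge: 12 sites = 17,328 um^2
  ag <- full$agents[!(full$agents$site_dv >= 4 & full$agents$site_ax <= 4), ]
  holed <- domain_state(6, 6, ag)
  bs2 <- belly_spot(holed)
  expect_true(bs2$present)
  expect_equal(bs2$area_sites, 12L)
  expect_equal(bs2$area_um2, 12 * 38^2)
  expect_false(colonization_status(holed))
  # interior holes do not count as belly spots
  ag3 <- full$agents[!(full$agents$site_dv %in% 2:4 &
                         full$agents$site_ax %in% 2:4), ]
  interior <- domain_state(6, 6, ag3)
  expect_false(belly_spot(interior)$present)
  # sub-threshold ventral nicks are ignored
  ag4 <- full$agents[!(full$agents$site_dv == 6 & full$agents$site_ax <= 3), ]
  nick <- domain_state(6, 6, ag4)
  expect_false(belly_spot(nick, min_area_sites = 5)$present)
  expect_true(belly_spot(nick, min_area_sites = 3)$present)
})
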