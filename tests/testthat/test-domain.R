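test_that("init_domain builds the empty embryonic lattice", {
  d <- init_domain(sim_params())
  expect_equal(d$n_sites_dv, 31L)
  expect_equal(d$n_sites_axial, 43L)
  expect_equal(d$time_min, 0)
  expect_equal(nrow(d$agents), 0L)
  expect_true(all(d$occupancy == 0L))
  # degenerate single-site world is valid
  d1 <- init_domain(sim_params(initial_sites_dv = 1, initial_sites_axial = 1,
                               n_founders = 1))
  expect_equal(dim(d1$occupancy), c(1L, 1L))
})

test_that("domain_state enforces exclusion and containment", {
  ag <- tibble::tibble(agent_id = 1:2, lineage = 1:2, colour = NA_integer_,
                       rare_mark = 0L, site_dv = c(1L, 1L), site_ax = c(1L, 1L))
  expect_error(domain_state(3, 3, ag), "exclusion")
  ag$site_ax <- c(1L, 9L)
  expect_error(domain_state(3, 3, ag), "outside")
})

test_that("founder placement follows the weighted embryonic distribution", {
  set.seed(42)
  draws <- do.call(rbind, lapply(1:500, function(i) {
    sample_founders(sim_params())$agents
  }))
  expect_equal(nrow(draws), 500 * 21)
  # one-third of axial positions in the mid-trunk band 12..32
  frac_mid <- mean(draws$site_ax >= 12 & draws$site_ax <= 32)
  expect_lt(abs(frac_mid - 1 / 3), 0.02)
  # all dorsoventral positions in 8..19, ~95% in 8..17
  expect_true(all(draws$site_dv >= 8 & draws$site_dv <= 19))
  expect_lt(abs(mean(draws$site_dv <= 17) - 0.95), 0.02)
  # founders occupy distinct sites and carry lineage labels 1..21
  one <- sample_founders(sim_params())
  expect_no_site_clash(one$agents)
  expect_equal(sort(one$agents$lineage), 1:21)
})

test_that("a single founder gets lineage label 1", {
  set.seed(7)
  d <- sample_founders(sim_params(n_founders = 1))
  expect_equal(nrow(d$agents), 1L)
  expect_equal(d$agents$lineage, 1L)
})

test_that("founder placement demands a large enough lattice", {
  expect_error(sample_founders(sim_params(initial_sites_dv = 10)),
               "too small")
  expect_error(sample_founders(sim_params(initial_sites_axial = 20)),
               "too small")
})

test_that("moves relocate into free sites and abort otherwise", {
  st <- domain_state(10, 10, tibble::tibble(
    agent_id = 1:2, lineage = 1:2, colour = NA_integer_, rare_mark = 0L,
    site_dv = c(5L, 5L), site_ax = c(5L, 6L)
  ))
  # free target
  r <- attempt_move(st, 1L, "+dv")
  expect_true(r$executed)
  expect_equal(r$state$agents$site_dv[1], 6L)
  expect_equal(r$state$occupancy[5, 5], 0L)
  expect_equal(r$state$occupancy[6, 5], 1L)
  # occupied target aborts and leaves the state untouched
  r2 <- attempt_move(st, 1L, "+ax")
  expect_false(r2$executed)
  expect_identical(r2$state$agents, st$agents)
  # off-lattice attempt aborts (zero-flux boundary)
  edge <- domain_state(3, 3, tibble::tibble(
    agent_id = 1L, lineage = 1L, colour = NA_integer_, rare_mark = 0L,
    site_dv = 1L, site_ax = 2L
  ))
  r3 <- attempt_move(edge, 1L, "-dv")
  expect_false(r3$executed)
  expect_error(attempt_move(st, 99L, "+dv"), "unknown agent")
})

test_that("proliferation creates inheriting progeny only into free sites", {
  st <- domain_state(5, 5, tibble::tibble(
    agent_id = 1L, lineage = 7L, colour = -1L, rare_mark = 1L,
    site_dv = 3L, site_ax = 3L
  ))
  r <- attempt_proliferate(st, 1L, "+ax")
  expect_true(r$executed)
  expect_equal(nrow(r$state$agents), 2L)
  child <- r$state$agents[2, ]
  expect_equal(child$lineage, 7L)   # lineage label inherited
  expect_equal(child$colour, -1L)   # colour inherited
  expect_equal(child$rare_mark, 1L) # rare mark inherited
  # fully surrounded agent cannot place progeny anywhere
  ag <- tibble::tibble(
    agent_id = 1:5, lineage = 1:5, colour = NA_integer_, rare_mark = 0L,
    site_dv = c(3L, 2L, 4L, 3L, 3L), site_ax = c(3L, 3L, 3L, 2L, 4L)
  )
  blocked <- domain_state(5, 5, ag)
  for (dir in c("+dv", "-dv", "+ax", "-ax")) {
    expect_false(attempt_proliferate(blocked, 1L, dir)$executed)
  }
})

test_that("pushing growth inserts empty sites and carries contents", {
  st <- diag3_state()
  # dorsoventral growth with fixed insertion columns per axial row
  g <- grow_dorsoventral(st, insert_at = c(2L, 1L, 3L))
  expect_equal(g$n_sites_dv, 4L)
  expect_equal(g$n_sites_axial, 3L)
  # row 1: agent at dv 1 < 2 stays; row 2: agent at dv 2 >= 1 shifts to 3;
  # row 3: agent at dv 3 >= 3 shifts to 4
  expect_equal(g$agents$site_dv, c(1L, 3L, 4L))
  expect_equal(g$agents$site_ax, 1:3)
  # inserted sites are empty
  expect_equal(g$occupancy[2, 1], 0L)
  expect_equal(g$occupancy[1, 2], 0L)
  expect_equal(g$occupancy[3, 3], 0L)
  # growth conserves the agents and their labels
  expect_equal(nrow(g$agents), 3L)
  expect_equal(sort(g$agents$lineage), sort(st$agents$lineage))
  # axial growth mirrors
  ga <- grow_axial(st, insert_at = c(1L, 3L, 2L))
  expect_equal(ga$n_sites_axial, 4L)
  # col 1: cut 1 shifts agent at ax 1 to 2; col 2: cut 3 leaves ax 2 in
  # place; col 3: cut 2 shifts ax 3 to 4
  expect_equal(ga$agents$site_ax, c(2L, 2L, 4L))
  expect_error(grow_dorsoventral(st, insert_at = c(1L, 9L, 1L)), "1..L_x")
})

test_that("the crowded Cheeseman initial condition is reproduced exactly", {
  d <- cheeseman_init()
  expect_equal(dim(d$occupancy), c(50L, 50L))
  expect_equal(nrow(d$agents), 500L)
  expect_true(all(d$agents$site_dv <= 10L))
  expect_true(all(d$occupancy[11:50, ] == 0L))
  expect_true(all(d$occupancy[1:10, ] > 0L))
  expect_equal(length(unique(d$agents$lineage)), 500L)
})

test_that("chimera labelling produces the requested colour classes", {
  set.seed(3)
  st <- sample_founders(sim_params())
  bal <- assign_chimera_labels(st)
  sizes <- sort(as.integer(table(bal$agents$colour)))
  expect_equal(sizes, c(10L, 11L))
  one <- assign_chimera_labels(st, balanced = FALSE, k = 1)
  expect_equal(sum(one$agents$colour == 1L), 1L)
  expect_equal(sum(one$agents$colour == -1L), 20L)
  uni <- assign_chimera_labels(st, n_colours = 21)
  expect_equal(uni$agents$colour, uni$agents$lineage)
  expect_error(assign_chimera_labels(st, n_colours = 22), "exceeds")
})
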