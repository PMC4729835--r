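# Shared fixtures built in code.

# Small fast parameter set for plumbing tests (short run, small lattice,
# growth on).
quick_params <- function(seed = 1, ...) {
  sim_params(duration_min = 200, rng_seed = seed, ...)
}

# A hand-built 3 x 3 state with three agents on the diagonal.
diag3_state <- function() {
  domain_state(3, 3, tibble::tibble(
    agent_id = 1:3, lineage = 1:3, colour = NA_integer_, rare_mark = 0L,
    site_dv = 1:3, site_ax = 1:3
  ))
}

# Lattice of founders spread far apart on a large growth-free domain, for
# low-crowding growth assays.
sparse_init <- function(n = 21, lattice = 150, spacing = 30) {
  side <- ceiling(sqrt(n))
  coord <- as.integer(seq(spacing / 2, by = spacing, length.out = side))
  pos <- expand.grid(site_dv = coord, site_ax = coord)[seq_len(n), ]
  domain_state(lattice, lattice, tibble::tibble(
    agent_id = seq_len(n), lineage = seq_len(n), colour = NA_integer_,
    rare_mark = 0L, site_dv = pos$site_dv, site_ax = pos$site_ax
  ))
}

expect_no_site_clash <- function(agents) {
  expect_equal(anyDuplicated(agents[c("site_dv", "site_ax")]), 0L)
}
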