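# Shared fixtures and independent oracles, built in code at test time.

# small stimulus (20 deg final size) keeps per-test rendering cheap
small_loom <- function() loom_params(l_over_v = 50, max_full_angle = 20)
small_grid <- function() coarse_grid(pixel_size = 2, azimuth_halfwidth = 14,
                                     elevation_halfwidth = 12)

# brute-force linear-sum-assignment oracle (exhaustive permutations, n <= 7)
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  rec <- function(row, used, acc) {
    if (acc >= best) return()
    if (row > n) {
      best <<- acc
      return()
    }
    for (j in which(!used)) {
      used[j] <- TRUE
      rec(row + 1, used, acc + cost[row, j])
      used[j] <- FALSE
    }
  }
  rec(1, rep(FALSE, n), 0)
  best
}

# single passive compartment: diameter/length chosen for round numbers
single_comp_model <- function(g_pas = 1e-4, diam = 50, len = 100) {
  m <- neuron_morphology(tibble::tibble(comp = 1, parent = 0,
                                        length_um = len, diam_um = diam,
                                        region = "trunk"))
  compartmental_model(m, passive_props(g_pas = g_pas),
                      channels = list(),
                      densities = default_densities()[0, ])
}

# unbranched passive cable of n segments
passive_cable_model <- function(n = 100, total_len = 2000, diam = 2,
                                passive = passive_props(g_pas = 1e-4,
                                                        ra = 200)) {
  m <- neuron_morphology(tibble::tibble(comp = seq_len(n),
                                        parent = 0:(n - 1),
                                        length_um = total_len / n,
                                        diam_um = diam, region = "trunk"))
  compartmental_model(m, passive, channels = list(),
                      densities = default_densities()[0, ])
}

# the desk-scale reference model used across tests
reference_model <- function(...) {
  compartmental_model(gen_toy_morphology("fan", n_branches = 12,
                                         comps_per_branch = 10, seed = 1),
                      ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
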