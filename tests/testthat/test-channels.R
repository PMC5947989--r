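test_that("Boltzmann curves respect midpoint, limits and monotonicity", {
  expect_equal(boltzmann(-77.6, -77.6, 13.34, "decreasing"), 0.5)
  expect_equal(boltzmann(-500, -77.6, 13.34, "decreasing"), 1, tolerance = 1e-9)
  expect_lt(boltzmann(100, -77.6, 13.34, "decreasing"), 1e-5)
  v <- seq(-120, 0, by = 1)
  expect_true(all(diff(hcn_steady_state(v)) < 0))
  expect_true(all(diff(boltzmann(v, -35, 5, "increasing")) > 0))
  expect_error(boltzmann(-60, -60, 0), "nonzero")
})

test_that("HCN resting activation at -65 mV is 28% of maximum", {
  expect_equal(hcn_steady_state(-65), 0.28, tolerance = 0.005)
  # g_max scales linearly
  expect_equal(hcn_steady_state(-65, g_max = 100),
               100 * hcn_steady_state(-65))
})

test_that("symmetric tau peaks at v_peak and is symmetric", {
  expect_equal(symmetric_tau(-83, 1340, 50, -83, 20), 1390)
  expect_equal(symmetric_tau(-73, 1340, 50, -83, 20),
               symmetric_tau(-93, 1340, 50, -83, 20))
  v <- seq(-150, 0, by = 1)
  tau <- symmetric_tau(v, 1340, 50, -83, 20)
  expect_true(all(tau > 50 & tau <= 1390))
  expect_equal(v[which.max(tau)], -83)
  # experimentally fitted curve gives ~985 ms at the resting potential
  expect_equal(hcn_tau(-65), 985, tolerance = 0.01)
})

test_that("exponential gate update is exact and stays bounded", {
  g <- gate_spec(1, v_half = -77.6, s = 13.34, direction = "decreasing",
                 tau = 100)
  v <- -90
  xinf <- loomsel:::gate_inf(g, v)
  # fixed point
  expect_equal(advance_gate(xinf, v, 5, g), xinf)
  # large dt converges to steady state
  expect_equal(advance_gate(0.1, v, 1e6, g), xinf, tolerance = 1e-9)
  # repeated small steps match the closed-form exponential
  x <- 0.9
  for (i in 1:200) x <- advance_gate(x, v, 0.5, g)
  analytic <- xinf + (0.9 - xinf) * exp(-100 / 100)
  expect_equal(x, analytic, tolerance = 1e-6)
  expect_true(x >= 0 && x <= 1)
})

test_that("ohmic current follows the conductance product convention", {
  expect_equal(channel_current(-35, 1, 50, -35), 0)
  expect_equal(channel_current(-50, 0, 50, -35), 0)
  # fully open 50 nS HCN at -95 mV: 50 * (-60) = -3000 pA = -3 nA inward
  expect_equal(channel_current(-95, 1, 50, -35), -3000)
  expect_equal(channel_current(-30, c(0.5, 0.5), 10, -80, powers = c(2, 1)),
               10 * 0.125 * 50)
})

test_that("default channel library carries the fitted kinetics and variants", {
  lib <- default_channel_library()
  expect_equal(lib$HCN$gates[[1]]$tau$tau_max, 1350)
  expect_equal(lib$HCN$gates[[1]]$v_half, -77.6)
  expect_equal(lib$HCN$e_rev, -35)
  expect_equal(lib$KD$gates[[2]]$tau$tau_max, 1050)
  # K_D-like peak inactivation time constant in the slow 0.3-2 s range
  kd <- lib$KD$gates[[2]]
  tau_peak <- loomsel:::gate_tau(kd, kd$tau$v_peak)
  expect_gte(tau_peak, 300)
  expect_lte(tau_peak, 2000)

  fast <- default_channel_library("fast")
  expect_equal(fast$HCN$gates[[1]]$tau$tau_max, 135)
  expect_equal(fast$KD$gates[[2]]$tau$tau_max, 105)
  slow <- default_channel_library("slow")
  expect_equal(slow$HCN$gates[[1]]$tau$tau_max, 13500)
  expect_equal(slow$KD$gates[[2]]$tau$tau_max, 10500)
  expect_error(default_channel_library("medium"))

  # all steady states bounded in [0, 1]; dendrites carry no fast Na+
  v <- seq(-120, 20, by = 2)
  for (ch in lib) for (g in ch$gates) {
    if (g$kind == "voltage") {
      x <- loomsel:::gate_inf(g, v)
      expect_true(all(x >= 0 & x <= 1))
    }
  }
  dens <- default_densities()
  expect_false(any(dens$channel == "Na" &
                     dens$region %in% c("fieldA", "fieldB", "fieldC")))
})
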