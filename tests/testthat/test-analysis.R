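test_that("sag measurement follows the peak-to-steady-state definition", {
  t <- seq(0, 1500, by = 1)
  v <- -65 - 35 * (1 - exp(-t / 30)) + 10 * (1 - exp(-t / 200))
  tr <- tibble::tibble(time_ms = t, v_mV = v)
  sg <- sag_measure(tr, 0, 1500)
  # dips toward -100, relaxes toward -90: sag close to 10 mV
  expect_equal(sg$sag_amplitude_mV, 10, tolerance = 0.8)
  expect_true(sg$converged)
  # pure exponential relaxation recovers its time constant
  t2 <- seq(0, 2000, by = 1)
  v2 <- -90 - 10 * exp(-t2 / 200)
  sg2 <- sag_measure(tibble::tibble(time_ms = t2, v_mV = v2), 0, 2000)
  expect_equal(sg2$sag_tau_ms, 200, tolerance = 1 / 200)
  expect_error(sag_measure(tr, 5000, 6000), "window")
})

test_that("membrane time constant uses the 0.5-13 ms window", {
  t <- seq(0, 50, by = 0.05)
  v <- -65 - 5 * (1 - exp(-t / 8))
  expect_equal(membrane_tau(tibble::tibble(time_ms = t, v_mV = v), 0), 8,
               tolerance = 1e-3)
  # bi-exponential dominated by the fast component: estimate lies between
  v2 <- -65 - 4 * (1 - exp(-t / 5)) - 1 * (1 - exp(-t / 60))
  tau2 <- membrane_tau(tibble::tibble(time_ms = t, v_mV = v2), 0)
  expect_gt(tau2, 5)
  expect_lt(tau2, 60)
  expect_lt(abs(tau2 - 5), abs(tau2 - 60))
  expect_error(membrane_tau(tibble::tibble(time_ms = t[t < 10],
                                           v_mV = v[t < 10]), 0), "13 ms")
})

test_that("HCN conductance-difference relation is applied correctly", {
  # g(v1) = 28 nS, g(v2) = 78.65 nS, v2 = -95, E_H = -35:
  # DeltaI_H = (78.65 - 28) nS * (-60 mV) = -3039 pA ~ -3.04 nA
  g1 <- 28; g2 <- 78.65; v2 <- -95; e_h <- -35
  delta_i_nA <- (g2 - g1) * (v2 - e_h) / 1000
  expect_equal(delta_i_nA, -3.039, tolerance = 1e-3)
  # a synthetic exponential current with that amplitude is recovered
  t <- seq(0, 1500, by = 1)
  tau <- 800
  i <- (0.5 + delta_i_nA * (1 - exp(-t / tau)))
  d <- tibble::tibble(step = 1, time_ms = t, i_nA = i, v1 = -65, v2 = v2)
  fit <- suppressWarnings(fit_hcn_activation(d))
  expect_equal(fit$per_step$delta_i_nA, delta_i_nA, tolerance = 1e-6)
  expect_equal(fit$per_step$tau_ms, tau, tolerance = 1e-3)
  expect_equal(fit$per_step$dg_nS, g2 - g1, tolerance = 1e-3)
})

test_that("noiseless clamp data recovers the generating Boltzmann", {
  d <- gen_clamp_dataset()
  fit <- fit_hcn_activation(d)
  truth <- attr(d, "truth")
  expect_rel_equal(fit$g_max_nS, truth$g_max_nS, 0.02)
  expect_rel_equal(fit$v_half_mV, truth$v_half, 0.02)
  expect_rel_equal(fit$s_mV, truth$s, 0.02)
  expect_gt(fit$r_squared, 0.999)
  expect_false(fit$flagged)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
})

test_that("absent HCN conductance yields a flagged near-zero fit", {
  truth <- list(g_max_nS = 0, v_half = -77.6, s = 13.34, tau_max = 1340,
                tau_min = 50, v_peak = -83, steepness = 20, e_h = -35,
                g_leak_nS = 50, e_leak = -65)
  d <- gen_clamp_dataset(truth = truth)
  fit <- suppressWarnings(fit_hcn_activation(d))
  expect_lt(abs(fit$g_max_nS), 1)
  expect_true(fit$flagged)
  expect_true(all(abs(fit$per_step$delta_i_nA) < 1e-9))
})

test_that("HCN time-constant curve is recovered from per-step fits", {
  d <- gen_clamp_dataset(v_steps = seq(-70, -115, by = -7.5),
                         duration_ms = 3000)
  per <- fit_hcn_activation(d)$per_step
  fit <- fit_hcn_tau(tibble::tibble(v_mV = per$v2, tau_ms = per$tau_ms),
                     tau_min = 50)
  expect_rel_equal(fit$tau_max_ms, 1340, 0.02)
  expect_rel_equal(fit$v_peak_mV, -83, 0.02)
  expect_rel_equal(fit$steepness_mV, 20, 0.05)
})

test_that("sEPSP waveform peaks at tau1 * log(1 + tau2/tau1)", {
  tpk <- 0.3 * log(1 + 3 / 0.3)
  expect_equal(tpk, 0.719, tolerance = 1e-3)
  t <- seq(0, 20, by = 1e-4)
  i <- sepsp_current(t, A = 2)
  expect_equal(t[which.max(i)], tpk, tolerance = 1e-3)
  expect_equal(sepsp_current(-1), 0)
})

test_that("sEPSP summation matches linear superposition on an RC membrane", {
  # passive RC membrane, tau_m = 25 ms: convolve the current train with the
  # exponential kernel as an independent oracle
  tau_m <- 25; R <- 10
  dt <- 0.02
  t <- seq(0, 400, by = dt)
  pulses <- 100 + (0:4) * 10
  i <- rowSums(vapply(pulses, function(p) sepsp_current(t - p, A = 0.5),
                      numeric(length(t))))
  kern <- exp(-t / tau_m)
  v <- -65 + (R / tau_m) * stats::convolve(i, rev(kern), type = "open")[
    seq_along(t)] * dt
  tr <- tibble::tibble(time_ms = t, v_mV = v)
  s <- sepsp_summation(tr, pulses)
  # superposition oracle: peaks measured from the analytic trace directly
  p1 <- max(v[t >= pulses[1] & t < pulses[2]]) + 65
  p5 <- max(v[t >= pulses[5] & t < pulses[5] + 10]) + 65
  expect_equal(s$summation, (p5 - p1) / p1, tolerance = 1e-9)
  expect_gt(s$summation, 0)

  # widely spaced pulses on the same membrane barely summate
  far <- 50 + (0:4) * 200
  i2 <- rowSums(vapply(far, function(p) sepsp_current(seq(0, 1200, dt) - p,
                                                      A = 0.5),
                       numeric(length(seq(0, 1200, dt)))))
  t2 <- seq(0, 1200, dt)
  v2 <- -65 + (R / tau_m) * stats::convolve(i2, rev(exp(-t2 / tau_m)),
                                            type = "open")[seq_along(t2)] * dt
  s2 <- sepsp_summation(tibble::tibble(time_ms = t2, v_mV = v2), far)
  expect_lt(abs(s2$summation), 0.01)
  expect_error(sepsp_summation(tr, pulses[1:3]), "five")
})

test_that("normalized integral equals resistance for steady current", {
  t <- seq(0, 5000, by = 1)
  R <- 12
  tr <- tibble::tibble(time_ms = t,
                       v_mV = -65 + 0.5 * R * (1 - exp(-t / 10)),
                       i_nA = 0.5)
  expect_equal(normalized_integral(tr), R, tolerance = 0.01)
  # linearity: doubling the current leaves the ratio unchanged
  tr2 <- tr; tr2$v_mV <- -65 + (tr$v_mV + 65) * 2; tr2$i_nA <- 1
  expect_equal(normalized_integral(tr2), normalized_integral(tr))
  expect_error(normalized_integral(tibble::tibble(time_ms = t,
                                                  v_mV = -65, i_nA = 0)),
               "charge")
})

test_that("firing rate kernel integrates to the spike count", {
  expect_true(all(firing_rate(numeric(0), c(0, 100))$rate_spk_s == 0))
  fr1 <- firing_rate(500, t_range = c(0, 1000))
  expect_equal(max(fr1$rate_spk_s), 1000 / (20 * sqrt(2 * pi)),
               tolerance = 1e-6)
  expect_equal(max(fr1$rate_spk_s), 19.95, tolerance = 1e-3)
  set.seed(7)
  spikes <- sort(runif(40, 200, 800))
  fr <- firing_rate(spikes, t_range = c(-200, 1200))
  expect_equal(sum(fr$rate_spk_s) * 1 / 1000, 40, tolerance = 1e-4)
  rm <- response_metrics(spikes, c(0, 1000))
  expect_equal(rm$spike_count, 40L)
})

test_that("coherence preference is the OLS slope of count vs coherence", {
  d <- tibble::tibble(coherence = c(0, 50, 100), spike_count = c(10, 20, 30))
  cp <- suppressWarnings(coherence_preference(d))  # exact fit is intended
  expect_equal(cp$slope, 0.2)
  expect_equal(cp$pearson_r, 1)
  d2 <- tibble::tibble(coherence = c(0, 50, 100), spike_count = c(7, 7, 7))
  expect_equal(suppressWarnings(coherence_preference(d2))$slope, 0)
  expect_error(coherence_preference(
    tibble::tibble(coherence = c(5, 5, 5), spike_count = 1:3)))
  expect_error(coherence_preference(
    tibble::tibble(coherence = c(0, 100), spike_count = 1:2)), "three")
  gl <- glance(cp)
  expect_named(gl, c("slope", "slope_se", "pearson_r", "p_value", "n"))
})

test_that("sustained/transient split finds the longest supra-threshold run", {
  # all 10 ms ISIs (100 spk/s): everything sustained
  s1 <- sustained_transient_split(seq(0, 90, by = 10))
  expect_equal(s1$sustained, 10L)
  expect_equal(s1$transient, 0L)
  # all 100 ms ISIs (10 spk/s): everything transient
  s2 <- sustained_transient_split(seq(0, 900, by = 100))
  expect_equal(s2$sustained, 0L)
  expect_equal(s2$transient, 10L)
  # 5 fast spikes, a 1 s gap, 5 slow spikes
  train <- c(seq(0, 40, by = 10), 1040 + seq(0, 400, by = 100))
  s3 <- sustained_transient_split(train)
  expect_equal(s3$sustained, 5L)
  expect_equal(s3$transient, 5L)
  # counts always add to the total (property over random trains)
  set.seed(3)
  for (i in 1:20) {
    tr <- cumsum(stats::rexp(sample(2:60, 1), rate = 1 / 40))
    s <- sustained_transient_split(tr)
    expect_equal(s$sustained + s$transient, length(tr))
  }
})

test_that("responses normalize to each unit's control maximum", {
  d <- tibble::tibble(animal = rep(c("a", "b"), each = 4),
                      condition = rep(c("control", "control", "drug", "drug"),
                                      2),
                      spike_count = c(2, 4, 3, 1, 10, 20, 30, 5))
  nr <- normalize_responses(d)
  expect_equal(nr$normalized[nr$animal == "a"], c(0.5, 1, 0.75, 0.25))
  expect_equal(nr$normalized[nr$animal == "b"], c(0.5, 1, 1.5, 0.25))
  # relative drug change reproduces (control - drug)/drug on raw or
  # normalized values identically
  a_ctrl <- max(d$spike_count[d$animal == "a" & d$condition == "control"])
  raw_change <- (4 - 1) / 1
  norm_change <- (1 - 0.25) / 0.25
  expect_equal(raw_change, norm_change)
  expect_error(normalize_responses(
    tibble::tibble(animal = "a", condition = "drug", spike_count = 1)),
    "control")
})
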