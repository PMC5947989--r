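test_that("single passive compartment matches the RC closed form", {
  mod <- single_comp_model()
  area <- pi * 100 * 50 * 1e-8
  R <- 1 / (1e-4 * area * 1e6)            # MOhm
  tau <- 10                                # Rm * Cm, ms
  sim <- simulate_model(mod, 80, dt = 0.025, settle_ms = 200,
                        iclamp = data.frame(comp = 1, onset_ms = 0,
                                            duration_ms = 80, amp_nA = -0.1),
                        record_comps = 1, record_every_ms = 0.1,
                        spike_comp = NULL)
  v <- sim$voltage
  analytic <- -65 - 0.1 * R * (1 - exp(-v$time_ms / tau))
  expect_lt(max(abs(v$v_mV - analytic)) / (0.1 * R), 0.005)
})

test_that("sealed-end cable attenuation matches 1/cosh within 1%", {
  n <- 100
  L <- 2000
  mod <- passive_cable_model(n = n, total_len = L, diam = 2)
  lam <- loomsel:::lambda_um(2, mod$passive)
  sim <- simulate_model(mod, 500, dt = 0.05, settle_ms = 200,
                        iclamp = data.frame(comp = 1, onset_ms = 0,
                                            duration_ms = 500, amp_nA = 0.05),
                        record_comps = c(1, n), record_every_ms = 1,
                        spike_comp = NULL)
  v <- sim$voltage
  v0 <- tail(v$v_mV[v$comp == 1], 1) + 65
  vL <- tail(v$v_mV[v$comp == n], 1) + 65
  # compartment centers sit at dx/2 and L - dx/2 of a sealed-sealed cable
  x0 <- L / n / 2
  xL <- L - L / n / 2
  theory <- cosh((L - xL) / lam) / cosh((L - x0) / lam)
  expect_lt(abs(vL / v0 - theory) / theory, 0.01)
})

test_that("zero input leaves a passive model at its leak reversal", {
  mod <- single_comp_model()
  sim <- simulate_model(mod, 50, settle_ms = 0, record_comps = 1,
                        spike_comp = NULL)
  expect_equal(unique(round(sim$voltage$v_mV, 9)), -65)
})

test_that("charge balance holds for a passive compartment", {
  mod <- single_comp_model()
  sim <- simulate_model(mod, 100, dt = 0.025, settle_ms = 100,
                        iclamp = data.frame(comp = 1, onset_ms = 10,
                                            duration_ms = 50, amp_nA = 0.2),
                        record_comps = 1, record_every_ms = 0.025,
                        spike_comp = NULL)
  v <- sim$voltage$v_mV
  t <- sim$voltage$time_ms
  cm <- mod$cm_nF[1]; gl <- mod$g_leak[1]
  dt <- diff(t)
  vm <- (v[-1] + v[-length(v)]) / 2
  i_cap <- cm * diff(v) / dt
  i_leak <- gl * (vm + 65)
  i_inj <- ifelse((t[-1] + t[-length(t)]) / 2 > 10 &
                    (t[-1] + t[-length(t)]) / 2 < 60, 0.2, 0)
  q_in <- sum(i_inj * dt)
  q_out <- sum((i_cap + i_leak) * dt)
  expect_lt(abs(q_in - q_out) / q_in, 1e-4)
})

test_that("discretize splits by the space-constant rule and conserves area", {
  m <- neuron_morphology(tibble::tibble(comp = 1:2, parent = 0:1,
                                        length_um = c(30, 3000),
                                        diam_um = c(2, 2),
                                        region = "trunk"))
  pas <- passive_props()
  d1 <- discretize(m, pas, max_frac_lambda = 0.2)
  lam <- loomsel:::lambda_um(2, pas)
  expect_equal(sum(d1$length_um), 3030)
  expect_true(all(d1$length_um <= 0.2 * lam + 1e-9))
  # short section stays one compartment
  expect_equal(sum(d1$length_um == 30), 1)
  d2 <- discretize(m, pas, max_frac_lambda = 0.1)
  expect_gte(nrow(d2), 2 * nrow(d1) - 2)
  expect_equal(sum(d2$length_um * d2$diam_um) / sum(m$length_um * m$diam_um),
               1, tolerance = 1e-9)
})

test_that("voltage clamp reports the required current", {
  mod <- single_comp_model()
  area <- pi * 100 * 50 * 1e-8
  gl <- 1e-4 * area * 1e6                  # uS
  n_steps <- 200 / 0.05
  wave <- rep(-65, n_steps); wave[(100 / 0.05):n_steps] <- -75
  sim <- simulate_model(mod, 200, dt = 0.05, settle_ms = 100,
                        vclamp = list(comp = 1, wave = wave),
                        record_comps = 1, record_every_ms = 0.5,
                        spike_comp = NULL)
  ic <- sim$clamp_current
  n <- length(ic)
  # at the holding (resting) potential the clamp passes no current
  expect_lt(abs(ic[100]), 1e-6)
  # steady clamp current for a -10 mV step equals g_leak * deltaV
  expect_equal(ic[n], gl * -10, tolerance = 1e-4)
})

test_that("hyperpolarizing steps produce an HCN-dependent sag", {
  model <- reference_model()
  site <- comps_in_region(model, "fieldA")[5]   # mid-branch dendrite
  pr <- clamp_protocol("current", comp = site, amplitudes = -2,
                       onset_ms = 200, duration_ms = 1500)
  tr <- run_clamp(model, pr)
  sg <- sag_measure(tr, 200, 1700)
  expect_gt(sg$sag_amplitude_mV, 1)
  # peak hyperpolarization exceeds the steady state
  expect_lt(sg$peak_mV, sg$steady_mV)
  tr0 <- run_clamp(set_channel_block(model, HCN = 0), pr)
  sg0 <- sag_measure(tr0, 200, 1700)
  expect_lt(sg0$sag_amplitude_mV, 0.2)
})

test_that("space clamp attenuation follows cable theory", {
  n <- 200
  L <- 6000
  mod <- passive_cable_model(n = n, total_len = L, diam = 2)
  lam <- loomsel:::lambda_um(2, mod$passive)
  att <- space_clamp_attenuation(mod, electrode = 1, region = "trunk")
  fr <- att$per_compartment$fraction
  expect_equal(fr[1], 1, tolerance = 1e-6)
  # far from the sealed end the attenuation follows exp(-x/lambda)
  x <- (seq_len(n) - 0.5) * L / n - L / n / 2
  near <- which(x < 2 * lam & x > 0)
  expect_equal(fr[near], exp(-x[near] / lam), tolerance = 0.02)
  expect_true(all(diff(fr) < 0))
})

test_that("space clamp mean is area-weighted over the requested region", {
  model <- reference_model()
  att <- space_clamp_attenuation(model, electrode = field_a_base(model))
  expect_gt(att$mean_fraction, 0.05)
  expect_lte(att$mean_fraction, 1)
  ia <- comps_in_region(model, "fieldA")
  manual <- sum(att$per_compartment$fraction[ia] * model$area_cm2[ia]) /
    sum(model$area_cm2[ia])
  expect_equal(att$mean_fraction, manual)
})

test_that("spike detection applies threshold and refractory rules", {
  t <- seq(0, 200, by = 0.1)
  expect_length(detect_spikes(rep(-65, length(t)), t), 0)
  v <- rep(-65, length(t))
  for (ts in c(50, 100, 150)) v[t >= ts & t <= ts + 1] <- 10
  s <- detect_spikes(v, t)
  expect_length(s, 3)
  expect_equal(diff(s), c(50, 50))
  # doublet separated by 1 ms collapses under the 2 ms lockout
  v2 <- rep(-65, length(t))
  v2[t >= 50 & t <= 50.3] <- 10
  v2[t >= 51 & t <= 51.3] <- 10
  expect_length(detect_spikes(v2, t), 1)
})

test_that("bAP amplitude decays with distance from the SIZ", {
  model <- reference_model()
  bap <- bap_amplitudes(model)
  siz <- bap$bap_mV[bap$region == "SIZ"]
  tips <- bap$bap_mV[bap$region == "fieldA"]
  expect_gt(siz[1], max(tips))
  # amplitude decreases with path distance within field A
  fa <- bap[bap$region == "fieldA", ]
  expect_lt(stats::cor(fa$path_um, fa$bap_mV), -0.5)
})

test_that("Rall reduction preserves the electrical structure it should", {
  # a region made of one unbranched cable reduces to an electrically
  # equivalent chain: input resistance preserved
  m <- neuron_morphology(tibble::tibble(
    comp = 1:12, parent = 0:11, length_um = 40, diam_um = 2.5,
    region = c(rep("trunk", 2), rep("fieldA", 10))))
  mod <- compartmental_model(m, channels = list(),
                             densities = default_densities()[0, ],
                             syn_gain_ratio = 1)
  red <- rall_reduce(mod, "fieldA")
  expect_lt(abs(input_resistance(red, 1) / input_resistance(mod, 1) - 1),
            0.01)

  # a symmetric 3/2-power tree is exactly collapsible
  tree <- gen_toy_morphology("rall_symmetric", n_branches = 8)
  mt <- compartmental_model(tree, channels = list(),
                            densities = default_densities()[0, ],
                            syn_gain_ratio = 1)
  rt <- rall_reduce(mt, "fieldA")
  expect_lt(nrow(rt$morph), nrow(mt$morph))
  expect_lt(abs(input_resistance(rt, 1) / input_resistance(mt, 1) - 1), 0.01)

  # synapse transfer map covers every original compartment
  map <- attr(rt, "comp_map")
  expect_true(all(map[mt$morph$region == "fieldA"] > 0))
  expect_error(rall_reduce(mt, "fieldB"), "empty")
})

test_that("Rall reduction conserves channel conductance on a 3/2 tree", {
  tree <- gen_toy_morphology("rall_symmetric", n_branches = 8)
  dens <- tibble::tribble(~channel, ~region, ~density, "HCN", "fieldA", 4e-4)
  mt <- compartmental_model(tree, channels = default_channel_library()["HCN"],
                            densities = dens, gradient_ratio = 1,
                            syn_gain_ratio = 1)
  rt <- rall_reduce(mt, "fieldA")
  g_full <- sum(mt$gbar[, "HCN"])
  g_red <- sum(rt$gbar[, "HCN"])
  expect_equal(g_red / g_full, 1, tolerance = 0.02)
})
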