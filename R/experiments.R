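#' Configuration for in-silico experiments
#'
#' Desk-scale defaults: the synthetic fan morphology (~70 compartments),
#' five jitter levels spanning 0-100% coherence, and the restrained-
#' preparation stimulus geometry (l/|v| = 50 ms, 2 deg coarse pixels,
#' 80 deg maximal size).
#'
#' @param morphology_kind Synthetic morphology for the model
#'   ([gen_toy_morphology()]).
#' @param n_branches,comps_per_branch Fan geometry.
#' @param variant Channel kinetic variant ([default_channel_library()]).
#' @param l_over_v Loom kinematics (ms).
#' @param pixel_size Coarse pixel size (deg).
#' @param azimuth_halfwidth,elevation_halfwidth Screen half-extents (deg).
#' @param max_full_angle Final stimulus size (deg).
#' @param sigmas Jitter standard deviations (deg); 0 gives 100% coherence.
#' @param n_seeds Jitter draws per sigma level.
#' @param n_draws Random draws for the coherence baseline.
#' @param unit_g_nS Synaptic conductance per full-contrast facet event.
#' @param latency_ms,jitter_sd_ms Synaptic latency and timing jitter.
#' @param spread,k_targets Facet-map footprint (pixels, compartments).
#' @param dt Integration step (ms).
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(morphology_kind = "fan", n_branches = 12,
                              comps_per_branch = 10, variant = "default",
                              l_over_v = 50, pixel_size = 2,
                              azimuth_halfwidth = 52,
                              elevation_halfwidth = 40, max_full_angle = 80,
                              sigmas = c(40, 20, 10, 5, 0), n_seeds = 2,
                              n_draws = 30, unit_g_nS = 14, latency_ms = 30,
                              jitter_sd_ms = 2, spread = 3, k_targets = 6,
                              dt = 0.025, seed = 1L) {
  structure(as.list(environment()), class = "experiment_config")
}

build_experiment_model <- function(config, variant = config$variant) {
  morph <- gen_toy_morphology(config$morphology_kind,
                              n_branches = config$n_branches,
                              comps_per_branch = config$comps_per_branch,
                              seed = config$seed)
  compartmental_model(morph,
                      channels = default_channel_library(variant))
}

# jittered movies + measured coherences + event trains, shared by the
# experiments below
prepare_stimuli <- function(config, model, sigmas = config$sigmas,
                            n_seeds = config$n_seeds) {
  params <- loom_params(l_over_v = config$l_over_v,
                        max_full_angle = config$max_full_angle)
  grid <- coarse_grid(config$pixel_size, config$azimuth_halfwidth,
                      config$elevation_halfwidth)
  reference <- render_coarse_loom(params, grid)
  base <- coherence_baseline(reference, n_draws = config$n_draws,
                             seed = config$seed)
  map <- build_facet_map(grid, model, spread = config$spread,
                         k = config$k_targets)
  stims <- list()
  for (i in seq_along(sigmas)) {
    for (r in seq_len(n_seeds)) {
      sig <- sigmas[i]
      jit <- jitter_layout(reference, sig, sigma_max = 2 * max(sigmas, 40),
                           seed = config$seed + 37L * i + r)
      coh <- coherence_percent(jit, reference, baseline = base)$coherence_percent
      ev <- stimulus_to_events(jit, map, unit_g_nS = config$unit_g_nS,
                               latency_ms = config$latency_ms,
                               jitter_sd_ms = config$jitter_sd_ms,
                               seed = config$seed + 1000L + 37L * i + r)
      stims[[length(stims) + 1]] <-
        list(sigma = sig, rep = r, coherence = coh, events = ev)
    }
  }
  list(params = params, grid = grid, reference = reference, map = map,
       baseline = base, stimuli = stims,
       window_ms = c(0, -reference$frame_times[1] * 1000))
}

loom_response <- function(model, events, window_ms, dt = 0.025,
                          record_gates = NULL, record_comps = NULL) {
  simulate_model(model, duration_ms = window_ms[2], dt = dt,
                 settle_ms = 2000, events = events,
                 record_comps = record_comps,
                 record_gates = record_gates, record_every_ms = 1)
}

#' Coherence sweep under channel blockade conditions
#'
#' Simulates looming responses across coherence levels for four conditions:
#' control, HCN block (`g_H = 0`), inactivating-K+ block (`K_D-like = 0`),
#' and tonic hyperpolarizing current injection matched to the resting
#' hyperpolarization produced by HCN block. Reports spike counts, peak
#' firing rates, sustained/transient splits and the coherence-preference
#' slope per condition.
#'
#' @param config An [experiment_config()].
#' @return A `coherence_sweep` list: `responses` tibble, `slopes` tibble,
#'   `stimulus_info`.
#' @export
run_coherence_sweep <- function(config = experiment_config()) {
  model <- build_experiment_model(config)
  stim <- prepare_stimuli(config, model)
  base_comp <- field_a_base(model)

  hcn_blocked <- set_channel_block(model, HCN = 0)
  rmp_shift <- steady_rmp(hcn_blocked, base_comp) - steady_rmp(model, base_comp)
  hold_nA <- rmp_shift / input_resistance(model, base_comp)  # negative
  conditions <- list(
    control = list(model = model, hold = 0),
    hcn_block = list(model = hcn_blocked, hold = 0),
    kd_block = list(model = set_channel_block(model, KD = 0), hold = 0),
    holding = list(model = model, hold = hold_nA))

  responses <- purrr::map_dfr(names(conditions), function(cn) {
    cond <- conditions[[cn]]
    purrr::map_dfr(stim$stimuli, function(s) {
      ic <- if (cond$hold != 0)
        data.frame(comp = base_comp, onset_ms = 0,
                   duration_ms = stim$window_ms[2], amp_nA = cond$hold)
      sim <- simulate_model(cond$model, duration_ms = stim$window_ms[2],
                            dt = config$dt, settle_ms = 2000,
                            events = s$events, iclamp = ic,
                            record_every_ms = 1)
      met <- response_metrics(sim$spike_times, stim$window_ms)
      st <- sustained_transient_split(sim$spike_times)
      tibble::tibble(condition = cn, sigma = s$sigma, rep = s$rep,
                     coherence = s$coherence,
                     spike_count = met$spike_count,
                     peak_rate_spk_s = met$peak_rate_spk_s,
                     sustained = st$sustained, transient = st$transient)
    })
  })

  slopes <- responses |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(g, key) {
      cp <- coherence_preference(g)
      glance(cp)
    }) |>
    dplyr::ungroup()

  structure(list(responses = responses, slopes = slopes,
                 holding_nA = hold_nA,
                 stimulus_info = tibble::tibble(
                   baseline = stim$baseline,
                   window_ms = stim$window_ms[2])),
            class = "coherence_sweep")
}

# resting potential after settling (mV) at a reference compartment
steady_rmp <- function(model, comp, settle_ms = 4000) {
  sim <- simulate_model(model, duration_ms = 1, dt = 0.1,
                        settle_ms = settle_ms, record_comps = comp,
                        spike_comp = NULL)
  tail(sim$voltage$v_mV, 1)
}

#' Retinotopic versus spatially randomized synaptic input
#'
#' Presents the same coherent looming input train with retinotopic and with
#' spatially randomized field A locations to three model variants: passive
#' dendrites, dendrites with HCN only (leak recalibrated to preserve the
#' resting potential), and the full model with both HCN and inactivating
#' K+ channels. Reports spike counts and the mean membrane potential at
#' the base of field A.
#'
#' @param config An [experiment_config()].
#' @return A tibble: `model`, `placement`, `spike_count`, `mean_vm_mV`.
#' @export
run_spatial_randomization <- function(config = experiment_config()) {
  full <- build_experiment_model(config)
  dens <- config_densities <- default_densities()
  passive <- compartmental_model(full$morph,
                                 channels = full$channels,
                                 densities = dens[!dens$channel %in%
                                                    c("HCN", "KD"), ])
  hcn_only <- compartmental_model(full$morph,
                                  channels = full$channels,
                                  densities = dens[dens$channel != "KD", ])
  stim <- prepare_stimuli(config, full, sigmas = 0, n_seeds = 1)
  retino <- stim$stimuli[[1]]$events
  rando <- randomize_locations(retino, stim$map, seed = config$seed + 99L)
  base_comp <- field_a_base(full)

  models <- list(passive = passive, hcn = hcn_only, full = full)
  placements <- list(retinotopic = retino, randomized = rando)
  purrr::map_dfr(names(models), function(mn) {
    purrr::map_dfr(names(placements), function(pn) {
      sim <- simulate_model(models[[mn]], duration_ms = stim$window_ms[2],
                            dt = config$dt, settle_ms = 2000,
                            events = placements[[pn]],
                            record_comps = base_comp, record_every_ms = 1)
      v <- sim$voltage$v_mV[sim$voltage$comp == base_comp]
      tibble::tibble(model = mn, placement = pn,
                     spike_count = length(sim$spike_times),
                     mean_vm_mV = mean(v))
    })
  })
}

#' Track channel inactivation across stimulus coherence
#'
#' Records the surface-area-weighted mean inactivation (1 - availability
#' gate) of the inactivating K+ channels over field A and of the Ca_T
#' channels at their sites during looming stimuli, averages it over the
#' last 2 s before the projected collision, and regresses it against
#' stimulus coherence.
#'
#' @param config An [experiment_config()].
#' @param blocked_hcn Also report the resting K+ inactivation with
#'   `g_H = 0` (its reduction mirrors the HCN-block effect).
#' @return A list: `per_stimulus` tibble, `slopes` tibble, and resting
#'   inactivation with/without HCN.
#' @export
run_inactivation_tracking <- function(config = experiment_config(),
                                      blocked_hcn = TRUE) {
  model <- build_experiment_model(config)
  stim <- prepare_stimuli(config, model, n_seeds = 1)
  gates <- data.frame(channel = c("KD", "CaT"), gate = c(2, 2),
                      region = c("fieldA", "SIZ"))
  per_stimulus <- purrr::map_dfr(stim$stimuli, function(s) {
    sim <- loom_response(model, s$events, stim$window_ms, dt = config$dt,
                         record_gates = gates)
    gt <- sim$gate_traces
    last2 <- gt$time_ms >= stim$window_ms[2] - 2000
    gt <- gt[last2, ]
    agg <- gt |>
      dplyr::group_by(.data$channel) |>
      dplyr::summarise(mean_inactivation = mean(1 - .data$value),
                       .groups = "drop")
    tibble::tibble(sigma = s$sigma, coherence = s$coherence,
                   channel = agg$channel,
                   mean_inactivation = agg$mean_inactivation)
  })
  slopes <- per_stimulus |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      slope_per_100pct = unname(coef(lm(mean_inactivation ~
                                          I(coherence / 100))))[2],
      .groups = "drop")

  resting <- NULL
  if (blocked_hcn) {
    rest_kd <- function(m) {
      sim <- simulate_model(m, duration_ms = 1, dt = 0.1, settle_ms = 5000,
                            record_gates = data.frame(channel = "KD",
                                                      gate = 2,
                                                      region = "fieldA"),
                            spike_comp = NULL)
      1 - tail(sim$gate_traces$value, 1)
    }
    resting <- tibble::tibble(
      condition = c("control", "hcn_block"),
      resting_kd_inactivation = c(rest_kd(model),
                                  rest_kd(set_channel_block(model, HCN = 0))))
  }
  list(per_stimulus = per_stimulus, slopes = slopes, resting = resting)
}

#' Morphology and kinetics controls for coherence selectivity
#'
#' Compares the coherence-preference slope of the full branched model with
#' (i) the equivalent-cylinder (Rall-reduced) morphology and (ii) ten-fold
#' faster and slower HCN-activation / K+-inactivation kinetics.
#'
#' @param config An [experiment_config()]; morphology controls default to a
#'   single jitter draw per level.
#' @param n_seeds Jitter draws per sigma level.
#' @return A tibble of slopes per condition (`full`, `reduced`, `fast`,
#'   `slow`) and the underlying responses as attribute `responses`.
#' @export
run_morphology_controls <- function(config = experiment_config(),
                                    n_seeds = 1) {
  model <- build_experiment_model(config)
  stim <- prepare_stimuli(config, model, n_seeds = n_seeds)
  reduced <- rall_reduce(model, "fieldA", grouping = "merged")
  comp_map <- attr(reduced, "comp_map")
  fast <- build_experiment_model(config, variant = "fast")
  slow <- build_experiment_model(config, variant = "slow")

  run_set <- function(m, remap = FALSE) {
    purrr::map_dfr(stim$stimuli, function(s) {
      ev <- s$events
      if (remap) ev$comp <- comp_map[ev$comp]
      sim <- loom_response(m, ev, stim$window_ms, dt = config$dt)
      tibble::tibble(sigma = s$sigma, rep = s$rep, coherence = s$coherence,
                     spike_count = length(sim$spike_times))
    })
  }
  sets <- list(full = run_set(model),
               reduced = run_set(reduced, remap = TRUE),
               fast = run_set(fast),
               slow = run_set(slow))
  out <- purrr::map_dfr(names(sets), function(nm) {
    cp <- coherence_preference(sets[[nm]])
    dplyr::bind_cols(tibble::tibble(condition = nm), glance(cp))
  })
  attr(out, "responses") <- dplyr::bind_rows(sets, .id = "condition")
  out
}
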