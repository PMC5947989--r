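# Assemble the C++ integrator's network description from a model
sim_net <- function(model) {
  has_ca <- any(vapply(model$channels, function(s) isTRUE(s$ca_source),
                       logical(1)) &
                colSums(model$gbar) > 0)
  list(parent = as.integer(model$morph$parent - 1L),
       cm = model$cm_nF,
       g_leak = model$g_leak,
       e_leak = model$e_leak,
       g_axial = model$g_ax,
       v_init = model$v_init,
       calcium = if (has_ca) model$calcium else NULL)
}

sim_channels <- function(model) {
  out <- list()
  for (ch in names(model$channels)) {
    g <- model$gbar[, ch] * model$block[ch]
    comps <- which(g > 0)
    if (length(comps) == 0) next
    spec <- model$channels[[ch]]
    out[[ch]] <- list(erev = spec$e_rev,
                      ca_source = isTRUE(spec$ca_source),
                      comps = as.integer(comps - 1L),
                      gbar = g[comps],
                      gates = channel_gate_matrix(spec))
  }
  out
}

#' Simulate a compartmental model
#'
#' Runs the Crank-Nicolson cable integrator with optional current steps, an
#' arbitrary injected current waveform, an ideal single-electrode voltage
#' clamp, and synaptic conductance events. Gates use Rush-Larsen exponential
#' updates; the model is first settled to its resting state with coarse
#' implicit steps.
#'
#' @param model A [compartmental_model()].
#' @param duration_ms Simulated time (ms).
#' @param dt Time step (ms).
#' @param settle_ms Settling time before `t = 0` (ms).
#' @param iclamp Data frame of current steps: `comp`, `onset_ms`,
#'   `duration_ms`, `amp_nA`.
#' @param iwave List `list(comp=, wave=)`: injected current (nA) sampled at
#'   `dt`.
#' @param vclamp List `list(comp=, wave=)` (mV command sampled at `dt`) for
#'   an ideal voltage clamp.
#' @param events Synaptic events: data frame `time_ms`, `g_nS`, `comp`, plus
#'   kinetics via `syn_tau_rise`, `syn_tau_decay`, `syn_e_rev`.
#' @param record_comps Compartments whose voltage is recorded.
#' @param record_every_ms Sampling interval of recordings.
#' @param record_gates Data frame `channel`, `gate`, `region`: area-weighted
#'   mean gate values to record.
#' @param record_currents Character vector of channel names whose total
#'   membrane current to record.
#' @param spike_comp Compartment for spike detection (`NULL` to disable;
#'   defaults to the SIZ when present).
#' @param spike_threshold,spike_refractory_ms Detection threshold (mV) and
#'   lockout (ms).
#' @param syn_tau_rise,syn_tau_decay,syn_e_rev Synaptic kinetics (ms, ms,
#'   mV): nicotinic excitatory defaults.
#' @return A `sim_result`: `time` (ms), voltage tibble (long), detected
#'   `spike_times` (ms), optional clamp current, gate and current traces.
#' @export
simulate_model <- function(model, duration_ms, dt = 0.025, settle_ms = 1000,
                           iclamp = NULL, iwave = NULL, vclamp = NULL,
                           events = NULL,
                           record_comps = NULL, record_every_ms = 0.5,
                           record_gates = NULL, record_currents = NULL,
                           spike_comp = NULL, spike_threshold = -15,
                           spike_refractory_ms = 2,
                           syn_tau_rise = 0.3, syn_tau_decay = 3,
                           syn_e_rev = 0) {
  stopifnot(dt > 0, duration_ms > 0)
  n_steps <- as.integer(ceiling(duration_ms / dt))
  if (is.null(record_comps)) {
    record_comps <- unique(c(
      if (any(model$morph$region == "SIZ")) siz_comp(model),
      field_a_base_safe(model)))
  }
  if (is.null(spike_comp) && any(model$morph$region == "SIZ"))
    spike_comp <- siz_comp(model)

  protocol <- list(dt = dt, n_steps = n_steps,
                   settle_ms = settle_ms, settle_dt = 0.5)
  if (!is.null(iclamp)) {
    ic <- as.data.frame(iclamp)
    protocol$iclamp <- cbind(ic$comp - 1L, ic$onset_ms, ic$duration_ms,
                             ic$amp_nA)
  }
  if (!is.null(iwave))
    protocol$iwave <- list(comp = as.integer(iwave$comp - 1L),
                           wave = rep_len(iwave$wave, n_steps))
  if (!is.null(vclamp))
    protocol$vclamp <- list(comp = as.integer(vclamp$comp - 1L),
                            wave = rep_len(vclamp$wave, n_steps))
  if (!is.null(events) && nrow(events) > 0) {
    ev <- dplyr::arrange(tibble::as_tibble(events), .data$time_ms)
    gain <- model$syn_gain %||% rep(1, nrow(model$morph))
    protocol$synapses <- list(step = as.integer(round(ev$time_ms / dt)),
                              comp = as.integer(ev$comp - 1L),
                              g = ev$g_nS * gain[ev$comp] / 1000,  # nS -> uS
                              tau_rise = syn_tau_rise,
                              tau_decay = syn_tau_decay,
                              e_rev = syn_e_rev)
  }

  rec <- list(comps = as.integer(record_comps - 1L),
              every = max(1L, as.integer(round(record_every_ms / dt))))
  ch_names <- names(sim_channels(model))
  if (!is.null(record_gates)) {
    rg <- as.data.frame(record_gates)
    rec$gates <- lapply(seq_len(nrow(rg)), function(r) {
      ci <- match(rg$channel[r], ch_names) - 1L
      if (is.na(ci)) stop("channel ", rg$channel[r], " not active in model")
      w <- numeric(nrow(model$morph))
      sel <- comps_in_region(model, rg$region[r])
      w[sel] <- model$area_cm2[sel]
      list(channel = ci, gate = as.integer(rg$gate[r] - 1L), weights = w)
    })
  }
  if (!is.null(record_currents)) {
    rec$currents <- lapply(record_currents, function(ch) {
      ci <- match(ch, ch_names) - 1L
      if (is.na(ci)) stop("channel ", ch, " not active in model")
      list(channel = ci, weights = rep(1, nrow(model$morph)))
    })
  }
  if (!is.null(spike_comp))
    rec$spikes <- list(comp = as.integer(spike_comp - 1L),
                       threshold = spike_threshold,
                       refractory = spike_refractory_ms)

  raw <- simulate_cable_cpp(sim_net(model), unname(sim_channels(model)),
                            protocol, rec)

  v <- raw$v
  volt <- tibble::tibble(
    time_ms = rep(raw$time, each = length(record_comps)),
    comp = rep(as.integer(record_comps), length(raw$time)),
    region = rep(model$morph$region[record_comps], length(raw$time)),
    v_mV = as.numeric(v))
  gate_traces <- NULL
  if (!is.null(record_gates)) {
    rg <- as.data.frame(record_gates)
    gate_traces <- purrr::map_dfr(seq_len(nrow(rg)), function(r) {
      tibble::tibble(time_ms = raw$time, channel = rg$channel[r],
                     gate = rg$gate[r], region = rg$region[r],
                     value = raw$gate_traces[r, ])
    })
  }
  current_traces <- NULL
  if (!is.null(record_currents)) {
    current_traces <- purrr::map_dfr(seq_along(record_currents), function(r) {
      tibble::tibble(time_ms = raw$time, channel = record_currents[r],
                     i_nA = raw$current_traces[r, ])
    })
  }
  structure(list(time = raw$time, voltage = volt,
                 spike_times = raw$spike_times,
                 clamp_current = if (!is.null(vclamp)) raw$clamp_current,
                 gate_traces = gate_traces,
                 current_traces = current_traces,
                 v_final = raw$v_final,
                 dt = dt, duration_ms = duration_ms,
                 record_comps = record_comps),
            class = "sim_result")
}

field_a_base_safe <- function(model) {
  if (any(model$morph$region == "fieldA")) field_a_base(model) else integer(0)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", x$duration_ms, " ms at dt ", x$dt, " ms; ",
      length(x$spike_times), " spikes; sites: ",
      paste(x$record_comps, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a simulation result
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return The long voltage tibble (`time_ms`, `comp`, `region`, `v_mV`).
#' @exportS3Method generics::tidy
tidy.sim_result <- function(x, ...) x$voltage

#' @exportS3Method generics::glance
glance.sim_result <- function(x, ...) {
  tibble::tibble(duration_ms = x$duration_ms, dt = x$dt,
                 n_spikes = length(x$spike_times),
                 n_sites = length(x$record_comps))
}

#' Clamp protocols
#'
#' Describes a family of 1-2 s current or voltage steps from a holding
#' level, as used to characterize the hyperpolarization-activated
#' conductance.
#'
#' @param mode `"current"` or `"voltage"`.
#' @param comp Electrode compartment.
#' @param amplitudes Step amplitudes (nA for current mode; absolute command
#'   mV for voltage mode).
#' @param onset_ms,duration_ms Step timing (ms).
#' @param holding Holding level (nA injected, or command mV).
#' @param post_ms Recorded tail after the step (ms).
#' @return A `clamp_protocol` list.
#' @export
clamp_protocol <- function(mode = c("current", "voltage"), comp, amplitudes,
                           onset_ms = 200, duration_ms = 1500, holding = NULL,
                           post_ms = 300) {
  mode <- match.arg(mode)
  stopifnot(duration_ms > 0, onset_ms >= 0)
  if (mode == "voltage" && (any(amplitudes < -150) || any(amplitudes > 50)))
    warning("voltage command outside [-150, 50] mV")
  structure(list(mode = mode, comp = comp, amplitudes = amplitudes,
                 onset_ms = onset_ms, duration_ms = duration_ms,
                 holding = holding, post_ms = post_ms),
            class = "clamp_protocol")
}

#' Run a clamp protocol
#'
#' Runs each step amplitude as an independent trial (amplitudes randomly
#' interleaved in the experiments; order is irrelevant for independent
#' simulations). Voltage mode uses an ideal single-electrode clamp and
#' reports the required current.
#'
#' @param model A [compartmental_model()].
#' @param protocol A [clamp_protocol()].
#' @param dt Integration step (ms).
#' @param record_every_ms Sampling interval (ms).
#' @return A tibble: `step`, `amplitude`, `time_ms`, `v_mV` and (voltage
#'   mode) `i_nA`.
#' @export
run_clamp <- function(model, protocol, dt = 0.05, record_every_ms = 1) {
  stopifnot(inherits(protocol, "clamp_protocol"))
  comp <- protocol$comp
  total <- protocol$onset_ms + protocol$duration_ms + protocol$post_ms
  purrr::map_dfr(seq_along(protocol$amplitudes), function(k) {
    amp <- protocol$amplitudes[k]
    if (protocol$mode == "current") {
      hold <- protocol$holding %||% 0
      ic <- data.frame(comp = comp, onset_ms = c(0, protocol$onset_ms),
                       duration_ms = c(total, protocol$duration_ms),
                       amp_nA = c(hold, amp))
      ic <- ic[ic$amp_nA != 0, , drop = FALSE]
      sim <- simulate_model(model, total, dt = dt,
                            iclamp = if (nrow(ic)) ic else NULL,
                            record_comps = comp,
                            record_every_ms = record_every_ms,
                            spike_comp = NULL)
      v <- sim$voltage[sim$voltage$comp == comp, ]
      tibble::tibble(step = k, amplitude = amp, time_ms = v$time_ms,
                     v_mV = v$v_mV)
    } else {
      hold <- protocol$holding %||% model$target_rmp
      n_steps <- ceiling(total / dt)
      tt <- (seq_len(n_steps) - 1) * dt
      wave <- ifelse(tt >= protocol$onset_ms &
                     tt < protocol$onset_ms + protocol$duration_ms, amp, hold)
      sim <- simulate_model(model, total, dt = dt,
                            vclamp = list(comp = comp, wave = wave),
                            record_comps = comp,
                            record_every_ms = record_every_ms,
                            spike_comp = NULL)
      v <- sim$voltage[sim$voltage$comp == comp, ]
      ic <- sim$clamp_current
      tibble::tibble(step = k, amplitude = amp, time_ms = v$time_ms,
                     v_mV = v$v_mV, i_nA = ic[seq_along(v$time_ms)])
    }
  })
}

#' Detect spikes by threshold crossing
#'
#' Upward crossings of a fixed threshold with a refractory lockout; spike
#' times are taken at the crossing sample.
#'
#' @param v Voltage trace (mV), uniformly sampled.
#' @param time_ms Sample times (ms).
#' @param threshold Crossing threshold (mV).
#' @param refractory_ms Minimal separation between detections (ms).
#' @return Spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(v, time_ms, threshold = -15, refractory_ms = 2) {
  stopifnot(length(v) == length(time_ms))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  if (length(up) == 0) return(numeric(0))
  times <- time_ms[up]
  out <- times[1]
  for (t in times[-1]) if (t - out[length(out)] >= refractory_ms)
    out <- c(out, t)
  out
}

#' Back-propagating action-potential amplitudes
#'
#' Evokes a single spike at the SIZ with a brief strong current pulse and
#' measures the peak depolarization relative to rest in every compartment;
#' bAP amplitude decays with electrotonic distance from the SIZ and serves
#' as an electrotonic coordinate.
#'
#' @param model A [compartmental_model()].
#' @param pulse_nA,pulse_ms Pulse amplitude and duration.
#' @return A tibble: `comp`, `region`, `path_um`, `bap_mV`.
#' @export
bap_amplitudes <- function(model, pulse_nA = 5, pulse_ms = 3) {
  n <- nrow(model$morph)
  sim <- simulate_model(model, 60,
                        iclamp = data.frame(comp = siz_comp(model),
                                            onset_ms = 5,
                                            duration_ms = pulse_ms,
                                            amp_nA = pulse_nA),
                        record_comps = seq_len(n), record_every_ms = 0.1,
                        spike_comp = NULL)
  v <- sim$voltage
  rest <- v$v_mV[v$time_ms == 0]
  peaks <- tapply(v$v_mV, v$comp, max)
  tibble::tibble(comp = seq_len(n), region = model$morph$region,
                 path_um = model$path_um,
                 bap_mV = as.numeric(peaks)[order(as.integer(names(peaks)))] -
                   rest)
}
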