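#' Synthetic voltage-clamp dataset from known HCN ground truth
#'
#' Simulates the clamp current of a single compartment carrying a leak and
#' an HCN conductance with known Boltzmann activation and bell-shaped time
#' constant, during 1-2 s voltage steps from a holding potential, with
#' additive Gaussian current noise. At a fixed clamp potential the gating
#' relaxation is exactly exponential, so the simulation is evaluated in
#' closed form on the sampling grid. The ground truth is stored as an
#' attribute for closed-loop recovery tests.
#'
#' @param truth Ground-truth parameters: `g_max_nS`, `v_half`, `s` (mV),
#'   `tau_max`, `tau_min` (ms), `v_peak`, `steepness` (mV), `e_h` (mV),
#'   `g_leak_nS`, `e_leak` (mV).
#' @param v_hold Holding potential (`v1`, mV).
#' @param v_steps Step command potentials (`v2`, mV), covering the
#'   activation range.
#' @param duration_ms Step duration (ms).
#' @param dt_ms Sampling interval (ms).
#' @param noise_sd_pA Gaussian current noise (pA).
#' @param seed Optional integer seed.
#' @return A tibble (`step`, `time_ms`, `i_nA`, `v1`, `v2`) with attribute
#'   `truth`; `time_ms` runs from step onset.
#' @export
gen_clamp_dataset <- function(truth = list(g_max_nS = 100, v_half = -77.6,
                                           s = 13.34, tau_max = 1340,
                                           tau_min = 50, v_peak = -83,
                                           steepness = 20, e_h = -35,
                                           g_leak_nS = 50, e_leak = -65),
                              v_hold = -65,
                              v_steps = c(-75, -85, -95, -105, -115),
                              duration_ms = 1500, dt_ms = 1,
                              noise_sd_pA = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(noise_sd_pA >= 0)
  tt <- seq(0, duration_ms, by = dt_ms)
  out <- purrr::map_dfr(seq_along(v_steps), function(k) {
    v2 <- v_steps[k]
    g1 <- hcn_steady_state(v_hold, truth$v_half, truth$s, truth$g_max_nS)
    g2 <- hcn_steady_state(v2, truth$v_half, truth$s, truth$g_max_nS)
    tau <- symmetric_tau(v2, truth$tau_max, truth$tau_min, truth$v_peak,
                         truth$steepness)
    g_h <- g2 + (g1 - g2) * exp(-tt / tau)
    i_pA <- truth$g_leak_nS * (v2 - truth$e_leak) + g_h * (v2 - truth$e_h)
    if (noise_sd_pA > 0) i_pA <- i_pA + rnorm(length(tt), 0, noise_sd_pA)
    tibble::tibble(step = k, time_ms = tt, i_nA = i_pA / 1000,
                   v1 = v_hold, v2 = v2)
  })
  attr(out, "truth") <- truth
  out
}

#' Synthetic looming-evoked spike trains with programmed coherence slope
#'
#' Draws spike trains from an inhomogeneous Poisson process whose rate
#' profile has the characteristic looming shape (the angular-velocity times
#' exponential-of-size template, `theta'(t - delta) exp(-alpha theta(t -
#' delta))`, truncated at the projected collision time) and whose
#' time-integral is `intercept + slope * coherence` spikes, so the expected
#' spike count is linear in stimulus coherence by construction. Optional
#' negative-binomial dispersion adds super-Poisson trial-to-trial count
#' variability.
#'
#' @param coherences Coherence levels in percent (vector).
#' @param n_trials Trials per coherence level.
#' @param intercept,slope Programmed count at 0% coherence and increase per
#'   percent coherence (spikes/%).
#' @param dispersion Extra count variance factor (0 = Poisson; variance is
#'   `lambda * (1 + dispersion)`).
#' @param params A [loom_params()] defining the rate-profile kinematics.
#' @param delta_ms Response delay of the profile (ms).
#' @param alpha Size-penalty constant (1/deg) of the profile template.
#' @param seed Optional integer seed.
#' @return A tibble (`coherence`, `trial`, `time_ms`); attribute
#'   `window_ms` gives the stimulus window (onset to collision).
#' @export
gen_loom_trains <- function(coherences, n_trials = 10, intercept = 5,
                            slope = 0.24, dispersion = 0,
                            params = loom_params(), delta_ms = 30,
                            alpha = 0.08, seed = NULL) {
  stopifnot(all(coherences >= 0), all(coherences <= 100), dispersion >= 0)
  if (!is.null(seed)) set.seed(seed)
  t_start <- loom_start_time(params)
  T_ms <- -t_start * 1000
  dt <- 1
  tt <- seq(dt / 2, T_ms - dt / 2, by = dt)           # ms since onset
  t_resp <- tt - delta_ms                              # delayed copy
  t_coll <- (t_start * 1000 + t_resp) / 1000           # s, < 0
  ok <- t_coll < -1e-6 & t_resp > 0
  theta <- rep(0, length(tt))
  theta[ok] <- angular_subtense(t_coll[ok], params) / 2
  dtheta <- c(0, diff(theta)) / dt                     # deg/ms
  profile <- pmax(dtheta, 0) * exp(-alpha * 2 * theta)
  if (sum(profile) == 0) stop("degenerate rate profile")
  profile <- profile / sum(profile)

  out <- purrr::map_dfr(coherences, function(coh) {
    lambda <- intercept + slope * coh
    purrr::map_dfr(seq_len(n_trials), function(tr) {
      n <- if (dispersion == 0) rpois(1, lambda) else {
        size <- lambda / dispersion
        rnbinom(1, size = size, mu = lambda)
      }
      times <- if (n > 0)
        sort(sample(tt, n, replace = TRUE, prob = profile) +
               runif(n, -dt / 2, dt / 2)) else numeric(0)
      tibble::tibble(coherence = coh, trial = tr, time_ms = times)
    })
  })
  attr(out, "window_ms") <- c(0, T_ms)
  attr(out, "trials") <- tidyr::expand_grid(coherence = coherences,
                                            trial = seq_len(n_trials))
  out
}

#' Spike counts per trial from a generated train table
#'
#' @param trains Output of [gen_loom_trains()].
#' @return A tibble (`coherence`, `trial`, `spike_count`) including
#'   zero-count trials.
#' @export
count_loom_trains <- function(trains) {
  win <- attr(trains, "window_ms")
  grid <- attr(trains, "trials")
  if (is.null(grid)) grid <- dplyr::distinct(trains[, c("coherence", "trial")])
  counted <- trains |>
    dplyr::filter(.data$time_ms >= win[1], .data$time_ms <= win[2]) |>
    dplyr::count(.data$coherence, .data$trial, name = "spike_count")
  dplyr::left_join(grid, counted, by = c("coherence", "trial")) |>
    dplyr::mutate(spike_count = dplyr::coalesce(.data$spike_count, 0L))
}
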