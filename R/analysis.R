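# single-exponential least squares: v = offset + amp * exp(-(t - t0)/tau)
fit_single_exp <- function(t, y, t0 = 0) {
  df <- data.frame(tt = t - t0, y = y)
  if (sd(y) < 1e-12)  # constant trace: zero-amplitude exponential
    return(list(offset = mean(y), amp = 0, tau = NA_real_, converged = TRUE))
  offset0 <- mean(tail(y, max(3, length(y) %/% 20)))
  amp0 <- y[1] - offset0
  resid0 <- y - offset0
  tau0 <- tryCatch({
    usable <- sign(resid0) == sign(amp0) & abs(resid0) > 1e-12 & amp0 != 0
    if (sum(usable) > 3) {
      cf <- coef(lm(log(abs(resid0[usable])) ~ df$tt[usable]))
      max(1e-3, -1 / cf[2])
    } else max(df$tt) / 3
  }, error = function(e) max(df$tt) / 3)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(df$tt) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ offset + amp * exp(-tt / tau), data = df,
                      start = list(offset = offset0, amp = amp0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(offset = NA_real_, amp = NA_real_, tau = NA_real_,
                converged = FALSE))
  cf <- coef(fit)
  list(offset = unname(cf["offset"]), amp = unname(cf["amp"]),
       tau = unname(cf["tau"]), converged = TRUE)
}

#' Sag amplitude and time constant
#'
#' The sag amplitude is the difference in membrane potential between the
#' peak hyperpolarization during a current step and the steady-state value
#' at the end of the step; the sag time constant comes from a
#' single-exponential fit over the period starting 15 ms after peak
#' hyperpolarization to the end of the step.
#'
#' @param trace A data frame with `time_ms` and `v_mV`.
#' @param step_onset_ms,step_end_ms Current-step window (ms).
#' @param steady_window_ms Averaging window for the steady-state level at
#'   the end of the step.
#' @return A one-row tibble: `sag_amplitude_mV`, `sag_tau_ms`, `peak_mV`,
#'   `steady_mV`, `converged`.
#' @export
sag_measure <- function(trace, step_onset_ms, step_end_ms,
                        steady_window_ms = 50) {
  stopifnot(all(c("time_ms", "v_mV") %in% names(trace)))
  w <- trace$time_ms >= step_onset_ms & trace$time_ms <= step_end_ms
  if (!any(w)) stop("step window lies outside the trace")
  tt <- trace$time_ms[w]; vv <- trace$v_mV[w]
  ipk <- which.min(vv)
  peak <- vv[ipk]; t_peak <- tt[ipk]
  steady <- mean(vv[tt >= step_end_ms - steady_window_ms])
  fitw <- tt >= t_peak + 15
  fit <- if (sum(fitw) > 5) fit_single_exp(tt[fitw], vv[fitw], t0 = t_peak + 15)
         else list(tau = NA_real_, converged = FALSE)
  tibble::tibble(sag_amplitude_mV = steady - peak, sag_tau_ms = fit$tau,
                 peak_mV = peak, steady_mV = steady,
                 converged = isTRUE(fit$converged))
}

#' Membrane time constant
#'
#' Single-exponential fit to the membrane potential from 0.5 to 13 ms after
#' the start of a hyperpolarizing current injection.
#'
#' @param trace A data frame with `time_ms` and `v_mV`.
#' @param step_onset_ms Current onset (ms).
#' @return Fitted time constant (ms).
#' @export
membrane_tau <- function(trace, step_onset_ms) {
  w <- trace$time_ms >= step_onset_ms + 0.5 & trace$time_ms <= step_onset_ms + 13
  if (max(trace$time_ms) < step_onset_ms + 13)
    stop("trace ends before the 13 ms fitting window")
  fit <- fit_single_exp(trace$time_ms[w], trace$v_mV[w],
                        t0 = step_onset_ms + 0.5)
  if (!fit$converged) warning("membrane tau fit did not converge")
  fit$tau
}

#' Fit the HCN activation curve from voltage-clamp steps
#'
#' For each clamp step from `v1` to `v2`, the slow HCN current change
#' `DeltaI_H` is measured by fitting a single exponential to the clamp
#' current from 15 ms after step onset to its end. The conductance
#' difference constraint `g(v2) - g(v1) = DeltaI_H / (v2 - E_H)` is then fit
#' by least squares with a Boltzmann curve reflected along the vertical
#' axis, `g(v) = g_max / (1 + exp((v - v_half)/s))`, with the HCN reversal
#' fixed at `E_H = -35` mV.
#'
#' @param data Tibble with columns `step`, `time_ms` (from step onset),
#'   `i_nA`, `v1`, `v2`; at least four distinct step amplitudes covering
#'   the activation range.
#' @param e_h HCN reversal potential (mV).
#' @param fit_start_ms Start of the exponential fitting window (ms after
#'   step onset).
#' @return An `hcn_fit` object; see [tidy.hcn_fit()].
#' @export
fit_hcn_activation <- function(data, e_h = -35, fit_start_ms = 15) {
  stopifnot(all(c("step", "time_ms", "i_nA", "v1", "v2") %in% names(data)))
  steps <- dplyr::distinct(dplyr::select(tibble::as_tibble(data),
                                         "step", "v1", "v2"))
  if (nrow(steps) < 4)
    warning("fewer than four step amplitudes; activation fit is ",
            "low-confidence")
  per_step <- purrr::map_dfr(seq_len(nrow(steps)), function(k) {
    d <- data[data$step == steps$step[k] & data$time_ms >= fit_start_ms, ]
    f <- fit_single_exp(d$time_ms, d$i_nA, t0 = 0)
    tibble::tibble(step = steps$step[k], v1 = steps$v1[k], v2 = steps$v2[k],
                   delta_i_nA = -f$amp, tau_ms = f$tau,
                   converged = f$converged)
  })
  # conductance-difference constraints in nS
  per_step$dg_nS <- per_step$delta_i_nA * 1000 / (per_step$v2 - e_h)
  span <- diff(range(c(per_step$v1, per_step$v2)))
  flagged <- span < 20 || any(!per_step$converged)
  dg_scale <- max(abs(per_step$dg_nS))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dg_nS ~ g_max / (1 + exp((v2 - v_half) / s)) -
        g_max / (1 + exp((v1 - v_half) / s)),
      data = per_step,
      start = list(g_max = max(dg_scale * 1.5, 1e-3), v_half = -78, s = 10),
      lower = c(0, -150, 0.5), upper = c(Inf, 0, 60),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || dg_scale < 1e-6) {
    cf <- c(g_max = 0, v_half = NA_real_, s = NA_real_)
    r2 <- NA_real_
    flagged <- TRUE
  } else {
    cf <- coef(fit)
    res <- per_step$dg_nS - predict(fit)
    r2 <- 1 - sum(res^2) / max(sum((per_step$dg_nS - mean(per_step$dg_nS))^2),
                               .Machine$double.eps)
  }
  structure(list(g_max_nS = unname(cf["g_max"]),
                 v_half_mV = unname(cf["v_half"]), s_mV = unname(cf["s"]),
                 e_h_mV = e_h, r_squared = r2, per_step = per_step,
                 flagged = flagged),
            class = "hcn_fit")
}

#' @export
print.hcn_fit <- function(x, ...) {
  cat("<hcn_fit> g_max = ", signif(x$g_max_nS, 4), " nS, v_half = ",
      signif(x$v_half_mV, 5), " mV, s = ", signif(x$s_mV, 4),
      " mV (E_H = ", x$e_h_mV, " mV), R^2 = ", signif(x$r_squared, 3),
      if (x$flagged) " [flagged]", "\n", sep = "")
  invisible(x)
}

#' Tidy an HCN activation fit
#'
#' @param x An `hcn_fit` object.
#' @param ... Unused.
#' @return A tibble of parameter estimates.
#' @exportS3Method generics::tidy
tidy.hcn_fit <- function(x, ...) {
  tibble::tibble(term = c("g_max_nS", "v_half_mV", "s_mV"),
                 estimate = c(x$g_max_nS, x$v_half_mV, x$s_mV))
}

#' @exportS3Method generics::glance
glance.hcn_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, e_h_mV = x$e_h_mV,
                 n_steps = nrow(x$per_step), flagged = x$flagged)
}

#' Fit the HCN time-constant curve
#'
#' Fits the symmetric bell `tau(v) = tau_max / (0.5 (exp((v - v_peak)/s) +
#' exp((v_peak - v)/s))) + tau_min` to per-potential time constants (from
#' single-exponential fits to clamp currents at hyperpolarizing and
#' depolarizing steps).
#'
#' @param data Tibble with `v_mV`, `tau_ms`.
#' @param tau_min Fixed minimal activation time (ms), or `NULL` to fit it.
#' @return An `hcn_tau_fit` with elements `tau_max_ms`, `tau_min_ms`,
#'   `v_peak_mV`, `steepness_mV`, `r_squared`.
#' @export
fit_hcn_tau <- function(data, tau_min = NULL) {
  stopifnot(all(c("v_mV", "tau_ms") %in% names(data)))
  v_peak0 <- data$v_mV[which.max(data$tau_ms)]
  tmax0 <- max(data$tau_ms)
  fit <- if (is.null(tau_min)) {
    minpack.lm::nlsLM(
      tau_ms ~ tau_max / (0.5 * (exp((v_mV - v_peak) / s) +
                                 exp((v_peak - v_mV) / s))) + tmin,
      data = data,
      start = list(tau_max = tmax0, v_peak = v_peak0, s = 20, tmin = 20),
      lower = c(1, -150, 2, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10))
  } else {
    minpack.lm::nlsLM(
      tau_ms ~ tau_max / (0.5 * (exp((v_mV - v_peak) / s) +
                                 exp((v_peak - v_mV) / s))) + tau_min,
      data = data,
      start = list(tau_max = tmax0, v_peak = v_peak0, s = 20),
      lower = c(1, -150, 2),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10))
  }
  cf <- coef(fit)
  res <- data$tau_ms - predict(fit)
  structure(list(tau_max_ms = unname(cf["tau_max"]),
                 tau_min_ms = if (is.null(tau_min)) unname(cf["tmin"])
                              else tau_min,
                 v_peak_mV = unname(cf["v_peak"]),
                 steepness_mV = unname(cf["s"]),
                 r_squared = 1 - sum(res^2) /
                   sum((data$tau_ms - mean(data$tau_ms))^2)),
            class = "hcn_tau_fit")
}

#' @exportS3Method generics::tidy
tidy.hcn_tau_fit <- function(x, ...) {
  tibble::tibble(term = c("tau_max_ms", "tau_min_ms", "v_peak_mV",
                          "steepness_mV"),
                 estimate = c(x$tau_max_ms, x$tau_min_ms, x$v_peak_mV,
                              x$steepness_mV))
}

#' Simulated-EPSP current waveform
#'
#' `I(t) = A (1 - exp(-t/tau1)) exp(1 - t/tau2)` with rising time constant
#' `tau1 = 0.3` ms and falling time constant `tau2 = 3.0` ms; zero for
#' `t < 0`. Peak occurs at `tau1 * log(1 + tau2/tau1)`.
#'
#' @param t Time from pulse onset (ms); vectorized.
#' @param A Peak-amplitude parameter (nA).
#' @param tau1,tau2 Rise and decay time constants (ms).
#' @return Current (nA).
#' @export
sepsp_current <- function(t, A = 1, tau1 = 0.3, tau2 = 3) {
  ifelse(t < 0, 0, A * (1 - exp(-t / tau1)) * exp(1 - t / tau2))
}

#' Temporal summation of a simulated-EPSP train
#'
#' For a series of five sEPSP current injections, summation is the ratio
#' `(p5 - p1)/p1`, where `p1` and `p5` are the peak membrane-potential
#' amplitudes relative to rest during the first and fifth sEPSP.
#'
#' @param trace Data frame with `time_ms`, `v_mV`.
#' @param pulse_times Onset times of the five pulses (ms).
#' @param rest Resting potential; defaults to the voltage just before the
#'   first pulse.
#' @param window_ms Search window for each peak after pulse onset.
#' @return A one-row tibble with `summation`, `p1_mV`, `p5_mV`.
#' @export
sepsp_summation <- function(trace, pulse_times, rest = NULL,
                            window_ms = NULL) {
  if (length(pulse_times) < 5)
    stop("summation requires five pulses")
  pulse_times <- sort(pulse_times)
  if (is.null(window_ms))
    window_ms <- min(diff(pulse_times))
  if (is.null(rest))
    rest <- trace$v_mV[max(which(trace$time_ms <= pulse_times[1]))]
  peak_in <- function(t0) {
    w <- trace$time_ms >= t0 & trace$time_ms <= t0 + window_ms
    max(trace$v_mV[w]) - rest
  }
  p1 <- peak_in(pulse_times[1])
  p5 <- peak_in(pulse_times[5])
  tibble::tibble(summation = (p5 - p1) / p1, p1_mV = p1, p5_mV = p5)
}

#' Integrated voltage normalized by integrated current
#'
#' `int (V - rest) dt / int I dt`, in mV ms / nA ms = MOhm: an effective
#' input resistance for arbitrary current waveforms, directly comparable to
#' the step input resistance.
#'
#' @param trace Data frame with `time_ms`, `v_mV`, `i_nA`.
#' @param rest Resting potential (defaults to the first sample).
#' @return Normalized integral (MOhm).
#' @export
normalized_integral <- function(trace, rest = NULL) {
  stopifnot(all(c("time_ms", "v_mV", "i_nA") %in% names(trace)))
  if (is.null(rest)) rest <- trace$v_mV[1]
  dt <- diff(trace$time_ms)
  mid <- function(x) (x[-1] + x[-length(x)]) / 2
  qv <- sum(mid(trace$v_mV - rest) * dt)
  qi <- sum(mid(trace$i_nA) * dt)
  if (abs(qi) < .Machine$double.eps * 100)
    stop("total injected charge is zero")
  qv / qi
}

#' Smoothed instantaneous firing rate
#'
#' Convolves the spike raster with a Gaussian kernel (20 ms standard
#' deviation by default); the kernel integrates to one spike, so the
#' integral of the rate equals the spike count.
#'
#' @param spike_times Spike times (ms).
#' @param t_range Time range `c(from, to)` of the evaluated rate (ms).
#' @param kernel_sd_ms Kernel standard deviation (ms).
#' @param dt_ms Evaluation grid step (ms).
#' @return A tibble: `time_ms`, `rate_spk_s`.
#' @export
firing_rate <- function(spike_times, t_range = NULL, kernel_sd_ms = 20,
                        dt_ms = 1) {
  if (is.null(t_range)) {
    t_range <- if (length(spike_times)) range(spike_times) +
      c(-4, 4) * kernel_sd_ms else c(0, 1)
  }
  tt <- seq(t_range[1], t_range[2], by = dt_ms)
  rate <- rep(0, length(tt))
  for (s in spike_times)
    rate <- rate + stats::dnorm(tt, mean = s, sd = kernel_sd_ms)
  tibble::tibble(time_ms = tt, rate_spk_s = rate * 1000)
}

#' Spike count and peak firing rate of a looming response
#'
#' Spike count over the response window (start of the stimulus until the
#' projected collision time) and the peak of the Gaussian-smoothed firing
#' rate, evaluated on a 1 ms grid.
#'
#' @param spike_times Spike times (ms).
#' @param window `c(start, end)` of the counting window (ms).
#' @param kernel_sd_ms Kernel standard deviation for the peak rate.
#' @return A one-row tibble: `spike_count`, `peak_rate_spk_s`.
#' @export
response_metrics <- function(spike_times, window, kernel_sd_ms = 20) {
  inw <- spike_times[spike_times >= window[1] & spike_times <= window[2]]
  if (length(inw) == 0)
    return(tibble::tibble(spike_count = 0L, peak_rate_spk_s = 0))
  fr <- firing_rate(inw, t_range = window, kernel_sd_ms = kernel_sd_ms)
  tibble::tibble(spike_count = length(inw),
                 peak_rate_spk_s = max(fr$rate_spk_s))
}

#' Coherence preference (selectivity slope)
#'
#' The slope of the ordinary-least-squares fit of spike count against
#' stimulus coherence, in spikes per percent coherence, with the Pearson
#' correlation coefficient of the relationship.
#'
#' @param data A data frame with coherence (%) and response columns.
#' @param coherence,response Column names.
#' @return A `coherence_preference` object wrapping the `lm` fit; `tidy()`
#'   returns slope/intercept, `glance()` slope, Pearson r and p-value.
#' @export
coherence_preference <- function(data, coherence = "coherence",
                                 response = "spike_count") {
  x <- data[[coherence]]; y <- data[[response]]
  if (length(unique(x)) < 3)
    stop("at least three coherence levels are required")
  if (sd(x) == 0) stop("degenerate coherence values")
  fit <- lm(y ~ x)
  ct <- if (sd(y) > 0) stats::cor.test(x, y) else
    list(estimate = c(cor = 0), p.value = NA_real_)
  structure(list(fit = fit, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 slope_se = summary(fit)$coefficients[2, 2],
                 data = tibble::tibble(coherence = x, response = y)),
            class = "coherence_preference")
}

#' @export
print.coherence_preference <- function(x, ...) {
  cat("<coherence_preference> slope = ", signif(x$slope, 4),
      " spikes/% coherence (r = ", signif(x$pearson_r, 3), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.coherence_preference <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std_error = summary(x$fit)$coefficients[, 2])
}

#' @exportS3Method generics::glance
glance.coherence_preference <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_se = x$slope_se,
                 pearson_r = x$pearson_r, p_value = x$p_value,
                 n = nrow(x$data))
}

#' Sustained/transient spike split
#'
#' The instantaneous firing frequency (1/ISI) is attached to each
#' inter-spike interval; the longest contiguous period in which it stays
#' above threshold (ties broken by the earliest period) defines the
#' "sustained" spikes (the bounding spikes included); all other spikes are
#' "transient".
#'
#' @param spike_times Spike times (ms), increasing.
#' @param threshold_spk_s Threshold (spk/s).
#' @return A one-row tibble: `sustained`, `transient`.
#' @export
sustained_transient_split <- function(spike_times, threshold_spk_s = 20) {
  n <- length(spike_times)
  if (n < 2) return(tibble::tibble(sustained = 0L, transient = n))
  isi <- diff(spike_times)
  supra <- (1000 / isi) > threshold_spk_s
  r <- rle(supra)
  if (!any(r$values))
    return(tibble::tibble(sustained = 0L, transient = n))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]   # which.max takes the earliest tie
  n_sus <- r$lengths[best] + 1L              # intervals -> bounding spikes
  tibble::tibble(sustained = n_sus, transient = n - n_sus)
}

#' Normalize responses to each unit's control maximum
#'
#' Divides the response amplitude for each stimulus by that unit's maximal
#' response amplitude under control conditions, so the control maximum maps
#' to 1 and drug conditions are scaled by the same factor.
#'
#' @param data A data frame.
#' @param response,animal,condition Column names.
#' @param control Value of `condition` identifying control rows.
#' @return The input with an added `normalized` column.
#' @export
normalize_responses <- function(data, response = "spike_count",
                                animal = "animal", condition = "condition",
                                control = "control") {
  df <- tibble::as_tibble(data)
  stopifnot(all(c(response, animal, condition) %in% names(df)))
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(animal))) |>
    dplyr::group_modify(function(g, key) {
      ctrl <- g[[response]][g[[condition]] == control]
      if (length(ctrl) == 0)
        stop("no control rows for a unit; cannot normalize")
      m <- max(ctrl)
      if (m == 0) stop("zero control maximum; cannot normalize")
      g$normalized <- g[[response]] / m
      g
    }) |>
    dplyr::ungroup()
}
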