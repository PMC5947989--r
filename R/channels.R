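#' Boltzmann steady-state activation curve
#'
#' For HCN conductances the curve is reflected along the vertical axis
#' (activation decreases with depolarization):
#' `g(v) = scale / (1 + exp((v - v_half)/s))` for `direction = "decreasing"`,
#' and `scale / (1 + exp(-(v - v_half)/s))` for `direction = "increasing"`.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param v_half Half-activation potential (mV).
#' @param s Steepness (mV), strictly positive.
#' @param direction `"increasing"` or `"decreasing"` in `v`.
#' @param scale Maximal value (1 for a gating fraction, or a maximal
#'   conductance).
#' @return Steady-state value, in `[0, scale]`.
#' @export
boltzmann <- function(v, v_half, s, direction = c("increasing", "decreasing"),
                      scale = 1) {
  direction <- match.arg(direction)
  if (s == 0) stop("steepness s must be nonzero")
  z <- (v - v_half) / s
  if (direction == "decreasing") scale / (1 + exp(z)) else scale / (1 + exp(-z))
}

#' Symmetric bell-shaped voltage dependence of a time constant
#'
#' `tau(v) = tau_max / (0.5 * (exp((v - v_peak)/steepness) +
#' exp((v_peak - v)/steepness))) + tau_min`: symmetric with respect to its
#' maximum `tau_max + tau_min`, attained at `v_peak`.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param tau_max Peak amplitude above `tau_min` (ms).
#' @param tau_min Offset (ms).
#' @param v_peak Membrane potential with the slowest kinetics (mV).
#' @param steepness Width parameter (mV), strictly positive.
#' @return Time constant in ms.
#' @export
symmetric_tau <- function(v, tau_max, tau_min, v_peak, steepness) {
  if (steepness == 0) stop("steepness must be nonzero")
  z <- (v - v_peak) / steepness
  tau_max / (0.5 * (exp(z) + exp(-z))) + tau_min
}

#' HCN steady-state conductance and activation time constant
#'
#' The steady-state HCN conductance follows a Boltzmann curve reflected
#' along the vertical axis (maximal when hyperpolarized); its activation
#' time constant is a symmetric bell. Defaults are the experimentally fitted
#' values: `v_half = -77.6` mV with 28% of maximal activation at the
#' resting potential of -65 mV, and a time-constant peak of 1.34 s at
#' -83 mV with 20 mV steepness.
#'
#' @param v Membrane potential (mV).
#' @param v_half,s Boltzmann parameters (mV).
#' @param g_max Maximal conductance (any unit; 1 gives the open fraction).
#' @param tau_max,tau_min,v_peak,steepness Bell parameters of the time
#'   constant (ms, ms, mV, mV).
#' @return `hcn_steady_state()`: conductance in units of `g_max`;
#'   `hcn_tau()`: ms.
#' @export
hcn_steady_state <- function(v, v_half = -77.6, s = 13.34, g_max = 1) {
  boltzmann(v, v_half, s, direction = "decreasing", scale = g_max)
}

#' @rdname hcn_steady_state
#' @export
hcn_tau <- function(v, tau_max = 1340, tau_min = 50, v_peak = -83,
                    steepness = 20) {
  symmetric_tau(v, tau_max, tau_min, v_peak, steepness)
}

#' Construct a gate specification
#'
#' A first-order gating variable with a Boltzmann steady state and either a
#' constant or a symmetric bell-shaped time constant; calcium-gated
#' variables use a saturating function of the local calcium pool instead.
#'
#' @param power Exponent of the gate in the conductance product.
#' @param v_half,s Steady-state Boltzmann parameters (mV); for
#'   `kind = "calcium"`, `v_half` is the half-activation concentration.
#' @param direction `"increasing"` or `"decreasing"` with voltage.
#' @param tau Either a single number (ms) or a list
#'   `list(tau_max=, tau_min=, v_peak=, steepness=)`.
#' @param kind `"voltage"` or `"calcium"`.
#' @return A `gate_spec` list.
#' @export
gate_spec <- function(power = 1, v_half, s = 1,
                      direction = c("increasing", "decreasing"),
                      tau = 1, kind = c("voltage", "calcium")) {
  direction <- match.arg(direction)
  kind <- match.arg(kind)
  if (is.numeric(tau) && length(tau) == 1) {
    tau <- list(type = "constant", tau = tau)
  } else {
    stopifnot(all(c("tau_max", "tau_min", "v_peak", "steepness") %in% names(tau)))
    tau$type <- "bell"
  }
  structure(list(power = power, v_half = v_half, s = s, direction = direction,
                 tau = tau, kind = kind), class = "gate_spec")
}

#' Construct a channel specification
#'
#' @param name Channel name.
#' @param e_rev Reversal potential (mV).
#' @param gates A list of [gate_spec()] objects (activation first, optional
#'   inactivation second).
#' @param ca_source Whether this channel's current feeds the calcium pool.
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(name, e_rev, gates, ca_source = FALSE) {
  stopifnot(is.character(name), length(gates) >= 1)
  structure(list(name = name, e_rev = e_rev, gates = gates,
                 ca_source = ca_source), class = "channel_spec")
}

gate_inf <- function(gate, v, ca = 0) {
  if (gate$kind == "calcium") return(ca / (ca + gate$v_half))
  boltzmann(v, gate$v_half, gate$s, direction = gate$direction)
}

gate_tau <- function(gate, v) {
  if (gate$tau$type == "constant") return(rep_len(gate$tau$tau, length(v)))
  symmetric_tau(v, gate$tau$tau_max, gate$tau$tau_min, gate$tau$v_peak,
                gate$tau$steepness)
}

#' Advance a gating variable by exact exponential relaxation
#'
#' First-order relaxation toward the voltage- (or calcium-) dependent steady
#' state: `x <- x_inf + (x - x_inf) * exp(-dt/tau(v))`. Unconditionally
#' stable for any `dt` and exact for constant `v`.
#'
#' @param x Current gate value in `[0, 1]`.
#' @param v Membrane potential (mV).
#' @param dt Time step (ms), positive.
#' @param gate A [gate_spec()].
#' @param ca Calcium concentration, for calcium-gated variables.
#' @return Updated gate value.
#' @export
advance_gate <- function(x, v, dt, gate, ca = 0) {
  stopifnot(dt > 0)
  xinf <- gate_inf(gate, v, ca)
  xinf + (x - xinf) * exp(-dt / gate_tau(gate, v))
}

#' Ohmic channel current
#'
#' `I = g_bar * prod(gates^powers) * (v - e_rev)`, outward positive.
#'
#' @param v Membrane potential (mV).
#' @param gates Numeric vector of gate values in `[0, 1]`.
#' @param g_bar Maximal conductance; with nS the current is in pA, with uS
#'   in nA.
#' @param e_rev Reversal potential (mV).
#' @param powers Gate exponents (default all 1).
#' @return Current (outward positive), in `g_bar` units times mV.
#' @export
channel_current <- function(v, gates, g_bar, e_rev, powers = rep(1, length(gates))) {
  stopifnot(all(gates >= 0 & gates <= 1))
  g_bar * prod(gates^powers) * (v - e_rev)
}

#' Default channel library
#'
#' The conductance complement of the model: HCN (field A, experimentally
#' fitted kinetics), a slowly inactivating low-threshold K+ conductance
#' (K_D-like, field A), fast Na+ and delayed-rectifier K+ (spike initiation
#' zone and axon; dendrites carry no fast Na+), a non-inactivating M-type
#' K+ conductance, and low-threshold Ca2+ (Ca_T) with a calcium-dependent
#' K+ conductance (K_Ca) at the spike initiation zone. Kinetic variants
#' scale the HCN activation and K_D-like inactivation peak time constants
#' ten-fold in either direction: default 1.35 s / 1.05 s, fast 135 ms /
#' 105 ms, slow 13.5 s / 10.5 s.
#'
#' @param variant `"default"`, `"fast"` or `"slow"`.
#' @param hcn_v_half HCN half-activation (mV); -77.6 fitted, -73.4 after
#'   cAMP modulation.
#' @param hcn_s HCN steepness (mV), chosen so resting activation at -65 mV
#'   is 28% of maximum.
#' @return Named list of [channel_spec()] objects.
#' @export
default_channel_library <- function(variant = c("default", "fast", "slow"),
                                    hcn_v_half = -77.6, hcn_s = 13.34) {
  variant <- match.arg(variant)
  scale <- switch(variant, default = 1, fast = 0.1, slow = 10)
  list(
    HCN = channel_spec("HCN", e_rev = -35, gates = list(
      gate_spec(1, v_half = hcn_v_half, s = hcn_s, direction = "decreasing",
                tau = list(tau_max = 1350 * scale, tau_min = 50,
                           v_peak = -83, steepness = 20)))),
    KD = channel_spec("KD", e_rev = -80, gates = list(
      gate_spec(1, v_half = -70, s = 5, direction = "increasing", tau = 2),
      gate_spec(1, v_half = -52, s = 5, direction = "decreasing",
                tau = list(tau_max = 1050 * scale, tau_min = 40,
                           v_peak = -65, steepness = 7)))),
    Na = channel_spec("Na", e_rev = 50, gates = list(
      gate_spec(3, v_half = -40, s = 4.5, direction = "increasing", tau = 0.08),
      gate_spec(1, v_half = -48, s = 5, direction = "decreasing",
                tau = list(tau_max = 4, tau_min = 0.3, v_peak = -52,
                           steepness = 12)))),
    KDR = channel_spec("KDR", e_rev = -80, gates = list(
      gate_spec(4, v_half = -35, s = 9, direction = "increasing",
                tau = list(tau_max = 3, tau_min = 0.6, v_peak = -50,
                           steepness = 25)))),
    M = channel_spec("M", e_rev = -80, gates = list(
      gate_spec(1, v_half = -45, s = 8, direction = "increasing", tau = 200))),
    CaT = channel_spec("CaT", e_rev = 120, ca_source = TRUE, gates = list(
      gate_spec(2, v_half = -55, s = 6, direction = "increasing", tau = 3),
      gate_spec(1, v_half = -70, s = 5, direction = "decreasing",
                tau = list(tau_max = 300, tau_min = 50, v_peak = -70,
                           steepness = 15)))),
    KCa = channel_spec("KCa", e_rev = -80, gates = list(
      gate_spec(1, v_half = 0.5, kind = "calcium", tau = 20)))
  )
}

# flatten a channel spec to the gate-parameter matrix consumed by the C++
# integrator: power, kind, vhalf, s, sign, tautype, p1..p4
channel_gate_matrix <- function(spec) {
  rows <- lapply(spec$gates, function(g) {
    sign <- if (g$direction == "increasing") 1 else -1
    if (g$tau$type == "constant") {
      c(g$power, if (g$kind == "calcium") 1 else 0, g$v_half, g$s, sign,
        0, g$tau$tau, 0, 0, 0)
    } else {
      c(g$power, if (g$kind == "calcium") 1 else 0, g$v_half, g$s, sign,
        1, g$tau$tau_max, g$tau$tau_min, g$tau$v_peak, g$tau$steepness)
    }
  })
  do.call(rbind, rows)
}
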