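// Branched compartmental cable integrator: Crank-Nicolson voltage update with
// a Hines-ordered tree solve, Rush-Larsen exponential integration of channel
// gates, double-exponential synaptic conductances, ideal voltage clamp, a
// first-order calcium pool, and online spike detection.
//
// Units: mV, ms, nA, uS (microsiemens), nF. uS * mV = nA; nF * mV / ms = nA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline double safe_exp(double x) {
  if (x > 50.0) x = 50.0;
  if (x < -50.0) x = -50.0;
  return std::exp(x);
}

struct Gate {
  double power;
  int kind;      // 0 voltage-gated, 1 calcium-gated
  double vhalf;  // mV (or Kd in concentration units for kind 1)
  double s;      // mV
  int sign;      // +1 activation increases with v, -1 decreases
  int tautype;   // 0 constant, 1 symmetric bell
  double p1, p2, p3, p4;  // const: p1 = tau; bell: tau_max, tau_min, v_peak, steepness

  double inf(double v, double ca) const {
    if (kind == 1) return ca / (ca + vhalf);
    double z = (v - vhalf) / s;
    return sign > 0 ? 1.0 / (1.0 + safe_exp(-z)) : 1.0 / (1.0 + safe_exp(z));
  }
  double tau(double v) const {
    if (tautype == 0) return p1;
    double z = (v - p3) / p4;
    return p1 / (0.5 * (safe_exp(z) + safe_exp(-z))) + p2;
  }
};

struct Channel {
  double erev;
  bool ca_source;
  std::vector<int> comps;
  std::vector<double> gbar;          // uS
  std::vector<Gate> gates;
  std::vector<std::vector<double>> state;  // [gate][active index]
  std::vector<double> gnow;          // uS, open conductance this step
};

static Channel parse_channel(const List& ch) {
  Channel c;
  c.erev = as<double>(ch["erev"]);
  c.ca_source = as<bool>(ch["ca_source"]);
  IntegerVector comps = ch["comps"];
  NumericVector gbar = ch["gbar"];
  c.comps.assign(comps.begin(), comps.end());
  c.gbar.assign(gbar.begin(), gbar.end());
  NumericMatrix gm = ch["gates"];
  for (int r = 0; r < gm.nrow(); ++r) {
    Gate g;
    g.power = gm(r, 0);
    g.kind = (int)gm(r, 1);
    g.vhalf = gm(r, 2);
    g.s = gm(r, 3);
    g.sign = (int)gm(r, 4);
    g.tautype = (int)gm(r, 5);
    g.p1 = gm(r, 6); g.p2 = gm(r, 7); g.p3 = gm(r, 8); g.p4 = gm(r, 9);
    c.gates.push_back(g);
  }
  c.state.assign(c.gates.size(), std::vector<double>(c.comps.size(), 0.0));
  c.gnow.assign(c.comps.size(), 0.0);
  return c;
}

// [[Rcpp::export]]
List simulate_cable_cpp(List net, List channel_list, List protocol,
                        List record) {
  // --- network ---
  IntegerVector parent_r = net["parent"];      // 0-based, -1 for root, sorted
  NumericVector cm = net["cm"];                // nF
  NumericVector g_leak = net["g_leak"];        // uS
  NumericVector e_leak = net["e_leak"];        // mV (per compartment)
  NumericVector g_ax = net["g_axial"];         // uS, edge to parent
  NumericVector v0 = net["v_init"];
  int N = parent_r.size();
  std::vector<int> parent(parent_r.begin(), parent_r.end());
  for (int i = 1; i < N; ++i)
    if (parent[i] < 0 || parent[i] >= i)
      stop("compartments must be topologically ordered (parent index < child)");

  std::vector<double> sum_gax(N, 0.0);
  for (int i = 1; i < N; ++i) {
    sum_gax[i] += g_ax[i];
    sum_gax[parent[i]] += g_ax[i];
  }

  std::vector<Channel> channels;
  for (int k = 0; k < channel_list.size(); ++k)
    channels.push_back(parse_channel(channel_list[k]));

  // --- calcium pools ---
  bool has_ca = net.containsElementNamed("calcium") &&
                !Rf_isNull(net["calcium"]);
  std::vector<double> ca(N, 0.0);
  double ca_tau = 150.0, ca_rest = 5e-2, ca_phi = 0.0;
  if (has_ca) {
    List cal = net["calcium"];
    ca_tau = as<double>(cal["tau"]);
    ca_rest = as<double>(cal["rest"]);
    ca_phi = as<double>(cal["phi"]);
  }
  std::fill(ca.begin(), ca.end(), ca_rest);

  // --- protocol ---
  double dt = as<double>(protocol["dt"]);
  int n_steps = as<int>(protocol["n_steps"]);
  double settle_ms = protocol.containsElementNamed("settle_ms")
                         ? as<double>(protocol["settle_ms"]) : 0.0;
  double settle_dt = protocol.containsElementNamed("settle_dt")
                         ? as<double>(protocol["settle_dt"]) : 0.5;

  // current injections: step sources
  std::vector<int> ic_comp; std::vector<double> ic_on, ic_off, ic_amp;
  if (protocol.containsElementNamed("iclamp") &&
      !Rf_isNull(protocol["iclamp"])) {
    NumericMatrix ic = protocol["iclamp"];  // comp(0-based), onset, dur, amp
    for (int r = 0; r < ic.nrow(); ++r) {
      ic_comp.push_back((int)ic(r, 0));
      ic_on.push_back(ic(r, 1));
      ic_off.push_back(ic(r, 1) + ic(r, 2));
      ic_amp.push_back(ic(r, 3));
    }
  }
  // arbitrary injected waveform at one compartment
  int wave_comp = -1;
  NumericVector wave;
  if (protocol.containsElementNamed("iwave") && !Rf_isNull(protocol["iwave"])) {
    List iw = protocol["iwave"];
    wave_comp = as<int>(iw["comp"]);
    wave = as<NumericVector>(iw["wave"]);
    if (wave.size() < n_steps) stop("iwave shorter than simulation");
  }
  // ideal voltage clamp
  int vc_comp = -1;
  NumericVector vc_wave;
  if (protocol.containsElementNamed("vclamp") &&
      !Rf_isNull(protocol["vclamp"])) {
    List vc = protocol["vclamp"];
    vc_comp = as<int>(vc["comp"]);
    vc_wave = as<NumericVector>(vc["wave"]);
    if (vc_wave.size() < n_steps) stop("vclamp command shorter than simulation");
  }
  // synaptic events
  bool has_syn = protocol.containsElementNamed("synapses") &&
                 !Rf_isNull(protocol["synapses"]);
  std::vector<int> ev_step, ev_comp;
  std::vector<double> ev_w;
  double syn_tr = 0.3, syn_td = 3.0, syn_erev = 0.0, syn_norm = 1.0;
  if (has_syn) {
    List sy = protocol["synapses"];
    IntegerVector es = sy["step"], ecm = sy["comp"];
    NumericVector ew = sy["g"];
    ev_step.assign(es.begin(), es.end());
    ev_comp.assign(ecm.begin(), ecm.end());
    ev_w.assign(ew.begin(), ew.end());
    syn_tr = as<double>(sy["tau_rise"]);
    syn_td = as<double>(sy["tau_decay"]);
    syn_erev = as<double>(sy["e_rev"]);
    double tp = syn_tr * syn_td / (syn_td - syn_tr) * std::log(syn_td / syn_tr);
    syn_norm = std::exp(-tp / syn_td) - std::exp(-tp / syn_tr);
  }

  // --- recording ---
  IntegerVector rec_comps = record["comps"];  // 0-based
  int rec_every = as<int>(record["every"]);
  int n_rec = rec_comps.size();
  int n_samples = n_steps / rec_every + 1;
  NumericMatrix v_out(n_rec, n_samples);
  NumericVector t_out(n_samples);
  NumericVector iclamp_out(vc_comp >= 0 ? n_samples : 0);

  // weighted gate recordings: list of (channel, gate, weights[N])
  std::vector<int> gr_ch, gr_gate;
  std::vector<std::vector<double>> gr_w;
  if (record.containsElementNamed("gates") && !Rf_isNull(record["gates"])) {
    List gl = record["gates"];
    for (int k = 0; k < gl.size(); ++k) {
      List e = gl[k];
      gr_ch.push_back(as<int>(e["channel"]));
      gr_gate.push_back(as<int>(e["gate"]));
      NumericVector w = e["weights"];
      gr_w.push_back(std::vector<double>(w.begin(), w.end()));
    }
  }
  NumericMatrix gates_out((int)gr_ch.size(), n_samples);

  // channel total-current recordings: list of (channel, weights[N])
  std::vector<int> cr_ch;
  std::vector<std::vector<double>> cr_w;
  if (record.containsElementNamed("currents") &&
      !Rf_isNull(record["currents"])) {
    List cl = record["currents"];
    for (int k = 0; k < cl.size(); ++k) {
      List e = cl[k];
      cr_ch.push_back(as<int>(e["channel"]));
      NumericVector w = e["weights"];
      cr_w.push_back(std::vector<double>(w.begin(), w.end()));
    }
  }
  NumericMatrix curr_out((int)cr_ch.size(), n_samples);

  // spike detection
  int spike_comp = -1;
  double spike_thresh = -15.0, spike_refrac = 2.0;
  if (record.containsElementNamed("spikes") && !Rf_isNull(record["spikes"])) {
    List sp = record["spikes"];
    spike_comp = as<int>(sp["comp"]);
    spike_thresh = as<double>(sp["threshold"]);
    spike_refrac = as<double>(sp["refractory"]);
  }
  std::vector<double> spike_times;

  // --- state ---
  std::vector<double> V(N);
  if (v0.size() == 1) std::fill(V.begin(), V.end(), v0[0]);
  else for (int i = 0; i < N; ++i) V[i] = v0[i];

  for (auto& c : channels)
    for (size_t g = 0; g < c.gates.size(); ++g)
      for (size_t k = 0; k < c.comps.size(); ++k)
        c.state[g][k] = c.gates[g].inf(V[c.comps[k]], ca[c.comps[k]]);

  std::vector<double> synA(N, 0.0), synB(N, 0.0);
  std::vector<double> Gtot(N), GE(N), Iinj(N), d(N), b(N), a(N), Vnew(N);
  double decA = 0.0, decB = 0.0;
  if (has_syn) {
    decA = std::exp(-dt / syn_tr);
    decB = std::exp(-dt / syn_td);
  }

  size_t ev_ptr = 0;
  double last_spike = -1e9;
  bool above = false;
  int out_col = 0;

  // one integration step; returns clamp current if vclamp active
  auto do_step = [&](double t, double h, bool live) -> double {
    // synaptic state
    if (has_syn && live) {
      double dA = std::exp(-h / syn_tr), dB = std::exp(-h / syn_td);
      for (int i = 0; i < N; ++i) { synA[i] *= dA; synB[i] *= dB; }
      (void)decA; (void)decB;
      while (ev_ptr < ev_step.size() && ev_step[ev_ptr] * dt <= t + 1e-9) {
        int cc = ev_comp[ev_ptr];
        double w = ev_w[ev_ptr] / syn_norm;
        synA[cc] += w;
        synB[cc] += w;
        ++ev_ptr;
      }
    }

    std::fill(Gtot.begin(), Gtot.end(), 0.0);
    std::fill(GE.begin(), GE.end(), 0.0);
    std::fill(Iinj.begin(), Iinj.end(), 0.0);

    // gates (Rush-Larsen) and channel conductances
    for (auto& c : channels) {
      size_t na = c.comps.size(), ng = c.gates.size();
      for (size_t k = 0; k < na; ++k) {
        int i = c.comps[k];
        double gp = c.gbar[k];
        for (size_t g = 0; g < ng; ++g) {
          const Gate& gg = c.gates[g];
          double xinf = gg.inf(V[i], ca[i]);
          double tau = gg.tau(V[i]);
          double x = xinf + (c.state[g][k] - xinf) * std::exp(-h / tau);
          c.state[g][k] = x;
          gp *= (gg.power == 1.0) ? x
               : (gg.power == 2.0) ? x * x
               : (gg.power == 3.0) ? x * x * x
               : (gg.power == 4.0) ? x * x * x * x
                                   : std::pow(x, gg.power);
        }
        c.gnow[k] = gp;
        Gtot[i] += gp;
        GE[i] += gp * c.erev;
      }
    }
    for (int i = 0; i < N; ++i) {
      Gtot[i] += g_leak[i];
      GE[i] += g_leak[i] * e_leak[i];
    }
    if (has_syn && live) {
      for (int i = 0; i < N; ++i) {
        double gs = synB[i] - synA[i];
        if (gs > 0) {
          Gtot[i] += gs;
          GE[i] += gs * syn_erev;
        }
      }
    }
    if (live) {
      for (size_t r = 0; r < ic_comp.size(); ++r)
        if (t >= ic_on[r] && t < ic_off[r]) Iinj[ic_comp[r]] += ic_amp[r];
      if (wave_comp >= 0) {
        int st = (int)std::floor(t / dt + 0.5);
        if (st < wave.size()) Iinj[wave_comp] += wave[st];
      }
    }

    // Crank-Nicolson tree solve
    for (int i = 0; i < N; ++i) {
      double cd = cm[i] / h;
      d[i] = cd + 0.5 * Gtot[i] + 0.5 * sum_gax[i];
      double ax = 0.0;
      if (i > 0) ax += g_ax[i] * (V[i] - V[parent[i]]);
      b[i] = (cd - 0.5 * Gtot[i] - 0.5 * sum_gax[i]) * V[i] + GE[i] + Iinj[i];
      a[i] = (i > 0) ? -0.5 * g_ax[i] : 0.0;
      (void)ax;
    }
    // axial RHS: +0.5 * sum_j g_ij V_j
    for (int i = 1; i < N; ++i) {
      b[i] += 0.5 * g_ax[i] * V[parent[i]];
      b[parent[i]] += 0.5 * g_ax[i] * V[i];
    }
    bool clamped = (vc_comp >= 0 && live);
    double cmd = 0.0;
    if (clamped) {
      int st = (int)std::floor(t / dt + 0.5);
      cmd = vc_wave[std::min(st, (int)vc_wave.size() - 1)];
      const double BIG = 1e12;
      d[vc_comp] += BIG;
      b[vc_comp] += BIG * cmd;
    }
    for (int i = N - 1; i >= 1; --i) {
      int p = parent[i];
      double f = a[i] / d[i];
      d[p] -= f * a[i];
      b[p] -= f * b[i];
    }
    Vnew[0] = b[0] / d[0];
    for (int i = 1; i < N; ++i)
      Vnew[i] = (b[i] - a[i] * Vnew[parent[i]]) / d[i];

    double iclamp = 0.0;
    if (clamped) {
      int e = vc_comp;
      double vm = 0.5 * (V[e] + Vnew[e]);
      double axial = 0.0;
      if (e > 0) axial += g_ax[e] * (vm - 0.5 * (V[parent[e]] + Vnew[parent[e]]));
      for (int i = 1; i < N; ++i)
        if (parent[i] == e)
          axial += g_ax[i] * (vm - 0.5 * (V[i] + Vnew[i]));
      iclamp = cm[e] / h * (Vnew[e] - V[e]) + Gtot[e] * vm - GE[e] + axial -
               Iinj[e];
    }

    // calcium pools driven by Ca channel currents
    if (has_ca) {
      for (auto& c : channels) {
        if (!c.ca_source) continue;
        for (size_t k = 0; k < c.comps.size(); ++k) {
          int i = c.comps[k];
          double vm = 0.5 * (V[i] + Vnew[i]);
          double ica = c.gnow[k] * (vm - c.erev);  // nA (inward negative)
          double ca_ss = ca_rest - ca_phi * ca_tau * ica;
          if (ca_ss < 0) ca_ss = 0;
          ca[i] = ca_ss + (ca[i] - ca_ss) * std::exp(-h / ca_tau);
        }
      }
    }

    std::copy(Vnew.begin(), Vnew.end(), V.begin());
    return iclamp;
  };

  // settle to steady state with coarse, unconditionally stable steps
  if (settle_ms > 0) {
    int ns = (int)std::ceil(settle_ms / settle_dt);
    for (int s = 0; s < ns; ++s) do_step(0.0, settle_dt, false);
  }

  // record initial sample
  t_out[0] = 0.0;
  for (int r = 0; r < n_rec; ++r) v_out(r, 0) = V[rec_comps[r]];
  for (size_t k = 0; k < gr_ch.size(); ++k) {
    const Channel& c = channels[gr_ch[k]];
    double acc = 0.0, wsum = 0.0;
    for (size_t j = 0; j < c.comps.size(); ++j) {
      double w = gr_w[k][c.comps[j]];
      acc += w * c.state[gr_gate[k]][j];
      wsum += w;
    }
    gates_out(k, 0) = wsum > 0 ? acc / wsum : NA_REAL;
  }
  out_col = 1;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    double ic = do_step(t, dt, true);

    if (spike_comp >= 0) {
      double vv = V[spike_comp];
      if (!above && vv >= spike_thresh) {
        double tt = t + dt;
        if (tt - last_spike >= spike_refrac) {
          spike_times.push_back(tt);
          last_spike = tt;
        }
        above = true;
      } else if (above && vv < spike_thresh) {
        above = false;
      }
    }

    if ((s + 1) % rec_every == 0 && out_col < n_samples) {
      t_out[out_col] = t + dt;
      for (int r = 0; r < n_rec; ++r) v_out(r, out_col) = V[rec_comps[r]];
      if (vc_comp >= 0) iclamp_out[out_col] = ic;
      for (size_t k = 0; k < gr_ch.size(); ++k) {
        const Channel& c = channels[gr_ch[k]];
        double acc = 0.0, wsum = 0.0;
        for (size_t j = 0; j < c.comps.size(); ++j) {
          double w = gr_w[k][c.comps[j]];
          acc += w * c.state[gr_gate[k]][j];
          wsum += w;
        }
        gates_out(k, out_col) = wsum > 0 ? acc / wsum : NA_REAL;
      }
      for (size_t k = 0; k < cr_ch.size(); ++k) {
        const Channel& c = channels[cr_ch[k]];
        double acc = 0.0;
        for (size_t j = 0; j < c.comps.size(); ++j)
          acc += cr_w[k][c.comps[j]] * c.gnow[j] * (V[c.comps[j]] - c.erev);
        curr_out(k, out_col) = acc;
      }
      ++out_col;
    }
  }

  // final gate states per channel (active compartments)
  List gate_final(channels.size());
  for (size_t k = 0; k < channels.size(); ++k) {
    const Channel& c = channels[k];
    NumericMatrix st(c.gates.size(), c.comps.size());
    for (size_t g = 0; g < c.gates.size(); ++g)
      for (size_t j = 0; j < c.comps.size(); ++j)
        st(g, j) = c.state[g][j];
    gate_final[k] = st;
  }

  return List::create(
      _["time"] = t_out, _["v"] = v_out,
      _["clamp_current"] = iclamp_out,
      _["gate_traces"] = gates_out,
      _["current_traces"] = curr_out,
      _["spike_times"] = NumericVector(spike_times.begin(), spike_times.end()),
      _["v_final"] = NumericVector(V.begin(), V.end()),
      _["gate_final"] = gate_final);
}
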