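#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Units throughout: mV, ms, pF, nS, pA, MOhm.  With these, C dV/dt in
// pF*mV/ms = pA matches g*(E-V) in nS*mV = pA; a clamp current
// (Vcmd - V)/Rs in mV/MOhm = nA needs a factor 1000 to land in pA.

// x/(exp(x/y)-1), stable near x = 0 (first-order expansion).
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / (2.0 * y));
  return x / (std::exp(x / y) - 1.0);
}

struct Rates { double a, b; };

// Traub-Miles style rate functions; u = V - VT where VT positions the
// spike threshold.  All rates in 1/ms.
static inline Rates rate_m(double u) {
  Rates r;
  r.a = 0.32 * vtrap(13.0 - u, 4.0);
  r.b = 0.28 * vtrap(u - 40.0, 5.0);
  return r;
}
static inline Rates rate_h(double u) {
  Rates r;
  r.a = 0.128 * std::exp((17.0 - u) / 18.0);
  r.b = 4.0 / (1.0 + std::exp((40.0 - u) / 5.0));
  return r;
}
static inline Rates rate_n(double u) {
  Rates r;
  r.a = 0.032 * vtrap(15.0 - u, 5.0);
  r.b = 0.5 * std::exp((10.0 - u) / 40.0);
  return r;
}

// Exponential-Euler gate update: relax toward a/(a+b) with tau = 1/(a+b).
static inline double gate_step(double x, const Rates& r, double dt) {
  double tau = 1.0 / (r.a + r.b);
  double xinf = r.a * tau;
  return xinf + (x - xinf) * std::exp(-dt / tau);
}

struct NeuronP {
  double C, gL, EL, gNa, ENa, gK, EK, VT;
};

static NeuronP neuron_from_list(const List& p) {
  NeuronP np;
  np.C = as<double>(p["capacitance"]);
  np.gL = as<double>(p["leak_conductance"]);
  np.EL = as<double>(p["leak_reversal"]);
  np.gNa = as<double>(p["na_max_conductance"]);
  np.ENa = as<double>(p["na_reversal"]);
  np.gK = as<double>(p["k_max_conductance"]);
  np.EK = as<double>(p["k_reversal"]);
  np.VT = as<double>(p["threshold_shift"]);
  return np;
}

// [[Rcpp::export]]
NumericVector hh_steady_gates_cpp(double V, double VT) {
  double u = V - VT;
  Rates m = rate_m(u), h = rate_h(u), n = rate_n(u);
  return NumericVector::create(
    _["m"] = m.a / (m.a + m.b),
    _["h"] = h.a / (h.a + h.b),
    _["n"] = n.a / (n.a + n.b));
}

// One integration step: gates by exponential Euler at the pre-step voltage,
// then a semi-implicit (backward) voltage update so that large conductances
// (and the stiff clamp term, handled in the network loop) stay stable.
// state = (V, m, h, n).
// [[Rcpp::export]]
NumericVector hh_step_cpp(NumericVector state, List neuron, double input_pA,
                          double dt) {
  NeuronP np = neuron_from_list(neuron);
  double V = state[0], m = state[1], h = state[2], n = state[3];
  double u = V - np.VT;
  m = gate_step(m, rate_m(u), dt);
  h = gate_step(h, rate_h(u), dt);
  n = gate_step(n, rate_n(u), dt);
  double gNa = np.gNa * m * m * m * h;
  double gK = np.gK * n * n * n * n;
  double num = V + (dt / np.C) * (np.gL * np.EL + gNa * np.ENa + gK * np.EK +
                                  input_pA);
  double den = 1.0 + (dt / np.C) * (np.gL + gNa + gK);
  V = num / den;
  return NumericVector::create(_["V"] = V, _["m"] = m, _["h"] = h, _["n"] = n);
}

// Single-neuron trace simulator.  input_pA has one value per step
// (piecewise-constant current over [k*dt, (k+1)*dt)).  Returns the voltage
// and gate traces on the n_steps+1 grid plus detected spike times.
// [[Rcpp::export]]
List simulate_neuron_cpp(List neuron, NumericVector init,
                         NumericVector input_pA, double dt,
                         double spike_threshold, double spike_refractory) {
  NeuronP np = neuron_from_list(neuron);
  int n_steps = input_pA.size();
  NumericVector V(n_steps + 1), M(n_steps + 1), H(n_steps + 1),
      N(n_steps + 1);
  double v = init[0], m = init[1], h = init[2], n = init[3];
  V[0] = v; M[0] = m; H[0] = h; N[0] = n;
  std::vector<double> spikes;
  double last_spike = -1e18;
  for (int k = 0; k < n_steps; ++k) {
    double u = v - np.VT;
    m = gate_step(m, rate_m(u), dt);
    h = gate_step(h, rate_h(u), dt);
    n = gate_step(n, rate_n(u), dt);
    double gNa = np.gNa * m * m * m * h;
    double gK = np.gK * n * n * n * n;
    double num = v + (dt / np.C) * (np.gL * np.EL + gNa * np.ENa +
                                    gK * np.EK + input_pA[k]);
    double den = 1.0 + (dt / np.C) * (np.gL + gNa + gK);
    double v_new = num / den;
    if (!std::isfinite(v_new))
      stop("integration failure: V non-finite at step %d (t = %.4f ms)",
           k + 1, (k + 1) * dt);
    double t_new = (k + 1) * dt;
    if (v < spike_threshold && v_new >= spike_threshold &&
        t_new - last_spike >= spike_refractory) {
      spikes.push_back(t_new);
      last_spike = t_new;
    }
    v = v_new;
    V[k + 1] = v; M[k + 1] = m; H[k + 1] = h; N[k + 1] = n;
  }
  return List::create(_["V"] = V, _["m"] = M, _["h"] = H, _["n"] = N,
                      _["spikes"] = NumericVector(spikes.begin(),
                                                  spikes.end()));
}

struct SynP {
  double gpeak, tau_rise, tau_decay, E, dfac, tau_rec, peak_norm;
  bool depressing;
};

static SynP syn_from_list(const List& p) {
  SynP sp;
  sp.gpeak = as<double>(p["peak_conductance"]);
  sp.tau_rise = as<double>(p["tau_rise"]);
  sp.tau_decay = as<double>(p["decay_tau"]);
  sp.E = as<double>(p["reversal"]);
  sp.depressing = as<bool>(p["depressing"]);
  sp.dfac = as<double>(p["depression_factor"]);
  sp.tau_rec = as<double>(p["recovery_tau"]);
  sp.peak_norm = as<double>(p["peak_norm"]);
  return sp;
}

// Full network simulator.
//
// mode: 0 = open loop, 1 = feedforward overwrite, 2 = feedback clamp.
// edges: E x 2 integer matrix of 0-based (pre, post) cortical connections.
// lgn_target: 0-based cortical index per LGN node; lgn_spikes: spike times.
// command: (n_steps+1) x n_cortical recorded voltages (modes 1 and 2).
//
// Event bookkeeping: a presynaptic spike detected at step k schedules
// conductance onset at step k + delay_steps; LGN spike times are mapped to
// onset steps the same way.  Within a step the order is: decay existing
// conductances to the end-of-step time, add arriving events, then advance
// the voltages against those conductances (backward in V).
// [[Rcpp::export]]
List simulate_network_cpp(int n_steps, double dt, List neuron,
                          IntegerMatrix edges, List syn_cortical,
                          List syn_lgn, IntegerVector lgn_target,
                          List lgn_spikes, double delay_ms, int mode,
                          NumericMatrix command, double series_resistance,
                          double spike_threshold, double spike_refractory) {
  NeuronP np = neuron_from_list(neuron);
  SynP sc = syn_from_list(syn_cortical);
  SynP sl = syn_from_list(syn_lgn);
  int n_cort = 0;
  for (int e = 0; e < edges.nrow(); ++e) {
    n_cort = std::max(n_cort, std::max(edges(e, 0), edges(e, 1)) + 1);
  }
  if (mode != 0) n_cort = std::max(n_cort, (int)command.ncol());
  int n_edges = edges.nrow();
  int n_lgn = lgn_target.size();
  int delay_steps = (int)std::lround(delay_ms / dt);

  // per-edge state
  std::vector<double> er(n_edges, 0.0), ed(n_edges, 0.0), es(n_edges, 1.0);
  // per-LGN-node state (one synapse onto its target)
  std::vector<double> lr(n_lgn, 0.0), ld(n_lgn, 0.0), ls(n_lgn, 1.0);
  std::vector<std::vector<int> > out_edges(n_cort);
  for (int e = 0; e < n_edges; ++e) out_edges[edges(e, 0)].push_back(e);

  // LGN spike times -> sorted onset steps per node
  std::vector<std::vector<int> > lgn_onset(n_lgn);
  for (int j = 0; j < n_lgn; ++j) {
    NumericVector st = lgn_spikes[j];
    for (int i = 0; i < st.size(); ++i) {
      int onset = (int)std::lround(st[i] / dt) + delay_steps;
      if (onset <= n_steps) lgn_onset[j].push_back(onset);
    }
    std::sort(lgn_onset[j].begin(), lgn_onset[j].end());
  }
  std::vector<size_t> lgn_ptr(n_lgn, 0);

  // pending cortical deliveries: ring buffer over delay_steps + 1 slots
  int ring = delay_steps + 2;
  std::vector<std::vector<int> > pending(ring);

  double cd_r = std::exp(-dt / sc.tau_rise), cd_d = std::exp(-dt / sc.tau_decay);
  double ld_r = std::exp(-dt / sl.tau_rise), ld_d = std::exp(-dt / sl.tau_decay);
  double crec = std::exp(-dt / sc.tau_rec), lrec = std::exp(-dt / sl.tau_rec);

  NumericMatrix V(n_steps + 1, n_cort), Ivc(n_steps + 1, n_cort),
      Ilgn(n_steps + 1, n_cort);
  std::vector<std::vector<double> > spikes(n_cort);
  std::vector<double> v(n_cort), m(n_cort), h(n_cort), n(n_cort);
  std::vector<double> last_spike(n_cort, -1e18);
  NumericVector g0 = hh_steady_gates_cpp(np.EL, np.VT);
  for (int i = 0; i < n_cort; ++i) {
    v[i] = (mode == 1) ? command(0, i) : np.EL;
    m[i] = g0[0]; h[i] = g0[1]; n[i] = g0[2];
    V(0, i) = v[i];
  }
  double kclamp = (mode == 2) ? 1000.0 / series_resistance : 0.0;  // nS-scale

  std::vector<double> gsum(n_cort), gEsum(n_cort), glgn(n_cort);

  for (int k = 0; k < n_steps; ++k) {
    int step_new = k + 1;
    // 1. decay conductances and recover depression to end-of-step time
    for (int e = 0; e < n_edges; ++e) {
      er[e] *= cd_r; ed[e] *= cd_d;
      if (sc.depressing) es[e] = 1.0 - (1.0 - es[e]) * crec;
    }
    for (int j = 0; j < n_lgn; ++j) {
      lr[j] *= ld_r; ld[j] *= ld_d;
      if (sl.depressing) ls[j] = 1.0 - (1.0 - ls[j]) * lrec;
    }
    // 2. arriving cortical events
    std::vector<int>& due = pending[step_new % ring];
    for (size_t q = 0; q < due.size(); ++q) {
      int pre = due[q];
      for (size_t o = 0; o < out_edges[pre].size(); ++o) {
        int e = out_edges[pre][o];
        double amp = es[e] * sc.gpeak * sc.peak_norm;
        er[e] += amp; ed[e] += amp;
        if (sc.depressing) es[e] *= sc.dfac;
      }
    }
    due.clear();
    // 3. arriving LGN events
    for (int j = 0; j < n_lgn; ++j) {
      while (lgn_ptr[j] < lgn_onset[j].size() &&
             lgn_onset[j][lgn_ptr[j]] == step_new) {
        double amp = ls[j] * sl.gpeak * sl.peak_norm;
        lr[j] += amp; ld[j] += amp;
        if (sl.depressing) ls[j] *= sl.dfac;
        ++lgn_ptr[j];
      }
    }
    // 4. aggregate synaptic conductances per neuron
    for (int i = 0; i < n_cort; ++i) { gsum[i] = 0.0; gEsum[i] = 0.0; glgn[i] = 0.0; }
    for (int e = 0; e < n_edges; ++e) {
      double g = ed[e] - er[e];
      if (g < 0) g = 0;
      int post = edges(e, 1);
      gsum[post] += g; gEsum[post] += g * sc.E;
    }
    for (int j = 0; j < n_lgn; ++j) {
      double g = ld[j] - lr[j];
      if (g < 0) g = 0;
      int tgt = lgn_target[j];
      glgn[tgt] += g;
      gsum[tgt] += g; gEsum[tgt] += g * sl.E;
    }
    // 5. advance each neuron
    for (int i = 0; i < n_cort; ++i) {
      double v_new;
      if (mode == 1) {
        v_new = command(step_new, i);
        double u = v[i] - np.VT;
        m[i] = gate_step(m[i], rate_m(u), dt);
        h[i] = gate_step(h[i], rate_h(u), dt);
        n[i] = gate_step(n[i], rate_n(u), dt);
      } else {
        double u = v[i] - np.VT;
        m[i] = gate_step(m[i], rate_m(u), dt);
        h[i] = gate_step(h[i], rate_h(u), dt);
        n[i] = gate_step(n[i], rate_n(u), dt);
        double gNa = np.gNa * m[i] * m[i] * m[i] * h[i];
        double gK = np.gK * n[i] * n[i] * n[i] * n[i];
        double num = v[i] + (dt / np.C) * (np.gL * np.EL + gNa * np.ENa +
                                           gK * np.EK + gEsum[i]);
        double den = 1.0 + (dt / np.C) * (np.gL + gNa + gK + gsum[i]);
        if (mode == 2) {
          num += (dt / np.C) * kclamp * command(step_new, i);
          den += (dt / np.C) * kclamp;
        }
        v_new = num / den;
      }
      if (!std::isfinite(v_new))
        stop("integration failure: neuron %d V non-finite at t = %.4f ms",
             i + 1, step_new * dt);
      if (mode == 2)
        Ivc(step_new, i) = kclamp * (command(step_new, i) - v_new);
      Ilgn(step_new, i) = glgn[i] * (sl.E - v_new);
      double t_new = step_new * dt;
      if (v[i] < spike_threshold && v_new >= spike_threshold &&
          t_new - last_spike[i] >= spike_refractory) {
        spikes[i].push_back(t_new);
        last_spike[i] = t_new;
        int slot = (step_new + delay_steps) % ring;
        pending[slot].push_back(i);
      }
      v[i] = v_new;
      V(step_new, i) = v_new;
    }
  }
  List sp(n_cort);
  for (int i = 0; i < n_cort; ++i)
    sp[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  return List::create(_["V"] = V, _["I_vc"] = Ivc, _["I_lgn"] = Ilgn,
                      _["spikes"] = sp);
}
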