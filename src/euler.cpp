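// Batched forward-Euler integration of the single-compartment model.
//
// All per-step work lives here because grid searches and regulation loops
// integrate thousands of conductance sets over 1e4-1e5 steps each; the R
// layer only prepares stimuli/initial states and interprets accumulators.
//
// Units: mV, ms, mS/cm2, uA/cm2, uF/cm2. Charge accumulators are in
// uA*ms/cm2 (= nC/cm2 = 1e-9 C/cm2).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double C, ENa, EK, El;
  double gfast, gslow, phiw;
  double bm, gm, bw, gw;
  double Vab, sab, kab;
  double tauzA, bzA, gzA;
  double tauzM, bzM, gzM;
  int n_form; // n-gate rate family, see alpha_n()
  double n_pow; // exponent on n in the generic Na/K currents
};

static Pars unpack(const List& p) {
  Pars s;
  s.C = p["C"]; s.ENa = p["E_Na"]; s.EK = p["E_K"]; s.El = p["E_leak"];
  s.gfast = p["gbar_fast"]; s.gslow = p["gbar_slow"]; s.phiw = p["phi_w"];
  s.bm = p["beta_m"]; s.gm = p["gamma_m"];
  s.bw = p["beta_w"]; s.gw = p["gamma_w"];
  s.Vab = p["V_ab"]; s.sab = p["s_ab"]; s.kab = p["k_ab"];
  s.tauzA = p["tau_z_AHP"]; s.bzA = p["beta_z_AHP"]; s.gzA = p["gamma_z_AHP"];
  s.tauzM = p["tau_z_M"];   s.bzM = p["beta_z_M"];   s.gzM = p["gamma_z_M"];
  s.n_form = as<int>(p["n_form_code"]);
  s.n_pow = p["n_gate_power"];
  return s;
}

static inline double minf(const Pars& p, double V) {
  return 0.5 * (1.0 + std::tanh((V - p.bm) / p.gm));
}
static inline double winf(const Pars& p, double V) {
  return 0.5 * (1.0 + std::tanh((V - p.bw) / p.gw));
}
static inline double tauw(const Pars& p, double V) {
  return 1.0 / std::cosh((V - p.bw) / (2.0 * p.gw));
}
// n-gate opening rate families (x = V - V_ab, u = x/s_ab, s_ab < 0):
//   0 "linoid":        alpha = k x / (1 - e^u)        (positive for all V)
//   1 "printed":       alpha = k x / (e^u - 1)        (sign-broken; diagnostic)
//   2 "exp":           alpha = k e^(-u)               (Borg-Graham pairing)
//   3 "linoid_scaled": alpha = k x / (|s| (1 - e^u))  (half-activation at V_ab)
// Removable singularities at x = 0 use the analytic series limit.
static inline double alpha_n(const Pars& p, double V) {
  double x = V - p.Vab;
  double u = x / p.sab;
  switch (p.n_form) {
  case 1:
    if (std::fabs(u) < 1e-7) return p.kab * p.sab * (1.0 - 0.5 * u);
    return p.kab * x / (std::exp(u) - 1.0);
  case 2:
    return p.kab * std::exp(-u);
  case 3:
    if (std::fabs(u) < 1e-7) return p.kab * (1.0 - 0.5 * u);
    return p.kab * x / (std::fabs(p.sab) * (1.0 - std::exp(u)));
  default:
    if (std::fabs(u) < 1e-7) return -p.kab * p.sab * (1.0 - 0.5 * u);
    return p.kab * x / (1.0 - std::exp(u));
  }
}
static inline double beta_n(const Pars& p, double V) {
  return p.kab * std::exp((V - p.Vab) / p.sab);
}
static inline double zinf(double beta, double gamma, double V) {
  return 1.0 / (1.0 + std::exp((beta - V) / gamma));
}

struct Currents {
  double ina;  // Na-carrying: fast + generic Na
  double ik;   // K-carrying: slow + generic K + AHP + M
  double il;   // leak (mixed ionic identity)
};

// Gate update: exponential (Rush-Larsen) relaxation toward the steady state,
// exact for frozen V and unconditionally stable. The n-gate rates reach
// ~60-90 ms^-1 in the reachable voltage range, far beyond the explicit-Euler
// stability bound at dt = 0.05-0.1 ms, so gates are never stepped explicitly.
struct GateStep {
  double wn, nn, pn, qn;
};

static inline GateStep gate_step(const Pars& p, double V, double dt,
                                 double w, double n, double pp, double q,
                                 double decayA, double decayM) {
  GateStep gs;
  double wi = winf(p, V);
  double rw = p.phiw / tauw(p, V);
  gs.wn = wi + (w - wi) * std::exp(-dt * rw);
  double an = alpha_n(p, V), bn = beta_n(p, V);
  double ni = an / (an + bn);
  gs.nn = ni + (n - ni) * std::exp(-dt * (an + bn));
  gs.pn = zinf(p.bzA, p.gzA, V) * (1.0 - decayA) + pp * decayA;
  gs.qn = zinf(p.bzM, p.gzM, V) * (1.0 - decayM) + q * decayM;
  return gs;
}

static inline Currents currents(const Pars& p, const double* g,
                                double V, double w, double n,
                                double pp, double q) {
  Currents c;
  double ne = (p.n_pow == 1.0) ? n
            : (p.n_pow == 4.0) ? (n * n) * (n * n) : std::pow(n, p.n_pow);
  c.ina = (p.gfast * minf(p, V) + g[0] * ne) * (V - p.ENa);
  c.ik  = (p.gslow * w + g[1] * ne + g[4] * pp + g[2] * q) * (V - p.EK);
  c.il  = g[3] * (V - p.El);
  return c;
}

// G columns: gNa, gK, gM, gleak, gAHP. init columns: V, w, n, p, q.
// stim is shared across models; offset[i] is added per model (an OU
// realization is generated zero-mean and shifted by each model's mu).
// [[Rcpp::export(name = ".euler_batch_cpp")]]
List euler_batch_cpp(List params, NumericMatrix G, NumericVector stim,
                     NumericVector offset, double dt, NumericMatrix init,
                     double thresh, double refract,
                     int count_from, int energy_from, int vstat_from,
                     bool record_trace, bool want_spike_times) {
  const Pars p = unpack(params);
  const int nmod = G.nrow();
  const int T = stim.size();
  if (record_trace && nmod != 1)
    stop("trace recording is only supported for a single model");

  IntegerVector nspk(nmod), status(nmod), div_step(nmod, NA_INTEGER);
  NumericVector qna(nmod), qk(nmod), vsum(nmod), vmax(nmod, R_NegInf);
  NumericMatrix fin(nmod, 5);
  List sptimes(want_spike_times ? nmod : 0);
  NumericMatrix trace(record_trace ? T : 0, record_trace ? 5 : 0);

  const int refr_steps = (int)std::ceil(refract / dt);
  const double decayA = std::exp(-dt / p.tauzA);
  const double decayM = std::exp(-dt / p.tauzM);

  for (int i = 0; i < nmod; ++i) {
    double g[5] = { G(i,0), G(i,1), G(i,2), G(i,3), G(i,4) };
    double V = init(i,0), w = init(i,1), n = init(i,2),
           pp = init(i,3), q = init(i,4);
    double off = offset[i];
    int last_spike = -refr_steps - 1;
    std::vector<double> st;
    double prevIna = 0.0, prevIk = 0.0;
    bool havePrev = false;

    for (int t = 0; t < T; ++t) {
      if (record_trace) {
        trace(t,0) = V; trace(t,1) = w; trace(t,2) = n;
        trace(t,3) = pp; trace(t,4) = q;
      }
      if (t >= vstat_from) {
        vsum[i] += V;
        if (V > vmax[i]) vmax[i] = V;
      }
      Currents cr = currents(p, g, V, w, n, pp, q);
      if (t >= energy_from) {
        if (havePrev) { // trapezoid on the labelled current series
          qna[i] += 0.5 * (prevIna + cr.ina) * dt;
          qk[i]  += 0.5 * (prevIk  + cr.ik)  * dt;
        }
        prevIna = cr.ina; prevIk = cr.ik; havePrev = true;
      }
      if (t == T - 1) break;

      double Istim = stim[t] + off;
      double Vnew = V + dt * (Istim - cr.ina - cr.ik - cr.il) / p.C;
      // gates relax from time-t voltage
      GateStep gs = gate_step(p, V, dt, w, n, pp, q, decayA, decayM);

      // upward crossing: previous sample strictly below, new strictly above
      if (V < thresh && Vnew > thresh && (t + 1 - last_spike) > refr_steps) {
        last_spike = t + 1;
        if (t + 1 >= count_from) {
          nspk[i] += 1;
          if (want_spike_times) st.push_back((t + 1) * dt);
        }
      }
      V = Vnew; w = gs.wn; n = gs.nn; pp = gs.pn; q = gs.qn;
      if (!std::isfinite(V) || std::fabs(V) > 500.0) {
        status[i] = 1; div_step[i] = t + 1;
        break;
      }
    }
    fin(i,0) = V; fin(i,1) = w; fin(i,2) = n; fin(i,3) = pp; fin(i,4) = q;
    if (want_spike_times) sptimes[i] = wrap(st);
  }

  List out = List::create(
    _["n_spikes"] = nspk, _["status"] = status, _["div_step"] = div_step,
    _["q_na"] = qna, _["q_k"] = qk,
    _["v_sum"] = vsum, _["v_max"] = vmax,
    _["v_n"] = T - vstat_from,
    _["final_state"] = fin);
  if (want_spike_times) out["spike_times"] = sptimes;
  if (record_trace) out["trace"] = trace;
  return out;
}

// Single-spike energy-efficiency protocol. From each model's resting state,
// V is reset to reset_v while the stimulus is held at hold_I (the mean of
// the fluctuating energy stimulus, which is suprathreshold in essentially
// every model, so the reset reliably evokes a spike). The window runs from
// the reset through the FIRST action potential (first local voltage maximum
// above peak_thresh) and closes at the post-spike trough (dV/dt >= 0), at a
// plateau (|dV/dt| < plateau_eps), on falling back below reset_v, or after
// max_ms. Accumulates total Na influx (trapezoid) over the window.
// [[Rcpp::export(name = ".efficiency_batch_cpp")]]
List efficiency_batch_cpp(List params, NumericMatrix G, NumericMatrix rest,
                          double dt, double reset_v, double hold_I,
                          double max_ms, double peak_thresh,
                          double plateau_eps) {
  const Pars p = unpack(params);
  const int nmod = G.nrow();
  const int T = (int)std::floor(max_ms / dt) + 1;
  const double decayA = std::exp(-dt / p.tauzA);
  const double decayM = std::exp(-dt / p.tauzM);
  const double eps_step = plateau_eps * dt; // mV per step

  NumericVector qna(nmod), vpeak(nmod, NA_REAL), vrest(nmod);
  IntegerVector spiked(nmod), status(nmod);

  for (int i = 0; i < nmod; ++i) {
    double g[5] = { G(i,0), G(i,1), G(i,2), G(i,3), G(i,4) };
    double V = reset_v, w = rest(i,1), n = rest(i,2),
           pp = rest(i,3), q = rest(i,4);
    vrest[i] = rest(i,0);
    double prevIna = 0.0;
    bool havePrev = false, postPeak = false;

    for (int t = 0; t < T - 1; ++t) {
      Currents cr = currents(p, g, V, w, n, pp, q);
      if (havePrev) qna[i] += 0.5 * (prevIna + cr.ina) * dt;
      prevIna = cr.ina; havePrev = true;

      double Vnew = V + dt * (hold_I - cr.ina - cr.ik - cr.il) / p.C;
      GateStep gs = gate_step(p, V, dt, w, n, pp, q, decayA, decayM);

      if (!postPeak) {
        if (V > peak_thresh && Vnew < V) { // first spike peak
          postPeak = true;
          spiked[i] = 1;
          vpeak[i] = V;
        }
      } else {
        if (Vnew >= V || std::fabs(Vnew - V) < eps_step || Vnew < reset_v)
          break; // trough, plateau, or repolarized past the reset level
      }
      V = Vnew; w = gs.wn; n = gs.nn; pp = gs.pn; q = gs.qn;
      if (!std::isfinite(V) || std::fabs(V) > 500.0) { status[i] = 1; break; }
    }
  }
  return List::create(_["q_na"] = qna, _["v_peak"] = vpeak,
                      _["v_rest"] = vrest, _["n_spikes"] = spiked,
                      _["status"] = status);
}
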