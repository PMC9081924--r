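// Closed-loop lumped-parameter cardiovascular model with a centrifugal
// blood pump. Three compartments: left ventricle (time-varying elastance
// with a Frank-Starling modulation of peak elastance), systemic arterial
// Windkessel, and a venous pool. The right heart and pulmonary bed are
// lumped into a single venous->LV filling resistance. Units internally:
// mmHg, mL, s; pump flow in L/min at the pump characteristic.
//
// Integration is fixed-step RK4. Valve diodes and the suction-occlusion
// law are smooth enough at 400 Hz for the waveform features the
// estimators consume (peak-to-peak flow, diastolic dips).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double MLS_PER_LMIN = 1000.0 / 60.0;

// Double-Hill activation shape (normalized ventricular elastance).
// Shape constants are the widely used two-sigmoid form; the normalization
// constant is computed once so the activation peaks at exactly 1.
static const double DH_A1 = 0.303, DH_N1 = 1.32, DH_A2 = 0.508, DH_N2 = 21.9;

static double dh_raw(double tn) {
  double u = std::pow(tn / DH_A1, DH_N1);
  double v = std::pow(tn / DH_A2, DH_N2);
  return (u / (1.0 + u)) * (1.0 / (1.0 + v));
}

static double dh_norm_const() {
  static double c = -1.0;
  if (c < 0) {
    double m = 0.0;
    for (int i = 1; i <= 4000; ++i) {
      double e = dh_raw(i * (1.0 / 4000.0));
      if (e > m) m = e;
    }
    c = m;
  }
  return c;
}

// Normalized activation in [0, 1]; t_in_beat in s, rr in s. Activation
// runs over a systolic interval scaled with sqrt(rr) (Bazett-like), the
// remainder of the beat is diastole at zero activation.
// [[Rcpp::export(name = ".cpp_activation")]]
double cpp_activation(double t_in_beat, double rr) {
  double t_act = 0.55 * std::sqrt(rr); // activation duration, s
  double tn = t_in_beat / t_act;
  if (tn <= 0.0 || tn >= 1.5) return 0.0;
  return dh_raw(tn) / dh_norm_const();
}

// Pump characteristic dp = b0*w^2 + b1*w*Q + b2*Q^2 solved for Q given dp
// (mmHg), w (rpm). Physical root is the larger one (descending branch,
// dDP/dQ < 0 there). r_lin is an extra series (cannula) resistance in
// mmHg per L/min folded into the linear coefficient. Returns Q in L/min;
// if no real root exists (dp above max head) returns the vertex flow.
static double pump_q(double dp, double w, double b0, double b1, double b2,
                     double r_lin, bool *clamped) {
  double A = b2;
  double B = b1 * w - r_lin;
  double C = b0 * w * w - dp;
  double disc = B * B - 4.0 * A * C;
  if (disc < 0.0) {
    if (clamped) *clamped = true;
    return -B / (2.0 * A);
  }
  if (clamped) *clamped = false;
  // A < 0 by the H-Q invariant, so the larger root is (-B - sqrt)/2A.
  return (-B - std::sqrt(disc)) / (2.0 * A);
}

// [[Rcpp::export(name = ".cpp_pump_flow")]]
List cpp_pump_flow(double dp, double omega, double b0, double b1, double b2,
                   double r_lin) {
  bool cl = false;
  double q = pump_q(dp, omega, b0, b1, b2, r_lin, &cl);
  return List::create(_["q"] = q, _["clamped"] = cl);
}

struct Pat {
  double Emax, Emin, V0, starling_gain, V_ed_ref;
  double R_fill, R_av, R_art, C_art, C_ven;
  double R_in, R_out, V_suction, k_occ, pth_venous_frac;
};

struct Pump { double b0, b1, b2, c0, c1, c2; };

static Pat read_pat(const List &p) {
  Pat q;
  q.Emax = p["Emax"]; q.Emin = p["Emin"]; q.V0 = p["V0"];
  q.starling_gain = p["starling_gain"]; q.V_ed_ref = p["V_ed_ref"];
  q.R_fill = p["R_fill"]; q.R_av = p["R_av"]; q.R_art = p["R_art"];
  q.C_art = p["C_art"]; q.C_ven = p["C_ven"];
  q.R_in = p["R_in"]; q.R_out = p["R_out"];
  q.V_suction = p["V_suction"]; q.k_occ = p["k_occ"];
  q.pth_venous_frac = p["pth_venous_frac"];
  return q;
}

static Pump read_pump(const List &p) {
  Pump q;
  q.b0 = p["b0"]; q.b1 = p["b1"]; q.b2 = p["b2"];
  q.c0 = p["c0"]; q.c1 = p["c1"]; q.c2 = p["c2"];
  return q;
}

// Instantaneous derivatives of (V_lv, P_art, P_ven). Pooled volume is
// handled by the caller (its rate is an input, not a state feedback).
// Outputs flows for bookkeeping: q_fill, q_av (mL/s), q_pump (L/min).
static void derivs(const double s[3], double e_act, double emax_eff,
                   const Pat &pat, const Pump &pm,
                   double omega, double pth, double rart_scale,
                   double rin_mult, double pool_rate,
                   double d[3], double flows[3]) {
  double V_lv = s[0], P_art = s[1], P_ven = s[2];
  // Intrathoracic pressure loads the LV fully but the (mostly
  // extrathoracic) venous pool only partially, so Valsalva strain cuts
  // the filling gradient and venous return (phase II preload drop).
  double E = pat.Emin + (emax_eff - pat.Emin) * e_act;
  double p_lv = E * (V_lv - pat.V0) + pth;
  double p_ven_tot = P_ven + pat.pth_venous_frac * pth;

  double q_fill = (p_ven_tot - p_lv) / pat.R_fill;
  if (q_fill < 0.0) q_fill = 0.0;
  double q_av = (p_lv - P_art) / pat.R_av;
  if (q_av < 0.0) q_av = 0.0;

  double dv = pat.V_suction - V_lv;
  double r_in_eff = pat.R_in * (1.0 + pat.k_occ * (dv > 0 ? dv * dv : 0.0));
  r_in_eff *= rin_mult;
  double q_pump = pump_q(P_art - p_lv, omega, pm.b0, pm.b1, pm.b2,
                         r_in_eff + pat.R_out, NULL);
  double q_pump_mls = q_pump * MLS_PER_LMIN;

  double q_sys = (P_art - p_ven_tot) / (pat.R_art * rart_scale);

  d[0] = q_fill - q_av - q_pump_mls;
  d[1] = (q_av + q_pump_mls - q_sys) / pat.C_art;
  d[2] = (q_sys - q_fill - pool_rate) / pat.C_ven;
  flows[0] = q_fill; flows[1] = q_av; flows[2] = q_pump;
}

// [[Rcpp::export(name = ".cpp_cv_derivs")]]
List cpp_cv_derivs(NumericVector state, double e_act, double emax_eff,
                   List patient, List pump, double omega, double pth,
                   double rart_scale, double rin_mult, double pool_rate) {
  Pat pat = read_pat(patient);
  Pump pm = read_pump(pump);
  double s[3] = {state[0], state[1], state[2]};
  double d[3], fl[3];
  derivs(s, e_act, emax_eff, pat, pm, omega, pth, rart_scale, rin_mult,
         pool_rate, d, fl);
  return List::create(
      _["d"] = NumericVector::create(d[0], d[1], d[2]),
      _["q_fill"] = fl[0], _["q_av"] = fl[1], _["q_pump"] = fl[2]);
}

// Integrate one chunk of n_steps internal steps of size dt, starting at
// time t0, with per-step parameter trajectories. Emits one output row per
// `out_every` internal steps (50 Hz for dt = 1/400, out_every = 8).
//
// state: V_lv, P_art, P_ven, V_pooled
// beat:  phase (s into current beat), rr (s), emax_eff (mmHg/mL),
//        jitter_idx (next index into rr_jitter, 0-based)
// Trajectories (length n_steps): hr0 (bpm), pth (mmHg), rart_scale,
// emax_scale, rin_mult, pool_rate (mL/s).
// [[Rcpp::export(name = ".cpp_cv_chunk")]]
List cpp_cv_chunk(NumericVector state, List beat, double t0, double dt,
                  int n_steps, int out_every, List patient, List pump,
                  double omega,
                  NumericVector hr0, NumericVector pth,
                  NumericVector rart_scale, NumericVector emax_scale,
                  NumericVector rin_mult, NumericVector pool_rate,
                  NumericVector rr_jitter) {
  Pat pat = read_pat(patient);
  Pump pm = read_pump(pump);
  double s[4] = {state[0], state[1], state[2], state[3]};
  double phase = beat["phase"], rr = beat["rr"], emax_eff = beat["emax_eff"];
  int jidx = beat["jitter_idx"];

  int n_out = n_steps / out_every;
  NumericMatrix out(n_out, 9);
  colnames(out) = CharacterVector::create(
      "t", "flow_true", "p_lv", "p_art", "p_ven", "v_lv", "hr_true",
      "aov_open", "occl");
  int orow = 0;
  bool failed = false;
  double t_fail = NA_REAL;

  for (int i = 0; i < n_steps; ++i) {
    // beat bookkeeping: start a new beat when the phase runs out
    if (phase >= rr) {
      phase -= rr;
      double jit = (jidx < rr_jitter.size()) ? rr_jitter[jidx++] : 1.0;
      rr = 60.0 / hr0[i] * jit;
      if (rr < 0.25) rr = 0.25;
      if (rr > 2.0) rr = 2.0;
      double v_ed = s[0];
      double emax_sc = pat.Emax * emax_scale[i];
      double f = 1.0 + pat.starling_gain * (v_ed - pat.V_ed_ref) / pat.V_ed_ref;
      if (f < 0.2) f = 0.2;
      if (f > 2.0) f = 2.0;
      emax_eff = emax_sc * f;
    }

    double d1[3], d2[3], d3[3], d4[3], fl[3], tmp[3];
    double e1 = cpp_activation(phase, rr);
    double e2 = cpp_activation(phase + 0.5 * dt, rr);
    double e4 = cpp_activation(phase + dt, rr);

    derivs(s, e1, emax_eff, pat, pm, omega, pth[i], rart_scale[i],
           rin_mult[i], pool_rate[i], d1, fl);
    for (int k = 0; k < 3; ++k) tmp[k] = s[k] + 0.5 * dt * d1[k];
    derivs(tmp, e2, emax_eff, pat, pm, omega, pth[i], rart_scale[i],
           rin_mult[i], pool_rate[i], d2, fl);
    for (int k = 0; k < 3; ++k) tmp[k] = s[k] + 0.5 * dt * d2[k];
    derivs(tmp, e2, emax_eff, pat, pm, omega, pth[i], rart_scale[i],
           rin_mult[i], pool_rate[i], d3, fl);
    for (int k = 0; k < 3; ++k) tmp[k] = s[k] + dt * d3[k];
    derivs(tmp, e4, emax_eff, pat, pm, omega, pth[i], rart_scale[i],
           rin_mult[i], pool_rate[i], d4, fl);
    for (int k = 0; k < 3; ++k)
      s[k] += dt / 6.0 * (d1[k] + 2.0 * d2[k] + 2.0 * d3[k] + d4[k]);
    s[3] += dt * pool_rate[i];
    phase += dt;

    if (s[0] <= 0.5 || !std::isfinite(s[0])) {
      failed = true;
      t_fail = t0 + (i + 1) * dt;
      break;
    }

    if ((i + 1) % out_every == 0) {
      // sample observables at the post-step state
      double dd[3];
      derivs(s, cpp_activation(phase, rr), emax_eff, pat, pm, omega,
             pth[i], rart_scale[i], rin_mult[i], pool_rate[i], dd, fl);
      double E = pat.Emin + (emax_eff - pat.Emin) * cpp_activation(phase, rr);
      out(orow, 0) = t0 + (i + 1) * dt;
      out(orow, 1) = fl[2];                      // pump flow L/min
      out(orow, 2) = E * (s[0] - pat.V0) + pth[i];
      out(orow, 3) = s[1];
      out(orow, 4) = s[2];
      out(orow, 5) = s[0];
      out(orow, 6) = 60.0 / rr;
      out(orow, 7) = (fl[1] > 0.0) ? 1.0 : 0.0;  // aortic valve flowing
      out(orow, 8) = (rin_mult[i] > 1.0 || s[0] < pat.V_suction) ? 1.0 : 0.0;
      ++orow;
    }
  }

  return List::create(
      _["out"] = out, _["n_out"] = orow,
      _["state"] = NumericVector::create(s[0], s[1], s[2], s[3]),
      _["beat"] = List::create(_["phase"] = phase, _["rr"] = rr,
                               _["emax_eff"] = emax_eff,
                               _["jitter_idx"] = jidx),
      _["failed"] = failed, _["t_fail"] = t_fail);
}
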