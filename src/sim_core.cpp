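// Fixed-step RK4 engine for the immune-tumor ecosystem.
//
// State vector layout (length 53), populations in units of 1e9 cells:
//   [0:8]   T      9 tumor sub-clone populations
//   [9]     H      host tissue
//   [10:18] Np     pre-immune-stimulatory damaged tumor cells (per clone)
//   [19]    NpH    pre-immune-stimulatory damaged host cells
//   [20:28] N      immune-stimulatory (necrotic/immunogenic-apoptotic) tumor cells
//   [29]    NH     immune-stimulatory host cells
//   [30:38] I      effector-cell populations (per antigen component)
//   [39:47] w      perceptron weights (may be negative)
//   [48:50] GT,GH,GI  transient biological dose equivalents (Gy)
//   [51]    theta  perfusion state, PEF = 1 + theta
//   [52]    phi    immune-stimulation state, ISF = 1 + phi
//
// Treatment events are realized as per-step flags taken from merged,
// grid-aligned interval lists (beam windows carry an effective dose rate
// rescaled so the delivered dose per fraction is exact on the grid).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

constexpr int NC = 9;   // tumor sub-clones
constexpr int NAC = 9;   // antigen-pattern components
constexpr int NS = 53;  // state length

struct Pars {
  double kT, kmut, keT, kTT, kIT, kHT, kTH, kaH, kbH, keH,
         kpn, kn, kap, kIH, kI, keI;
  double Yact, Xact, eta, chi, Lact, a;
  int xi;
  double alphaT, betaT, alphaH, betaH, alphaI, betaI,
         gammaT, gammaH, gammaI;
  double kperf1, kperf2, kims1, kims2;
  double aT_factor, bT_factor;
};

struct Flags {
  bool mod_ab, mod_kI, mod_Xact, mod_Lact;
  bool xact_fast, lact_fast;       // fast (PEF) vs slow (ISF) process
  bool consume_per_effector;       // effector consumption includes I_n factor
  bool mut_outflow_all;            // -kmut outflow from every parent clone
};

inline double sig2(double s, double act) {
  // squared-sigmoid s^2 / (act^2 + s^2)
  double s2 = s * s;
  return s2 / (act * act + s2);
}

Pars unpack_pars(const List& p) {
  Pars q;
  q.kT = p["kT"]; q.kmut = p["kmut"]; q.keT = p["keT"]; q.kTT = p["kTT"];
  q.kIT = p["kIT"]; q.kHT = p["kHT"]; q.kTH = p["kTH"]; q.kaH = p["kaH"];
  q.kbH = p["kbH"]; q.keH = p["keH"]; q.kpn = p["kpn"]; q.kn = p["kn"];
  q.kap = p["kap"]; q.kIH = p["kIH"]; q.kI = p["kI"]; q.keI = p["keI"];
  q.Yact = p["Yact"]; q.Xact = p["Xact"]; q.eta = p["eta"]; q.chi = p["chi"];
  q.Lact = p["Lact"]; q.a = p["a"]; q.xi = as<int>(p["xi"]);
  q.alphaT = p["alphaT"]; q.betaT = p["betaT"]; q.alphaH = p["alphaH"];
  q.betaH = p["betaH"]; q.alphaI = p["alphaI"]; q.betaI = p["betaI"];
  q.gammaT = p["gammaT"]; q.gammaH = p["gammaH"]; q.gammaI = p["gammaI"];
  q.kperf1 = p["kperf1"]; q.kperf2 = p["kperf2"];
  q.kims1 = p["kims1"]; q.kims2 = p["kims2"];
  q.aT_factor = p["alphaT_factor"]; q.bT_factor = p["betaT_factor"];
  return q;
}

Flags unpack_flags(const List& f) {
  Flags g;
  g.mod_ab = f["alpha_beta"]; g.mod_kI = f["kI"];
  g.mod_Xact = f["Xact"]; g.mod_Lact = f["Lact"];
  g.xact_fast = f["Xact_fast"]; g.lact_fast = f["Lact_fast"];
  g.consume_per_effector = f["consume_per_effector"];
  g.mut_outflow_all = f["mut_outflow_all"];
  return g;
}

// Full coupled right-hand side. P is NAC x (NC+1), column-major; qmat is
// NC x NC routing (qmat[c, l] = 1 when clone l feeds clone c by mutation).
// sig (optional, length 3+NAC) receives D, Sigma, Y, X[1..NAC].
void rhs(const double* y, double R, bool beam_paired, bool heat, bool ims,
         const Pars& p, const Flags& f,
         const double* P, const double* qmat, const int* has_child,
         double* dy, double* sig) {
  const double* T = y;
  const double H = y[NC];
  const double* Np = y + 10;
  const double NpH = y[19];
  const double* N = y + 20;
  const double NH = y[29];
  const double* I = y + 30;
  const double* w = y + 39;
  const double GT = y[48], GH = y[49], GI = y[50];
  const double theta = y[51], phi = y[52];

  const double PEF = 1.0 + theta;
  const double ISF = 1.0 + phi;

  // HT-modified effective parameters (pure functions of base + theta/phi)
  const double aT = (f.mod_ab && beam_paired) ? p.aT_factor * p.alphaT : p.alphaT;
  const double bT = (f.mod_ab && beam_paired) ? p.bT_factor * p.betaT : p.betaT;
  const double kI_eff = f.mod_kI ? p.kI * PEF : p.kI;
  const double Xact_eff = f.mod_Xact ? p.Xact / (f.xact_fast ? PEF : ISF) : p.Xact;
  const double Lact_eff = f.mod_Lact ? p.Lact / (f.lact_fast ? PEF : ISF) : p.Lact;

  // match coefficients r = P^T I for 9 clones + host
  double r[NC + 1];
  for (int c = 0; c <= NC; ++c) {
    double s = 0.0;
    for (int n = 0; n < NAC; ++n) s += I[n] * P[n + NAC * c];
    r[c] = s;
  }

  double Ttot = 0.0;
  for (int c = 0; c < NC; ++c) Ttot += T[c];

  const double radT = (aT + 2.0 * bT * GT) * R;
  const double radH = (p.alphaH + 2.0 * p.betaH * GH) * R;
  const double radI = (p.alphaI + 2.0 * p.betaI * GI) * R;

  // tumor sub-clones
  for (int c = 0; c < NC; ++c) {
    double grow = p.kT - p.keT - r[c] * p.kIT - p.kHT * H - p.kTT * Ttot - radT;
    double influx = 0.0;
    for (int l = 0; l < NC; ++l) influx += qmat[c + NC * l] * T[l];
    dy[c] = grow * T[c] + p.kmut * influx;
  }
  // mutation outflow: literally only from the founder clone unless the
  // per-clone-outflow switch is set (then every clone with descendants)
  if (f.mut_outflow_all) {
    for (int c = 0; c < NC; ++c)
      if (has_child[c]) dy[c] -= p.kmut * T[c];
  } else {
    dy[0] -= p.kmut * T[0];
  }

  // host
  dy[NC] = (p.kaH - p.keH - r[NC] * p.kIH - p.kbH * H - p.kTH * Ttot - radH) * H;

  // damaged-cell pools: inflow = elimination terms only (keT/keH, immune
  // kill, radiation kill) applied to the living populations
  for (int c = 0; c < NC; ++c) {
    double elim = (p.keT + r[c] * p.kIT + radT) * T[c];
    dy[10 + c] = elim - p.kpn * Np[c];
    dy[20 + c] = p.kpn * Np[c] - p.kn * N[c];
  }
  double elimH = (p.keH + r[NC] * p.kIH + radH) * H;
  dy[19] = elimH - (p.kpn + p.kap) * NpH;
  dy[29] = p.kpn * NpH - p.kn * NH;

  // danger signal
  double S = NH;
  for (int c = 0; c < NC; ++c) S += N[c];
  const double D = sig2(S, Lact_eff);

  // antigen signals from T~ = T + eta*Np + chi*N (host included for the
  // components the host bears)
  double Ttil[NC + 1];
  for (int c = 0; c < NC; ++c) Ttil[c] = T[c] + p.eta * Np[c] + p.chi * N[c];
  Ttil[NC] = H + p.eta * NpH + p.chi * NH;
  double X[NAC];
  for (int n = 0; n < NAC; ++n) {
    double Sn = 0.0;
    for (int c = 0; c <= NC; ++c) Sn += P[n + NAC * c] * Ttil[c];
    X[n] = sig2(Sn, Xact_eff);
  }

  // perceptron response (clamped at Sigma <= 0)
  double Sigma = 0.0;
  for (int n = 0; n < NAC; ++n) Sigma += w[n] * X[n];
  double Y = 0.0;
  if (Sigma > 0.0) {
    double sx = std::pow(Sigma, p.xi);
    Y = sx / (std::pow(p.Yact, p.xi) + sx);
  }

  // weight learning and effector dynamics
  for (int n = 0; n < NAC; ++n) {
    dy[39 + n] = p.a * (D - Y) * X[n];
    double consume;
    if (f.consume_per_effector) {
      double Bn = 0.0;  // total living tumor bearing component n
      for (int c = 0; c < NC; ++c) Bn += P[n + NAC * c] * T[c];
      consume = p.kIT * I[n] * Bn;
    } else {
      double s = 0.0;   // matched-kill share, as printed (r already holds I)
      for (int c = 0; c < NC; ++c) s += P[n + NAC * c] * r[c] * T[c];
      consume = p.kIT * s;
    }
    dy[30 + n] = kI_eff * Y * X[n] - (p.keI + radI) * I[n] - consume;
  }

  // TBDE kinetics and HT state kinetics
  dy[48] = R - p.gammaT * GT;
  dy[49] = R - p.gammaH * GH;
  dy[50] = R - p.gammaI * GI;
  dy[51] = (heat ? p.kperf1 : 0.0) - p.kperf2 * theta;
  dy[52] = (ims ? p.kims1 : 0.0) - p.kims2 * phi;

  if (sig) {
    sig[0] = D; sig[1] = Sigma; sig[2] = Y;
    for (int n = 0; n < NAC; ++n) sig[3 + n] = X[n];
  }
}

// interval lookup: matrices with columns (start_step, end_step_exclusive, ...)
struct IntervalCursor {
  const IntegerMatrix m;
  int idx;
  IntervalCursor(const IntegerMatrix& mm) : m(mm), idx(0) {}
  // returns row covering step, or -1
  int covering(int step) {
    while (idx < m.nrow() && m(idx, 1) <= step) ++idx;
    if (idx < m.nrow() && m(idx, 0) <= step) return idx;
    return -1;
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector y0, double dt, int n_steps, double rt_start,
              List pars, List flags, NumericMatrix P, NumericMatrix qmat,
              IntegerVector has_child,
              IntegerMatrix beam, NumericVector beam_rate,
              IntegerVector beam_paired,
              IntegerMatrix heat, IntegerMatrix ims,
              int stride) {
  if (y0.size() != NS) stop("state vector must have length %d", NS);
  Pars p = unpack_pars(pars);
  Flags f = unpack_flags(flags);

  std::vector<double> y(y0.begin(), y0.end());
  double k1[NS], k2[NS], k3[NS], k4[NS], yt[NS];
  double sig[3 + NAC];

  const int n_rec = n_steps / stride + 1 + ((n_steps % stride) ? 1 : 0);
  NumericMatrix states(n_rec, NS);
  NumericMatrix signals(n_rec, 3 + NAC + 4);  // D,Sigma,Y,X1..9,PEF,ISF,Ttot,R
  NumericVector times(n_rec);

  IntervalCursor cur_beam(beam), cur_heat(heat), cur_ims(ims);

  double t_min_val = R_PosInf, t_min_time = NA_REAL;
  double clipped = 0.0;
  int rec = 0;

  auto total_T = [&](const double* yy) {
    double s = 0.0;
    for (int c = 0; c < NC; ++c) s += yy[c];
    return s;
  };
  auto record = [&](int step) {
    double t = step * dt;
    int b = cur_beam.covering(step < n_steps ? step : n_steps - 1);
    double R = 0.0; bool paired = false;
    if (b >= 0 && step < n_steps) { R = beam_rate[b]; paired = beam_paired[b] != 0; }
    bool heat_on = cur_heat.covering(step < n_steps ? step : n_steps - 1) >= 0;
    bool ims_on = cur_ims.covering(step < n_steps ? step : n_steps - 1) >= 0;
    rhs(y.data(), R, paired, heat_on, ims_on, p, f, P.begin(), qmat.begin(),
        has_child.begin(), k1, sig);
    times[rec] = t;
    for (int i = 0; i < NS; ++i) states(rec, i) = y[i];
    for (int i = 0; i < 3 + NAC; ++i) signals(rec, i) = sig[i];
    signals(rec, 12) = 1.0 + y[51];
    signals(rec, 13) = 1.0 + y[52];
    signals(rec, 14) = total_T(y.data());
    signals(rec, 15) = R;
    ++rec;
  };

  // nadir tracking starts at rt_start (inclusive)
  if (0.0 >= rt_start) { t_min_val = total_T(y.data()); t_min_time = 0.0; }
  record(0);

  for (int step = 0; step < n_steps; ++step) {
    int b = cur_beam.covering(step);
    double R = 0.0; bool paired = false;
    if (b >= 0) { R = beam_rate[b]; paired = beam_paired[b] != 0; }
    bool heat_on = cur_heat.covering(step) >= 0;
    bool ims_on = cur_ims.covering(step) >= 0;

    // classical RK4 with flags held constant over the step
    rhs(y.data(), R, paired, heat_on, ims_on, p, f, P.begin(), qmat.begin(),
        has_child.begin(), k1, nullptr);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    rhs(yt, R, paired, heat_on, ims_on, p, f, P.begin(), qmat.begin(),
        has_child.begin(), k2, nullptr);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    rhs(yt, R, paired, heat_on, ims_on, p, f, P.begin(), qmat.begin(),
        has_child.begin(), k3, nullptr);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + dt * k3[i];
    rhs(yt, R, paired, heat_on, ims_on, p, f, P.begin(), qmat.begin(),
        has_child.begin(), k4, nullptr);
    for (int i = 0; i < NS; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    // post-step clipping: populations and TBDE to >= 0 (weights may be
    // negative), theta/phi to [0,1]
    for (int i = 0; i < 48; ++i) {
      if (i >= 39) continue;
      if (y[i] < 0.0) { clipped -= y[i]; y[i] = 0.0; }
    }
    for (int i = 48; i <= 50; ++i) if (y[i] < 0.0) { clipped -= y[i]; y[i] = 0.0; }
    for (int i = 51; i <= 52; ++i) {
      if (y[i] < 0.0) y[i] = 0.0;
      if (y[i] > 1.0) y[i] = 1.0;
    }

    for (int i = 0; i < NS; ++i)
      if (!std::isfinite(y[i]))
        stop("non-finite state at t = %g (component %d)", (step + 1) * dt, i + 1);

    double t_next = (step + 1) * dt;
    if (t_next >= rt_start) {
      double tt = total_T(y.data());
      if (tt < t_min_val) { t_min_val = tt; t_min_time = t_next; }
    }
    if ((step + 1) % stride == 0 || step + 1 == n_steps) record(step + 1);
  }

  return List::create(
    _["times"] = times[Range(0, rec - 1)],
    _["states"] = states(Range(0, rec - 1), _),
    _["signals"] = signals(Range(0, rec - 1), _),
    _["t_min"] = t_min_val,
    _["t_min_time"] = t_min_time,
    _["clipped_mass"] = clipped);
}

// [[Rcpp::export(name = ".rhs_core")]]
NumericVector rhs_core(NumericVector y, double R, bool beam_paired, bool heat,
                       bool ims, List pars, List flags, NumericMatrix P,
                       NumericMatrix qmat, IntegerVector has_child) {
  if (y.size() != NS) stop("state vector must have length %d", NS);
  Pars p = unpack_pars(pars);
  Flags f = unpack_flags(flags);
  NumericVector dy(NS);
  double sig[3 + NAC];
  rhs(y.begin(), R, beam_paired, heat, ims, p, f, P.begin(), qmat.begin(),
      has_child.begin(), dy.begin(), sig);
  dy.attr("signals") = NumericVector(sig, sig + 3 + NAC);
  return dy;
}
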