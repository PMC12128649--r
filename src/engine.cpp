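#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Event-driven (first-reaction Gillespie) core of the motor-clutch model.
// All state is in pN / nm / s. The R layer owns parameter validation and
// seeding; this file owns the hot loop.

namespace {

constexpr double BELL_EXP_CAP = 50.0;   // keep off-rates finite
constexpr double XS_TOL = 1e-10;        // nm, force-balance tolerance

struct Pars {
  int n_c;
  int n_m;
  double F_m, v_u, F_b, k_on, k_off, k_c;
  double k_s, k_se, l, l_prime, F0, x0;
  bool canonical;
  bool bell_signed;
};

double substrate_force(double xs, const Pars &p) {
  if (p.canonical) return p.k_s * xs;
  double r = std::sqrt(p.l_prime * p.l_prime + xs * xs);
  return p.k_se * (r - p.l) * xs / r + p.k_s * xs;
}

// Root of F0 + k_c*(S - m*x) - F_s(x) = 0; strictly decreasing in x.
double solve_balance(double S, int m, const Pars &p, double hint) {
  if (p.canonical) return p.k_c * S / (p.k_s + m * p.k_c);
  if (m == 0 && p.F0 == 0.0) return 0.0;

  auto g = [&](double x) {
    return p.F0 + p.k_c * (S - m * x) - substrate_force(x, p);
  };

  double lo = 0.0;
  if (g(lo) < 0.0) {
    double step = 1.0;
    while (g(lo) < 0.0 && step < 1e12) { lo -= step; step *= 2.0; }
    if (g(lo) < 0.0) stop("equilibrium solver failed to bracket below zero");
  }
  double hi = std::max(1.0, std::max(hint, p.x0));
  int n_exp = 0;
  while (g(hi) > 0.0) {
    hi *= 2.0;
    if (++n_exp > 400) stop("equilibrium solver failed to bracket the root");
  }
  while (hi - lo > XS_TOL) {
    double mid = 0.5 * (lo + hi);
    if (mid <= lo || mid >= hi) break;  // bracket at machine resolution
    if (g(mid) > 0.0) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

double off_rate(double Fc, const Pars &p) {
  double f = p.bell_signed ? Fc : std::fabs(Fc);
  double e = f / p.F_b;
  if (e > BELL_EXP_CAP) e = BELL_EXP_CAP;
  return p.k_off * std::exp(e);
}

double hill(double load, const Pars &p) {
  double v = p.v_u * (1.0 - load / (double(p.n_m) * p.F_m));
  if (v < 0.0) v = 0.0;
  if (v > p.v_u) v = p.v_u;
  return v;
}

double u01() {
  double u = unif_rand();
  while (u <= 0.0 || u >= 1.0) u = unif_rand();
  return u;
}

struct Acc {
  double T = 0, vf = 0, xs = 0, Fs = 0, eng = 0, Fc = 0;
  void add(double dt, double vf_, double xs_, double Fs_, int eng_,
           double Fc_) {
    T += dt; vf += dt * vf_; xs += dt * xs_; Fs += dt * Fs_;
    eng += dt * eng_; Fc += dt * Fc_;
  }
};

List acc_to_list(const Acc &a) {
  return List::create(_["duration"] = a.T, _["vf"] = a.vf, _["xs"] = a.xs,
                      _["Fs"] = a.Fs, _["engaged"] = a.eng, _["Fc"] = a.Fc);
}

} // namespace

// [[Rcpp::export(name = ".clutch_engine")]]
List clutch_engine(List pars, int n_events, bool record,
                   Nullable<List> init_state) {
  Pars p;
  p.n_c = as<int>(pars["n_c"]);
  p.n_m = as<int>(pars["n_m"]);
  p.F_m = as<double>(pars["F_m"]);
  p.v_u = as<double>(pars["v_u"]);
  p.F_b = as<double>(pars["F_b"]);
  p.k_on = as<double>(pars["k_on"]);
  p.k_off = as<double>(pars["k_off"]);
  p.k_c = as<double>(pars["k_c"]);
  p.k_s = as<double>(pars["k_s"]);
  p.k_se = as<double>(pars["k_s_eps0"]);
  p.l = as<double>(pars["l"]);
  p.l_prime = as<double>(pars["l_prime"]);
  p.F0 = as<double>(pars["F0"]);
  p.x0 = as<double>(pars["x0"]);
  p.canonical = as<bool>(pars["canonical"]);
  p.bell_signed = as<bool>(pars["bell_signed"]);
  bool load_share = pars.containsElementNamed("load_share") ?
    as<bool>(pars["load_share"]) : false;

  const int n_c = p.n_c;
  std::vector<double> xc(n_c, 0.0);
  std::vector<char> eng(n_c, 0);
  double t = 0.0, xs, vf, Fs, Fc_tot;
  int m = 0;

  if (init_state.isNotNull()) {
    List st(init_state);
    t = as<double>(st["t"]);
    xs = as<double>(st["x_s"]);
    NumericVector xc0 = st["x_c"];
    LogicalVector en0 = st["engaged"];
    if (xc0.size() != n_c || en0.size() != n_c)
      stop("initial state does not match n_c");
    for (int i = 0; i < n_c; ++i) {
      xc[i] = xc0[i];
      eng[i] = en0[i] ? 1 : 0;
      if (eng[i]) ++m;
    }
  } else {
    // clutch-free equilibrium: 0 unless a transverse residual force is held
    xs = solve_balance(0.0, 0, p, 1.0);
    for (int i = 0; i < n_c; ++i) xc[i] = xs;
  }
  Fs = substrate_force(xs, p);
  {
    double S = 0.0;
    for (int i = 0; i < n_c; ++i) if (eng[i]) S += xc[i];
    Fc_tot = p.k_c * (S - double(m) * xs);
  }
  vf = hill(Fs - p.F0, p);

  // trace storage (init row + one per event)
  int cap = record ? n_events + 1 : 0;
  NumericVector tr_t(cap), tr_xs(cap), tr_Fs(cap), tr_vf(cap), tr_Fc(cap);
  IntegerVector tr_ev(cap), tr_cl(cap), tr_eng(cap);
  int row = 0;
  auto rec = [&](int ev, int cl) {
    if (!record) return;
    tr_t[row] = t; tr_ev[row] = ev; tr_cl[row] = cl;
    tr_xs[row] = xs; tr_eng[row] = m; tr_Fs[row] = Fs; tr_vf[row] = vf;
    tr_Fc[row] = Fc_tot;
    ++row;
  };
  rec(0, NA_INTEGER);

  std::vector<double> failures;
  Acc total, at_burn;
  bool burned = false;
  double t_burn = NA_REAL;

  for (int ev = 0; ev < n_events; ++ev) {
    // first-reaction: fresh exponential draw for every clutch
    double dt = R_PosInf;
    int win = -1;
    double shared_rate = 0.0;
    if (load_share && m > 0) shared_rate = off_rate((Fs - p.F0) / m, p);
    for (int i = 0; i < n_c; ++i) {
      double rate;
      if (!eng[i]) rate = p.k_on;
      else rate = load_share ? shared_rate : off_rate(p.k_c * (xc[i] - xs), p);
      double ti = -std::log(u01()) / rate;
      if (ti < dt) { dt = ti; win = i; }
    }

    total.add(dt, vf, xs, Fs, m, Fc_tot);
    t += dt;

    // advect engaged clutches with the flow computed at interval start
    for (int i = 0; i < n_c; ++i) if (eng[i]) xc[i] += vf * dt;

    if (eng[win]) {
      eng[win] = 0; --m;
    } else {
      eng[win] = 1; ++m;
      xc[win] = xs;  // binds unstretched at the current substrate position
    }

    double S = 0.0;
    for (int i = 0; i < n_c; ++i) if (eng[i]) S += xc[i];
    xs = solve_balance(S, m, p, std::max(xs, 1.0));
    for (int i = 0; i < n_c; ++i) if (!eng[i]) xc[i] = xs;

    Fs = substrate_force(xs, p);
    Fc_tot = p.k_c * (S - double(m) * xs);
    vf = hill(Fs - p.F0, p);

    if (m == 0) {
      failures.push_back(t);
      if (!burned) { burned = true; t_burn = t; at_burn = total; }
    }
    rec(eng[win] ? 1 : -1, win + 1);

    if ((ev & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List trace = R_NilValue;
  if (record) {
    trace = List::create(
      _["t"] = tr_t, _["event"] = tr_ev, _["clutch"] = tr_cl,
      _["x_s"] = tr_xs, _["engaged"] = tr_eng, _["F_s"] = tr_Fs,
      _["v_f"] = tr_vf, _["F_clutch_total"] = tr_Fc);
  }

  LogicalVector eng_out(n_c);
  NumericVector xc_out(n_c);
  for (int i = 0; i < n_c; ++i) { eng_out[i] = eng[i] != 0; xc_out[i] = xc[i]; }

  return List::create(
    _["trace"] = trace,
    _["failure_times"] = NumericVector(failures.begin(), failures.end()),
    _["acc_total"] = acc_to_list(total),
    _["acc_at_burn"] = acc_to_list(at_burn),
    _["t_burn"] = t_burn,
    _["t_end"] = t,
    _["state"] = List::create(
      _["t"] = t, _["x_s"] = xs, _["x_c"] = xc_out, _["engaged"] = eng_out,
      _["v_f"] = vf));
}
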