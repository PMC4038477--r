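#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Adaptive Dormand-Prince 5(4) with dense output on a fixed grid.
// Two built-in right-hand sides (the core-clock network and a harmonic
// test system) run without callback overhead; arbitrary R functions are
// supported through a functor wrapper for small test systems.

typedef void (*rhs_fn)(double, const double*, double*, const double*);

// Parameter layout for the core-clock RHS (order is fixed; see R side):
//  0 kt1  1 kt2  2 kt3  3 kt4  4 kt5  5 ktt
//  6 a    7 g    8 h    9 r   10 hb  11 rb  12 ab  13 gb
// 14 kp_p 15 kp_c 16 kp_b 17 k_ass
// 18 dm_p 19 dm_c 20 dm_b 21 d_R 22 d_Ra 23 dp_p 24 dp_c 25 dp_b 26 d_PC
// 27 k_seq (PER:CRY--BMAL1 mutual sequestration/annihilation rate)
// 28 Km (Michaelis constant of saturable mRNA decay; large Km ~ linear)
// 29 dummy (never used; exists to test zero control coefficients)
// States: 0 P_m, 1 C_m, 2 P_c, 3 C_c, 4 PC, 5 R, 6 R_a, 7 B_m, 8 B_p
// Three loops: BMAL1 activates Per/Cry/Rev-Erb/Ror (all scaled by ktt,
// all repressed by PER:CRY); REV-ERB represses Bmal1; ROR activates it.
static void clock_rhs(double t, const double* y, double* dy, const double* p) {
  (void)t;
  const double Pm = y[0], Cm = y[1], Pc = y[2], Cc = y[3];
  const double PC = y[4], R = y[5], Ra = y[6], Bm = y[7], Bp = y[8];
  const double act = std::pow(Bp, p[6]) / (std::pow(p[7], p[6]) + std::pow(Bp, p[6]));
  // PER:CRY represses by sequestering BMAL1:CLOCK, so the repression
  // argument is the repressor:activator ratio (stoichiometric titration).
  const double ratio = PC / std::max(Bp, 1e-12);
  const double rep = 1.0 / (1.0 + std::pow(ratio / p[9], p[8]));
  const double drive = p[5] * act * rep;           // ktt * H_act(B_p) * H_rep(PC)
  // saturable (Michaelis-Menten) mRNA decay: at levels above Km the
  // machinery runs at capacity, the classic source of relaxation-type
  // clock dynamics
  const double Km = p[28];
  dy[0] = p[0] * drive - p[18] * Pm * Km / (Km + Pm);  // Per mRNA
  dy[1] = p[1] * drive - p[19] * Cm * Km / (Km + Cm);  // Cry mRNA
  dy[5] = p[2] * drive - p[21] * R;                // REV-ERB protein (lumped)
  dy[6] = p[4] * drive - p[22] * Ra;               // ROR protein (lumped)
  const double act_b = std::pow(Ra, p[12]) /
      (std::pow(p[13], p[12]) + std::pow(Ra, p[12]));
  dy[7] = p[3] * act_b / (1.0 + std::pow(R / p[11], p[10])) -
          p[20] * Bm * Km / (Km + Bm);             // Bmal1 mRNA
  // PER:CRY titrates BMAL1 away 1:1 (mutual annihilation), the
  // stoichiometric repression that couples period to transactivation
  const double seq = p[27] * Bp * PC;
  dy[8] = p[16] * Bm - p[25] * Bp - seq;           // BMAL1 protein
  const double ass = p[17] * Pc * Cc;
  dy[2] = p[14] * Pm - ass - p[23] * Pc;           // PER protein
  dy[3] = p[15] * Cm - ass - p[24] * Cc;           // CRY protein
  dy[4] = ass - p[26] * PC - seq;                  // PER:CRY complex
}

// Harmonic test system: params[0] = omega, params[1] = dummy.
static void harmonic_rhs(double t, const double* y, double* dy, const double* p) {
  (void)t;
  dy[0] = y[1];
  dy[1] = -p[0] * p[0] * y[0];
}

struct DPResult {
  std::vector<double> t;
  std::vector<double> y; // column-major n_out x n_state
  bool ok;
};

template <typename F>
static DPResult dp45(F f, const std::vector<double>& y0, double t0, double t1,
                     double dt_out, double rtol, double atol) {
  // Dormand-Prince coefficients
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  const size_t n = y0.size();
  DPResult res;
  res.ok = true;
  size_t n_out = (size_t)std::floor((t1 - t0) / dt_out + 1e-9) + 1;
  res.t.reserve(n_out);
  res.y.assign(n_out * n, NA_REAL);

  std::vector<double> y(y0), k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), y5(n), err(n);
  double t = t0;
  double h = dt_out; // initial step
  const double hmax = (t1 - t0) / 4.0;
  size_t iout = 0;
  // record t0
  res.t.push_back(t0);
  for (size_t j = 0; j < n; ++j) res.y[0 * n + j] = y[j];
  iout = 1;
  double next_out = t0 + dt_out;

  f(t, y.data(), k1.data());
  long max_steps = 10000000;
  while (t < t1 && max_steps-- > 0) {
    if (h > hmax) h = hmax;
    if (t + h > t1) h = t1 - t;
    // stages
    for (size_t j = 0; j < n; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
    f(t + c2 * h, ytmp.data(), k2.data());
    for (size_t j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    f(t + c3 * h, ytmp.data(), k3.data());
    for (size_t j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    f(t + c4 * h, ytmp.data(), k4.data());
    for (size_t j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] + a54 * k4[j]);
    f(t + c5 * h, ytmp.data(), k5.data());
    for (size_t j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                            a64 * k4[j] + a65 * k5[j]);
    f(t + h, ytmp.data(), k6.data());
    for (size_t j = 0; j < n; ++j)
      y5[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] + b5 * k5[j] +
                          b6 * k6[j]);
    f(t + h, y5.data(), k7.data());
    // error estimate
    double errnorm = 0.0;
    for (size_t j = 0; j < n; ++j) {
      err[j] = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                    e6 * k6[j] + e7 * k7[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(y5[j]));
      double r = err[j] / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / n);
    if (!std::isfinite(errnorm)) { res.ok = false; break; }

    if (errnorm <= 1.0) {
      // accept; dense output via cubic Hermite on [t, t+h]
      double tnew = t + h;
      while (iout < n_out && next_out <= tnew + 1e-12) {
        double th = (next_out - t) / h;
        double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
        double h10 = th * (1 - th) * (1 - th);
        double h01 = th * th * (3 - 2 * th);
        double h11 = th * th * (th - 1);
        for (size_t j = 0; j < n; ++j)
          res.y[iout * n + j] = h00 * y[j] + h10 * h * k1[j] + h01 * y5[j] +
                                h11 * h * k7[j];
        res.t.push_back(next_out);
        ++iout;
        next_out = t0 + dt_out * (double)iout;
      }
      t = tnew;
      y = y5;
      k1 = k7; // FSAL
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      fac = std::min(5.0, std::max(0.2, fac));
      h *= fac;
    } else {
      double fac = std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
      h *= fac;
    }
    if (h < 1e-12) { res.ok = false; break; }
  }
  if (max_steps <= 0) res.ok = false;
  if (iout < n_out) res.y.resize(iout * n);
  return res;
}

struct BuiltinF {
  rhs_fn fn;
  const double* pars;
  void operator()(double t, const double* y, double* dy) const {
    fn(t, y, dy, pars);
  }
};

struct RFunF {
  Function f;
  size_t n;
  void operator()(double t, const double* y, double* dy) const {
    NumericVector yv(y, y + n);
    NumericVector out = f(t, yv);
    for (size_t j = 0; j < n; ++j) dy[j] = out[j];
  }
};

static List pack(const DPResult& res, size_t n) {
  size_t n_out = res.t.size();
  NumericVector tv(res.t.begin(), res.t.end());
  NumericMatrix ym((int)n_out, (int)n);
  for (size_t i = 0; i < n_out; ++i)
    for (size_t j = 0; j < n; ++j) ym((int)i, (int)j) = res.y[i * n + j];
  return List::create(_["time"] = tv, _["y"] = ym, _["ok"] = res.ok);
}

// [[Rcpp::export(name = ".dp45_builtin")]]
List dp45_builtin(std::string model, NumericVector pars, NumericVector y0,
                  double t0, double t1, double dt_out, double rtol,
                  double atol) {
  BuiltinF f;
  if (model == "core_clock") {
    if (pars.size() < 30) stop("core_clock expects 30 parameters");
    f.fn = clock_rhs;
  } else if (model == "harmonic") {
    if (pars.size() < 1) stop("harmonic expects >= 1 parameter (omega)");
    f.fn = harmonic_rhs;
  } else {
    stop("unknown builtin model '%s'", model.c_str());
  }
  f.pars = REAL(pars);
  std::vector<double> y(y0.begin(), y0.end());
  DPResult res = dp45(f, y, t0, t1, dt_out, rtol, atol);
  return pack(res, y.size());
}

// [[Rcpp::export(name = ".dp45_rfun")]]
List dp45_rfun(Function rhs, NumericVector y0, double t0, double t1,
               double dt_out, double rtol, double atol) {
  RFunF f{rhs, (size_t)y0.size()};
  std::vector<double> y(y0.begin(), y0.end());
  DPResult res = dp45(f, y, t0, t1, dt_out, rtol, atol);
  return pack(res, y.size());
}
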