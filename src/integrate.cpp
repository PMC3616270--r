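// Compiled core for the Wilson-Cowan CPG chain: right-hand side evaluation
// and time integration (fixed-step RK4 and adaptive Dormand-Prince 5(4)).
//
// State layout (one side, n segments):
//   [E_1..E_n, I_1..I_n, (S_1..S_n when sensory feedback is enabled)]
// Two-sided models stack the left block before the right block.
// Segment index 1 is the most anterior (A1), index n the most posterior (A8).

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Model {
  int n;
  double a, c, e, f;          // within-segment weights (signed)
  double kE, kI;              // response ceilings
  double tauE, tauI, tauS;
  double lamE, thE, lamI, thI, lamS, thS;
  bool sensory;
  double alpha, beta, gamma;
  bool two_sided;
  int contra_kind;            // 0 EE, 1 IE, 2 EI, 3 II
  double contra_weight;
  // chain weights per edge k (between segments k and k+1), k = 1..n-1:
  //   *_asc[k]: input segment k+1 receives from segment k
  //   *_desc[k]: input segment k receives from segment k+1
  std::vector<double> b_asc, b_desc, d_asc, d_desc;
  // drive pulses: side (0 left/only, 1 right), segment (1..n), strength,
  // onset, offset
  NumericMatrix pulses;

  int side_len() const { return sensory ? 3 * n : 2 * n; }
  int nstate() const { return (two_sided ? 2 : 1) * side_len(); }

  double sig(double x, double lam, double th) const {
    return 1.0 / (1.0 + std::exp(-lam * (x - th))) -
           1.0 / (1.0 + std::exp(lam * th));
  }

  // Per-span cached drive. Spans never straddle a pulse edge, so the
  // drive is constant within a span; it is sampled once at the span
  // midpoint, which keeps Runge-Kutta stages that land exactly on a pulse
  // edge from seeing the wrong side of the discontinuity.
  std::vector<double> drive_cache[2];

  double drive_at(double t, int seg, int side) const {
    double p = 0.0;
    for (int r = 0; r < pulses.nrow(); ++r) {
      if ((int)pulses(r, 0) == side && (int)pulses(r, 1) == seg &&
          t >= pulses(r, 3) && t < pulses(r, 4))
        p += pulses(r, 2);
    }
    return p;
  }

  void set_drive(double t) {
    for (int side = 0; side < 2; ++side) {
      drive_cache[side].assign(n, 0.0);
      for (int i = 0; i < n; ++i)
        drive_cache[side][i] = drive_at(t, i + 1, side);
    }
  }

  // derivative of one side; `other` may be NULL for a one-sided model
  void rhs_side(double t, const double* y, const double* other, int side,
                double* dy) const {
    const double* E = y;
    const double* I = y + n;
    const double* S = sensory ? y + 2 * n : nullptr;
    for (int i = 0; i < n; ++i) {
      double argE = a * E[i] + c * I[i];
      if (i > 0)     argE += b_asc[i - 1] * E[i - 1] + d_asc[i - 1] * I[i - 1];
      if (i < n - 1) argE += b_desc[i] * E[i + 1] + d_desc[i] * I[i + 1];
      double argI = e * E[i] + f * I[i];
      if (sensory) {
        argE += beta * S[i];
        argI += gamma * S[i];
      }
      argE += drive_cache[side][i];
      if (two_sided && other != nullptr) {
        const double* Eo = other;
        const double* Io = other + n;
        switch (contra_kind) {
          case 0: argE += contra_weight * Eo[i]; break;
          case 1: argE += contra_weight * Io[i]; break;
          case 2: argI += contra_weight * Eo[i]; break;
          case 3: argI += contra_weight * Io[i]; break;
        }
      }
      dy[i]     = (-E[i] + (kE - E[i]) * sig(argE, lamE, thE)) / tauE;
      dy[n + i] = (-I[i] + (kI - I[i]) * sig(argI, lamI, thI)) / tauI;
    }
    if (sensory) {
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        if (i < n - 1) s += std::max(E[i + 1] - E[i], 0.0);
        if (i > 0)     s += std::max(E[i - 1] - E[i], 0.0);
        dy[2 * n + i] = (-S[i] + sig(alpha * s, lamS, thS)) / tauS;
      }
    }
  }

  void rhs(double t, const double* y, double* dy) const {
    int L = side_len();
    if (!two_sided) {
      rhs_side(t, y, nullptr, 0, dy);
    } else {
      rhs_side(t, y, y + L, 0, dy);
      rhs_side(t, y + L, y, 1, dy + L);
    }
  }
};

Model build_model(const List& par) {
  Model m;
  m.n = as<int>(par["n"]);
  m.a = as<double>(par["a"]);
  m.c = as<double>(par["c"]);
  m.e = as<double>(par["e"]);
  m.f = as<double>(par["f"]);
  m.kE = as<double>(par["kE"]);
  m.kI = as<double>(par["kI"]);
  m.tauE = as<double>(par["tauE"]);
  m.tauI = as<double>(par["tauI"]);
  m.tauS = as<double>(par["tauS"]);
  m.lamE = as<double>(par["lamE"]);
  m.thE = as<double>(par["thE"]);
  m.lamI = as<double>(par["lamI"]);
  m.thI = as<double>(par["thI"]);
  m.lamS = as<double>(par["lamS"]);
  m.thS = as<double>(par["thS"]);
  m.sensory = as<bool>(par["sensory"]);
  m.alpha = as<double>(par["alpha"]);
  m.beta = as<double>(par["beta"]);
  m.gamma = as<double>(par["gamma"]);
  m.two_sided = as<bool>(par["two_sided"]);
  m.contra_kind = as<int>(par["contra_kind"]);
  m.contra_weight = as<double>(par["contra_weight"]);
  m.b_asc = as<std::vector<double>>(par["b_asc"]);
  m.b_desc = as<std::vector<double>>(par["b_desc"]);
  m.d_asc = as<std::vector<double>>(par["d_asc"]);
  m.d_desc = as<std::vector<double>>(par["d_desc"]);
  m.pulses = as<NumericMatrix>(par["pulses"]);
  if ((int)m.b_asc.size() != m.n - 1 || (int)m.b_desc.size() != m.n - 1 ||
      (int)m.d_asc.size() != m.n - 1 || (int)m.d_desc.size() != m.n - 1)
    stop("chain weight vectors must have n - 1 entries");
  return m;
}

void check_finite(const std::vector<double>& y, double t) {
  for (double v : y)
    if (!std::isfinite(v))
      stop("non-finite state encountered at t = %f", t);
}

// one RK4 step from t over h
void rk4_step(const Model& m, double t, double h, std::vector<double>& y,
              std::vector<double>& k1, std::vector<double>& k2,
              std::vector<double>& k3, std::vector<double>& k4,
              std::vector<double>& tmp) {
  int ns = (int)y.size();
  m.rhs(t, y.data(), k1.data());
  for (int i = 0; i < ns; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  m.rhs(t + 0.5 * h, tmp.data(), k2.data());
  for (int i = 0; i < ns; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  m.rhs(t + 0.5 * h, tmp.data(), k3.data());
  for (int i = 0; i < ns; ++i) tmp[i] = y[i] + h * k3[i];
  m.rhs(t + h, tmp.data(), k4.data());
  for (int i = 0; i < ns; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Dormand-Prince 5(4) coefficients
const double DP_C[7] = {0.0, 1.0 / 5, 3.0 / 10, 4.0 / 5, 8.0 / 9, 1.0, 1.0};
const double DP_A[7][6] = {
    {0, 0, 0, 0, 0, 0},
    {1.0 / 5, 0, 0, 0, 0, 0},
    {3.0 / 40, 9.0 / 40, 0, 0, 0, 0},
    {44.0 / 45, -56.0 / 15, 32.0 / 9, 0, 0, 0},
    {19372.0 / 6561, -25360.0 / 2187, 64448.0 / 6561, -212.0 / 729, 0, 0},
    {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247, 49.0 / 176, -5103.0 / 18656,
     0},
    {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192, -2187.0 / 6784, 11.0 / 84}};
const double DP_B5[7] = {35.0 / 384,     0, 500.0 / 1113, 125.0 / 192,
                         -2187.0 / 6784, 11.0 / 84,       0};
const double DP_B4[7] = {5179.0 / 57600,  0,           7571.0 / 16695,
                         393.0 / 640,     -92097.0 / 339200,
                         187.0 / 2100,    1.0 / 40};

// integrate adaptively from t0 to t1 (no interior drive discontinuities)
void dp45_span(Model& m, double t0, double t1, std::vector<double>& y,
               double rtol, double atol, double max_step) {
  m.set_drive(0.5 * (t0 + t1));
  int ns = (int)y.size();
  std::vector<std::vector<double>> k(7, std::vector<double>(ns));
  std::vector<double> tmp(ns), y5(ns), err(ns);
  double t = t0;
  double h = std::min(max_step, t1 - t0);
  const double hmin = 1e-10;
  while (t < t1 - 1e-12) {
    h = std::min(h, t1 - t);
    m.rhs(t, y.data(), k[0].data());
    bool accept = false;
    while (!accept) {
      for (int s = 1; s < 7; ++s) {
        for (int i = 0; i < ns; ++i) {
          double acc = 0.0;
          for (int j = 0; j < s; ++j) acc += DP_A[s][j] * k[j][i];
          tmp[i] = y[i] + h * acc;
        }
        m.rhs(t + DP_C[s] * h, tmp.data(), k[s].data());
      }
      double errnorm = 0.0;
      for (int i = 0; i < ns; ++i) {
        double acc5 = 0.0, acc4 = 0.0;
        for (int s = 0; s < 7; ++s) {
          acc5 += DP_B5[s] * k[s][i];
          acc4 += DP_B4[s] * k[s][i];
        }
        y5[i] = y[i] + h * acc5;
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
        double d = h * (acc5 - acc4) / sc;
        errnorm += d * d;
      }
      errnorm = std::sqrt(errnorm / ns);
      if (errnorm <= 1.0 || h <= hmin) {
        t += h;
        y = y5;
        double fac = errnorm > 0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
        h = std::min(max_step, h * std::min(5.0, std::max(0.2, fac)));
        accept = true;
      } else {
        double fac = 0.9 * std::pow(errnorm, -0.2);
        h *= std::min(1.0, std::max(0.1, fac));
        if (h < hmin) h = hmin;
        m.rhs(t, y.data(), k[0].data());
      }
    }
    check_finite(y, t);
  }
}

void rk4_span(Model& m, double t0, double t1, std::vector<double>& y,
              double step) {
  m.set_drive(0.5 * (t0 + t1));
  int ns = (int)y.size();
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  double span = t1 - t0;
  int nstep = std::max(1, (int)std::ceil(span / step - 1e-12));
  double h = span / nstep;
  for (int s = 0; s < nstep; ++s)
    rk4_step(m, t0 + s * h, h, y, k1, k2, k3, k4, tmp);
  check_finite(y, t1);
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector state, double t, List par) {
  Model m = build_model(par);
  if ((int)state.size() != m.nstate())
    stop("state length %d does not match model dimension %d",
         (int)state.size(), m.nstate());
  NumericVector out(state.size());
  m.set_drive(t);
  m.rhs(t, REAL(state), REAL(out));
  return out;
}

// Integrate and sample at fixed resolution; `times` must be strictly
// increasing, start at t0, and already include every drive discontinuity
// between consecutive entries handled piecewise here.
// [[Rcpp::export]]
List cpp_integrate(NumericVector init, NumericVector times,
                   NumericVector breaks, List par, std::string method,
                   double rtol, double atol, double max_step) {
  Model m = build_model(par);
  int ns = m.nstate();
  if ((int)init.size() != ns)
    stop("initial state length %d does not match model dimension %d",
         (int)init.size(), ns);
  int nt = times.size();
  NumericMatrix out(nt, ns);
  std::vector<double> y(init.begin(), init.end());
  for (int i = 0; i < ns; ++i) out(0, i) = y[i];
  bool fixed = (method == "fixed_step");
  for (int ti = 1; ti < nt; ++ti) {
    double t0 = times[ti - 1], t1 = times[ti];
    // split the span at drive discontinuities so no step straddles one
    std::vector<double> cuts;
    cuts.push_back(t0);
    for (int b = 0; b < breaks.size(); ++b)
      if (breaks[b] > t0 + 1e-12 && breaks[b] < t1 - 1e-12)
        cuts.push_back(breaks[b]);
    cuts.push_back(t1);
    for (size_t s = 0; s + 1 < cuts.size(); ++s) {
      if (fixed)
        rk4_span(m, cuts[s], cuts[s + 1], y, max_step);
      else
        dp45_span(m, cuts[s], cuts[s + 1], y, rtol, atol, max_step);
    }
    for (int i = 0; i < ns; ++i) out(ti, i) = y[i];
    if (ti % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["states"] = out);
}
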