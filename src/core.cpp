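#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Units: distance A, energy kcal/mol, time ps, mass amu.
// KCAL converts kcal/mol to amu*A^2/ps^2 so that a = KCAL * F / m.
static const double KCAL = 418.4;
static const double KB = 0.0019872041;

// Potential codes: 0 = harmonic {r0, kappa}, 1 = double well {ra, rb, barrier},
// 2 = piecewise tabulated (linear interpolation, reflective domain edges).
struct Potential {
  int type;
  double p1, p2, p3;
  const double *tg, *te;
  int tn;
  double tdr;
};

static inline double tab_energy(const Potential &P, double r) {
  if (r <= P.tg[0]) return P.te[0];
  if (r >= P.tg[P.tn - 1]) return P.te[P.tn - 1];
  double u = (r - P.tg[0]) / P.tdr;
  int i = (int)std::floor(u);
  if (i >= P.tn - 1) i = P.tn - 2;
  double f = u - i;
  return P.te[i] * (1.0 - f) + P.te[i + 1] * f;
}

static inline double pot_energy(const Potential &P, double r) {
  switch (P.type) {
  case 0: {
    double d = r - P.p1;
    return 0.5 * P.p2 * d * d;
  }
  case 1: {
    double half = 0.5 * (P.p2 - P.p1);
    double B = P.p3 / (half * half * half * half);
    double a = r - P.p1, b = r - P.p2;
    return B * a * a * b * b;
  }
  default:
    return tab_energy(P, r);
  }
}

static inline double pot_force(const Potential &P, double r) {
  switch (P.type) {
  case 0:
    return -P.p2 * (r - P.p1);
  case 1: {
    double half = 0.5 * (P.p2 - P.p1);
    double B = P.p3 / (half * half * half * half);
    double a = r - P.p1, b = r - P.p2;
    return -B * 2.0 * a * b * (a + b);
  }
  default: {
    // centered finite difference, step = grid spacing / 10
    double h = P.tdr / 10.0;
    return -(tab_energy(P, r + h) - tab_energy(P, r - h)) / (2.0 * h);
  }
  }
}

// Linear interpolation on a uniform grid, clamped to the edge values.
static inline double grid_interp(const double *g0, double dr, int n,
                                 const double *y, double r) {
  double u = (r - *g0) / dr;
  if (u <= 0.0) return y[0];
  if (u >= n - 1) return y[n - 1];
  int i = (int)std::floor(u);
  double f = u - i;
  return y[i] * (1.0 - f) + y[i + 1] * f;
}

// Run Langevin (BAOAB) dynamics of one distance-like collective variable,
// optionally depositing ensemble-biased metadynamics hills every hill_stride
// steps.  Hill heights are interpolated from hill_h_grid (precomputed in R as
// h0 / (rho_floored * exp(S_rho))).  The accumulated bias and its derivative
// are tabulated on `grid`; half-harmonic walls act outside [wall_lo, wall_hi].
// Uses R's RNG so set.seed() gives bitwise reproducibility.
// [[Rcpp::export(name = ".cv_dynamics_core")]]
List cv_dynamics_core(int pot_type, NumericVector pot_params,
                      NumericVector tab_grid, NumericVector tab_energy_v,
                      double temperature, double friction, double mass,
                      double dt, double r_start, double v_start,
                      double nsteps_d, int sample_stride, bool bias_on,
                      NumericVector grid, NumericVector hill_h_grid,
                      double sigma_g, int hill_stride, double wall_lo,
                      double wall_hi, double wall_k) {
  RNGScope scope;
  Potential P;
  P.type = pot_type;
  P.p1 = pot_params.size() > 0 ? pot_params[0] : 0.0;
  P.p2 = pot_params.size() > 1 ? pot_params[1] : 0.0;
  P.p3 = pot_params.size() > 2 ? pot_params[2] : 0.0;
  P.tg = tab_grid.begin();
  P.te = tab_energy_v.begin();
  P.tn = tab_grid.size();
  P.tdr = P.tn > 1 ? tab_grid[1] - tab_grid[0] : 1.0;

  const long long nsteps = (long long)nsteps_d;
  const int ng = grid.size();
  const double g0 = ng > 0 ? grid[0] : 0.0;
  const double gdr = ng > 1 ? grid[1] - grid[0] : 1.0;
  std::vector<double> Vb(ng, 0.0), dVb(ng, 0.0);

  const double kT = KB * temperature;
  const double c1 = std::exp(-friction * dt);
  const double sigO =
      temperature > 0.0 ? std::sqrt(kT * KCAL / mass * (1.0 - c1 * c1)) : 0.0;

  const double dom_lo = P.type == 2 ? P.tg[0] : -1e30;
  const double dom_hi = P.type == 2 ? P.tg[P.tn - 1] : 1e30;

  long long n_samp = (nsteps + sample_stride - 1) / sample_stride;
  long long n_hill = bias_on ? (nsteps + hill_stride - 1) / hill_stride : 0;
  NumericVector s_step(n_samp), s_cv(n_samp), s_bias(n_samp);
  NumericVector h_time(n_hill), h_center(n_hill), h_height(n_hill);

  double x = r_start, v = v_start;

  auto bias_energy = [&](double r) -> double {
    if (!bias_on) return 0.0;
    return grid_interp(&g0, gdr, ng, Vb.data(), r);
  };
  auto total_force = [&](double r) -> double {
    double F = pot_force(P, r);
    if (bias_on) F -= grid_interp(&g0, gdr, ng, dVb.data(), r);
    if (wall_k > 0.0) {
      if (r < wall_lo) F += wall_k * (wall_lo - r);
      else if (r > wall_hi) F -= wall_k * (r - wall_hi);
    }
    return F;
  };

  double F = total_force(x);
  long long is = 0, ih = 0;
  const double span = 6.0 * sigma_g;
  const double inv2s2 = 1.0 / (2.0 * sigma_g * sigma_g);

  for (long long t = 0; t < nsteps; ++t) {
    if (t % sample_stride == 0) {
      s_step[is] = (double)t;
      s_cv[is] = x;
      s_bias[is] = bias_energy(x);
      ++is;
    }
    if (bias_on && t % hill_stride == 0) {
      double h = grid_interp(&g0, gdr, ng, hill_h_grid.begin(), x);
      h_time[ih] = (double)t;
      h_center[ih] = x;
      h_height[ih] = h;
      ++ih;
      int klo = (int)std::ceil((x - span - g0) / gdr);
      int khi = (int)std::floor((x + span - g0) / gdr);
      if (klo < 0) klo = 0;
      if (khi > ng - 1) khi = ng - 1;
      for (int k = klo; k <= khi; ++k) {
        double d = grid[k] - x;
        double e = h * std::exp(-d * d * inv2s2);
        Vb[k] += e;
        dVb[k] += -d * 2.0 * inv2s2 * e; // dV/dr = -(d / sigma^2) * e
      }
      F = total_force(x);
    }
    // BAOAB
    v += 0.5 * dt * KCAL * F / mass;
    x += 0.5 * dt * v;
    if (P.type == 2) { // reflective walls at tabulated domain edges
      if (x < dom_lo) { x = 2.0 * dom_lo - x; v = -v; }
      if (x > dom_hi) { x = 2.0 * dom_hi - x; v = -v; }
    }
    v = c1 * v + sigO * norm_rand();
    x += 0.5 * dt * v;
    if (P.type == 2) {
      if (x < dom_lo) { x = 2.0 * dom_lo - x; v = -v; }
      if (x > dom_hi) { x = 2.0 * dom_hi - x; v = -v; }
    }
    F = total_force(x);
    v += 0.5 * dt * KCAL * F / mass;
    if (!std::isfinite(x) || !std::isfinite(v))
      stop("non-finite coordinate or velocity at step %d", (int)t);
  }

  // deposits can be skipped while the CV is off-support; trim to ih entries
  NumericVector ht(h_time.begin(), h_time.begin() + ih);
  NumericVector hc(h_center.begin(), h_center.begin() + ih);
  NumericVector hh(h_height.begin(), h_height.begin() + ih);
  return List::create(
      _["step"] = s_step, _["cv"] = s_cv, _["inst_bias"] = s_bias,
      _["hill_time"] = ht, _["hill_center"] = hc, _["hill_height"] = hh,
      _["bias_grid"] = NumericVector(Vb.begin(), Vb.end()),
      _["r_final"] = x, _["v_final"] = v);
}
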