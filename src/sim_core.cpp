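// Core kernels for the coarse-grained Langevin engine.
//
// Pair energy: U(r) = S(r) * [ 4 eps ((s/r)^10 - (s/r)^5)
//                              + (A_ij + A0) (kappa s / r) exp(-r/(kappa s)) ]
// with s = sigma_ij and S(r) a C2 quintic switch (1 below switch_on, 0 at
// cutoff). Integrator: BAOAB Langevin splitting. Distances use the minimum
// image convention in a cubic periodic box. Positions are propagated
// unwrapped; saved frames are wrapped into [0, box).

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

struct PairParams {
  int nsp;
  std::vector<double> sigma;   // nsp x nsp
  std::vector<double> aij;     // nsp x nsp
  double eps, a0, kappa, rc, ron, box;
};

static inline double min_image(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

// energy and dU/dr for one pair at distance r (r < rc assumed)
static inline void pair_eu(const PairParams& pp, double s, double a,
                           double r, double& u, double& dudr) {
  double sr = s / r;
  double sr5 = sr * sr * sr * sr * sr;
  double sr10 = sr5 * sr5;
  double lj = 4.0 * pp.eps * (sr10 - sr5);
  double dlj = 4.0 * pp.eps * (-10.0 * sr10 + 5.0 * sr5) / r;
  double lam = pp.kappa * s;
  double ex = std::exp(-r / lam);
  double dh = (a + pp.a0) * (lam / r) * ex;
  double ddh = -dh * (1.0 / r + 1.0 / lam);
  double uraw = lj + dh;
  double duraw = dlj + ddh;
  if (r <= pp.ron) {
    u = uraw;
    dudr = duraw;
  } else {
    double w = pp.rc - pp.ron;
    double t = (r - pp.ron) / w;
    double t2 = t * t;
    double sw = 1.0 - (10.0 * t2 * t - 15.0 * t2 * t2 + 6.0 * t2 * t2 * t);
    double dsw = -(30.0 * t2 - 60.0 * t2 * t + 30.0 * t2 * t2) / w;
    u = uraw * sw;
    dudr = duraw * sw + uraw * dsw;
  }
}

static void compute_forces(const PairParams& pp, const std::vector<int>& sp,
                           const std::vector<double>& x,
                           std::vector<double>& f, double& utot) {
  int n = sp.size();
  std::fill(f.begin(), f.end(), 0.0);
  utot = 0.0;
  double rc2 = pp.rc * pp.rc;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(x[3 * i] - x[3 * j], pp.box);
      double dy = min_image(x[3 * i + 1] - x[3 * j + 1], pp.box);
      double dz = min_image(x[3 * i + 2] - x[3 * j + 2], pp.box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      int si = sp[i], sj = sp[j];
      double s = pp.sigma[si * pp.nsp + sj];
      double a = pp.aij[si * pp.nsp + sj];
      double u, dudr;
      pair_eu(pp, s, a, r, u, dudr);
      utot += u;
      double fr = -dudr / r;  // force magnitude / r
      f[3 * i] += fr * dx;
      f[3 * i + 1] += fr * dy;
      f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx;
      f[3 * j + 1] -= fr * dy;
      f[3 * j + 2] -= fr * dz;
    }
  }
}

static PairParams make_pp(NumericMatrix sigma_ij, NumericMatrix A_ij,
                          double eps, double a0, double kappa,
                          double cutoff, double switch_on, double box) {
  PairParams pp;
  pp.nsp = sigma_ij.nrow();
  pp.sigma.assign(sigma_ij.begin(), sigma_ij.end());
  pp.aij.assign(A_ij.begin(), A_ij.end());
  // stored column-major by Rcpp; matrices are symmetric so row/col order is
  // irrelevant, but index as si * nsp + sj for clarity
  pp.eps = eps;
  pp.a0 = a0;
  pp.kappa = kappa;
  pp.rc = cutoff;
  pp.ron = switch_on;
  pp.box = box;
  return pp;
}

// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix coords, IntegerVector species0,
                            NumericMatrix sigma_ij, NumericMatrix A_ij,
                            double eps, double a0, double kappa,
                            double cutoff, double switch_on, double box) {
  PairParams pp = make_pp(sigma_ij, A_ij, eps, a0, kappa, cutoff, switch_on, box);
  int n = coords.nrow();
  std::vector<int> sp(species0.begin(), species0.end());
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  double u;
  compute_forces(pp, sp, x, f, u);
  return u;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix coords, IntegerVector species0,
                         NumericMatrix sigma_ij, NumericMatrix A_ij,
                         double eps, double a0, double kappa,
                         double cutoff, double switch_on, double box) {
  PairParams pp = make_pp(sigma_ij, A_ij, eps, a0, kappa, cutoff, switch_on, box);
  int n = coords.nrow();
  std::vector<int> sp(species0.begin(), species0.end());
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  double u;
  compute_forces(pp, sp, x, f, u);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = f[3 * i + k];
  return out;
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords, IntegerVector species0,
                      NumericMatrix sigma_ij, NumericMatrix A_ij,
                      double eps, double a0, double kappa,
                      double cutoff, double switch_on, double box,
                      NumericVector mass_sp, double kT, double gamma,
                      double dt, int n_steps, int save_every,
                      int seed, bool save_first) {
  PairParams pp = make_pp(sigma_ij, A_ij, eps, a0, kappa, cutoff, switch_on, box);
  int n = coords.nrow();
  std::vector<int> sp(species0.begin(), species0.end());
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), m(n), invm(n), osig(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
    m[i] = mass_sp[sp[i]];
    invm[i] = 1.0 / m[i];
  }
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  for (int i = 0; i < n; ++i) osig[i] = c2 * std::sqrt(kT * invm[i]);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  // Maxwell-Boltzmann start velocities
  for (int i = 0; i < n; ++i) {
    double vs = std::sqrt(kT * invm[i]);
    for (int k = 0; k < 3; ++k) v[3 * i + k] = vs * gauss(rng);
  }

  double utot;
  compute_forces(pp, sp, x, f, utot);
  double fmax = 0.0;
  int fmax_i = -1;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k)
      if (std::fabs(f[3 * i + k]) > fmax) { fmax = std::fabs(f[3 * i + k]); fmax_i = i; }
  if (fmax > 1e8 || !std::isfinite(utot)) {
    stop("force overflow in the starting configuration (max |F| = %g kJ/mol/nm on particle %d); particles overlap",
         fmax, fmax_i + 1);
  }

  int n_frames = n_steps / save_every + (save_first ? 1 : 0);
  NumericVector frames(static_cast<R_xlen_t>(n_frames) * n * 3);
  NumericVector times(n_frames);
  NumericVector epot(n_frames), ekin(n_frames);
  int fidx = 0;
  auto save_frame = [&](int step) {
    double ek = 0.0;
    for (int i = 0; i < n; ++i) {
      double w;
      for (int k = 0; k < 3; ++k) {
        w = x[3 * i + k] - box * std::floor(x[3 * i + k] / box);
        frames[static_cast<R_xlen_t>(fidx) * n * 3 + i + static_cast<R_xlen_t>(k) * n] = w;
        ek += 0.5 * m[i] * v[3 * i + k] * v[3 * i + k];
      }
    }
    times[fidx] = step * dt;
    epot[fidx] = utot;
    ekin[fidx] = ek;
    ++fidx;
  };
  if (save_first) save_frame(0);

  double half_dt = 0.5 * dt;
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] += half_dt * f[3 * i + k] * invm[i];
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += half_dt * v[i];
    // O
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] = c1 * v[3 * i + k] + osig[i] * gauss(rng);
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += half_dt * v[i];
    // B
    compute_forces(pp, sp, x, f, utot);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] += half_dt * f[3 * i + k] * invm[i];

    if (step % save_every == 0) {
      if (!std::isfinite(utot)) {
        stop("NaN/Inf potential energy at step %d; last good frame index %d",
             step, fidx);
      }
      save_frame(step);
      if (step % (save_every * 16) == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix final_coords(n, 3);
  NumericMatrix final_vel(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      final_coords(i, k) = x[3 * i + k] - box * std::floor(x[3 * i + k] / box);
      final_vel(i, k) = v[3 * i + k];
    }
  frames.attr("dim") = IntegerVector::create(n, 3, n_frames);
  return List::create(
    _["frames"] = frames, _["times_ps"] = times,
    _["potential_kJmol"] = epot, _["kinetic_kJmol"] = ekin,
    _["final_coords"] = final_coords, _["final_velocities"] = final_vel);
}
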