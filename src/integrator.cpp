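#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "kc_ff.h"
#include "kc_rng.h"

using namespace Rcpp;

// Langevin leap-frog (BAOAB splitting): one force evaluation per step,
// exact Ornstein-Uhlenbeck factors for the friction/noise substep, so the
// stationary velocity distribution is Maxwell-Boltzmann for any gamma*dt
// and the gamma = 0 limit is plain (symplectic) velocity Verlet.
//
// [[Rcpp::export(name = ".integrate_cpp")]]
List integrate_cpp(NumericMatrix coords0, Nullable<NumericMatrix> vel0,
                   List ff, double dt, double gamma, double kT,
                   double n_steps_d, int record_stride, double seed,
                   NumericVector masses) {
  const long long n_steps = (long long)n_steps_d;
  kc::FFData d = kc::parse_ff(ff);
  const int n = coords0.nrow();
  if ((int)masses.size() != n) stop("masses length mismatch");

  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords0(i, k);

  kc::RNG rng((uint64_t)(seed + 0.5) * 2862933555777941757ULL + 3037000493ULL);

  if (vel0.isNotNull()) {
    NumericMatrix v0(vel0);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] = v0(i, k);
  } else {
    // Maxwell-Boltzmann draw at the run temperature
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(kT / masses[i]);
      for (int k = 0; k < 3; ++k) v[3 * i + k] = s * rng.normal();
    }
  }

  const double a = std::exp(-gamma * dt);
  std::vector<double> bfac(n);
  for (int i = 0; i < n; ++i)
    bfac[i] = std::sqrt(kT * (1.0 - a * a) / masses[i]);

  const long long n_frames = n_steps / record_stride + 1;
  NumericVector frames((R_xlen_t)(3 * n) * n_frames);
  NumericVector epot(n_frames), ekin(n_frames), steps(n_frames);

  double comps[6];
  double e = kc::eval_ff(d, x.data(), n, f.data(), nullptr);
  (void)e;

  long long fr = 0;
  auto record = [&](long long step) {
    double ep = kc::eval_ff(d, x.data(), n, nullptr, comps);
    double ek = 0;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        ek += 0.5 * masses[i] * v[3 * i + k] * v[3 * i + k];
    for (int i = 0; i < 3 * n; ++i) frames[(R_xlen_t)fr * 3 * n + i] = x[i];
    epot[fr] = ep; ekin[fr] = ek; steps[fr] = (double)step;
    ++fr;
  };
  record(0);

  for (long long s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n; ++i) {
      double hm = 0.5 * dt / masses[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += hm * f[3 * i + k];
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (gamma > 0.0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          v[3 * i + k] = a * v[3 * i + k] + bfac[i] * rng.normal();
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];

    kc::eval_ff(d, x.data(), n, f.data(), nullptr);
    bool bad = false;
    for (int i = 0; i < 3 * n && !bad; ++i)
      if (!std::isfinite(f[i]) || !std::isfinite(x[i])) bad = true;
    if (bad)
      stop("integration diverged at step %lld (last valid frame %lld)",
           s, fr - 1);
    for (int i = 0; i < n; ++i) {
      double hm = 0.5 * dt / masses[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += hm * f[3 * i + k];
    }
    if (s % record_stride == 0) record(s);
  }

  NumericMatrix vfin(n, 3), xfin(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      vfin(i, k) = v[3 * i + k];
      xfin(i, k) = x[3 * i + k];
    }
  frames.attr("dim") = IntegerVector::create(3, n, (int)n_frames);
  return List::create(_["frames"] = frames, _["step"] = steps,
                      _["epot"] = epot, _["ekin"] = ekin,
                      _["final_coords"] = xfin, _["final_vel"] = vfin);
}
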