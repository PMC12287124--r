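#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stationary damped Langevin motion in 3D (a stochastic harmonic oscillator):
//   dx = v dt
//   dv = (-k (x - mu) - g v) dt + s dW
// with g = 1/tau, k = (sigma_v / sigma_x)^2 and s = sigma_v * sqrt(2 g),
// giving stationary per-component sds sigma_x (position) and sigma_v
// (velocity). Velocity is continuous, so the sampled path length converges
// with the sampling rate, unlike a position-level OU process whose arc
// length diverges. Uses R's RNG so set.seed() controls reproducibility.

// [[Rcpp::export(name = ".sim_motion")]]
NumericMatrix sim_motion(int n, double dt, double sigma_x, double sigma_v,
                         double tau) {
  NumericMatrix out(n, 3);
  if (n <= 0) return out;
  const double g = 1.0 / tau;
  const double k = (sigma_v / sigma_x) * (sigma_v / sigma_x);
  const double s = sigma_v * std::sqrt(2.0 * g);
  const double sq = s * std::sqrt(dt);
  double x[3], v[3];
  for (int c = 0; c < 3; ++c) {
    x[c] = R::rnorm(0.0, sigma_x);
    v[c] = R::rnorm(0.0, sigma_v);
    out(0, c) = x[c];
  }
  for (int i = 1; i < n; ++i) {
    for (int c = 0; c < 3; ++c) {
      v[c] += (-k * x[c] - g * v[c]) * dt + sq * R::norm_rand();
      x[c] += v[c] * dt;
      out(i, c) = x[c];
    }
  }
  return out;
}
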