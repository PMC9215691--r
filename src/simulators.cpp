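#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Wrap an angle into (-pi, pi].
static inline double wrap_pi(double x) {
  double y = std::remainder(x, 2.0 * M_PI);
  if (y <= -M_PI) y += 2.0 * M_PI;
  return y;
}

// Theta-neuron network integrator (Euler-Maruyama).
//
// dtheta_i = [(1 - cos theta_i) + (1 + cos theta_i) * I_i] dt
// I_i      = I0 + (sigma/sqrt(dt)) eta_i + (K/N) sum_j W(j,i) [1 - cos(theta_j - theta_s)]
//
// All nodes start at the stable fixed point theta_s. A sample is classified
// seizure-like when the wrapped distance from theta_s exceeds the distance
// to the unstable fixed point theta_u (the escape arc through pi).
// Returns the per-node fraction of post-transient samples that are ictal.
// Noise uses R's RNG (seed via set.seed in the caller) unless a noise
// matrix (n_nodes x n_steps, standard normal) is supplied.
// [[Rcpp::export]]
NumericVector theta_sim_cpp(NumericMatrix W, double I0, double sigma, double K,
                            double dt, int n_steps, int transient_steps,
                            Nullable<NumericMatrix> noise = R_NilValue) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  // For I0 >= 0 the fixed points have merged (SNIC bifurcation): start at
  // the ghost point 0 and classify any displacement as seizure-like.
  const double theta_s =
      I0 < 0 ? -std::acos((1.0 + I0) / (1.0 - I0)) : 0.0;
  // Escape arc: phases whose counterclockwise offset from theta_s exceeds
  // theta_u - theta_s, i.e. the arc from theta_u through pi back to theta_s.
  const double arc = -2.0 * theta_s; // theta_u - theta_s
  const double sq = sigma / std::sqrt(dt);

  std::vector<double> theta(n, theta_s), out(n, 0.0), drive(n);
  NumericMatrix eta;
  bool has_noise = noise.isNotNull();
  if (has_noise) {
    eta = NumericMatrix(noise);
    if (eta.nrow() != n || eta.ncol() < n_steps)
      stop("noise matrix must be n_nodes x n_steps");
  }
  std::vector<long> ictal(n, 0);
  // Escape-arc occupancy with crossing bookkeeping: a node turns ictal when
  // its counterclockwise offset from theta_s crosses the unstable point
  // (offset arc = theta_u - theta_s) in a forward step, and turns resting
  // again when the offset drops back to <= arc -- either by falling back
  // into the well or by completing the rotation (offset wraps past 2*pi).
  // Pure pointwise arc membership would count the sub-theta_s half of
  // ordinary resting noise as ictal.
  std::vector<char> state(n, 0);
  std::vector<double> d_prev(n, 0.0);
  const double scale = (n > 0) ? K / n : 0.0;

  for (int k = 0; k < n_steps; ++k) {
    // node outputs relative to the resting phase
    for (int j = 0; j < n; ++j) drive[j] = 1.0 - std::cos(theta[j] - theta_s);
    for (int i = 0; i < n; ++i) {
      double coup = 0.0;
      for (int j = 0; j < n; ++j) coup += W(j, i) * drive[j];
      double e = has_noise ? eta(i, k) : (sigma > 0 ? norm_rand() : 0.0);
      double I = I0 + sq * e + scale * coup;
      double c = std::cos(theta[i]);
      double th = theta[i] + dt * ((1.0 - c) + (1.0 + c) * I);
      if (!std::isfinite(th))
        stop("non-finite state at step %d, node %d", k + 1, i + 1);
      th = wrap_pi(th);
      theta[i] = th;
      double x = th - theta_s;
      double d = x - 2.0 * M_PI * std::floor(x / (2.0 * M_PI));
      double dd = d - d_prev[i];
      if (!state[i] && d > arc && d_prev[i] <= arc && dd > 0 && dd < M_PI)
        state[i] = 1;
      else if (state[i] && d <= arc)
        state[i] = 0;
      d_prev[i] = d;
      if (k >= transient_steps && state[i]) ictal[i] += 1;
    }
  }
  NumericVector frac(n);
  const double denom = n_steps - transient_steps;
  for (int i = 0; i < n; ++i) frac[i] = denom > 0 ? ictal[i] / denom : 0.0;
  return frac;
}

// Stochastic Kuramoto-type phase oscillators with pairwise target lags.
//
// dtheta_i = [omega_i + sum_j g(i,j) sin(theta_j - theta_i + lag(i,j))] dt
//            + phase_noise_sd * sqrt(dt) * eta_i
//
// g = coupling_gain * pair_coupling (rad/s); lag(i,j) is the phase by which
// channel i is pulled to lead channel j. Returns the n x n_steps phase matrix.
// [[Rcpp::export]]
NumericMatrix kuramoto_sim_cpp(NumericMatrix gain, NumericMatrix lag,
                               NumericVector omega, double phase_noise_sd,
                               double dt, int n_steps, NumericVector theta0) {
  const int n = gain.nrow();
  if (gain.ncol() != n || lag.nrow() != n || lag.ncol() != n)
    stop("gain and lag must be square matrices of equal size");
  if (omega.size() != n || theta0.size() != n)
    stop("omega and theta0 must have one entry per channel");
  NumericMatrix phases(n, n_steps);
  std::vector<double> theta(n), dth(n);
  for (int i = 0; i < n; ++i) theta[i] = theta0[i];
  const double sq = phase_noise_sd * std::sqrt(dt);

  for (int k = 0; k < n_steps; ++k) {
    for (int i = 0; i < n; ++i) {
      double drift = 0.0;
      for (int j = 0; j < n; ++j) {
        double g = gain(i, j);
        if (g != 0.0) drift += g * std::sin(theta[j] - theta[i] + lag(i, j));
      }
      dth[i] = dt * (omega[i] + drift) +
               (phase_noise_sd > 0 ? sq * norm_rand() : 0.0);
    }
    for (int i = 0; i < n; ++i) {
      theta[i] = wrap_pi(theta[i] + dth[i]);
      phases(i, k) = theta[i];
    }
  }
  return phases;
}
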