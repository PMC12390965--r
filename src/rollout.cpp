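#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Population rollout: run one full cart-pole episode per release-sample set
// through the recurrent LIF spiking network and return the episodic returns.
//
// Weight arrays are (rows x cols x slices), column-major; slices = number of
// population members, or 1 to broadcast a single weight set across all
// episodes (deterministic evaluation). All randomness lives in R: initial
// states and weights are inputs, the dynamics here are pure arithmetic and
// match the R reference implementation step for step. Hidden neurons are
// split half excitatory / half inhibitory; only spike signs differ.
//
// [[Rcpp::export]]
NumericVector cartpole_population_returns_cpp(
    NumericVector w_in, NumericVector w_rec, NumericVector w_out,
    NumericMatrix init_states, NumericVector obs_scale,
    double mem_decay, double syn_decay, double threshold, double reset,
    double v_min, double readout_decay, int max_steps) {

  IntegerVector d_in = w_in.attr("dim");
  IntegerVector d_rec = w_rec.attr("dim");
  IntegerVector d_out = w_out.attr("dim");
  const int hidden = d_in[0];
  const int in_dim = d_in[1];          // balanced observation dimension
  const int out_dim = d_out[0];
  const int n_ep = init_states.nrow();
  const int s_in = d_in[2], s_rec = d_rec[2], s_out = d_out[2];
  if (d_rec[0] != hidden || d_rec[1] != hidden || d_out[1] != hidden)
    stop("inconsistent weight dimensions");
  if (init_states.ncol() != 4 || in_dim != 8 || obs_scale.size() != 4)
    stop("cart-pole rollout expects 4 state variables (balanced to 8)");
  const double s0 = obs_scale[0], s1 = obs_scale[1], s2 = obs_scale[2],
      s3 = obs_scale[3];
  const int half = hidden / 2;

  // standard cart-pole constants
  const double gravity = 9.8, mass_cart = 1.0, mass_pole = 0.1;
  const double half_length = 0.5, force_mag = 10.0, dt = 0.02;
  const double total_mass = mass_cart + mass_pole;
  const double pml = mass_pole * half_length;
  const double x_limit = 2.4, theta_limit = 12.0 * M_PI / 180.0;

  NumericVector returns(n_ep);
  std::vector<double> v(hidden), isyn(hidden), cur(hidden), rcur(hidden),
      spikes(hidden);
  std::vector<double> y(out_dim), yadd(out_dim), u(in_dim);

  const double *p_in_all = w_in.begin();
  const double *p_rec_all = w_rec.begin();
  const double *p_out_all = w_out.begin();

  for (int n = 0; n < n_ep; ++n) {
    const double *p_in = p_in_all + (size_t)(s_in == 1 ? 0 : n) * hidden * in_dim;
    const double *p_rec = p_rec_all + (size_t)(s_rec == 1 ? 0 : n) * hidden * hidden;
    const double *p_out = p_out_all + (size_t)(s_out == 1 ? 0 : n) * out_dim * hidden;

    double x = init_states(n, 0), x_dot = init_states(n, 1);
    double theta = init_states(n, 2), theta_dot = init_states(n, 3);
    std::fill(v.begin(), v.end(), 0.0);
    std::fill(isyn.begin(), isyn.end(), 0.0);
    std::fill(spikes.begin(), spikes.end(), 0.0);
    std::fill(y.begin(), y.end(), 0.0);

    int steps = 0;
    bool done = false;
    while (!done && steps < max_steps) {
      // balanced input current: W_in @ concat(obs, -obs)
      u[0] = x / s0; u[1] = x_dot / s1; u[2] = theta / s2;
      u[3] = theta_dot / s3;
      u[4] = -u[0]; u[5] = -u[1]; u[6] = -u[2]; u[7] = -u[3];
      std::fill(cur.begin(), cur.end(), 0.0);
      for (int j = 0; j < in_dim; ++j) {
        const double uj = u[j];
        const double *col = p_in + (size_t)j * hidden;
        for (int i = 0; i < hidden; ++i) cur[i] += col[i] * uj;
      }
      // recurrent drive from last step's spikes (inhibitory half negated);
      // zero spikes contribute exactly zero, so they can be skipped.
      // Accumulated in its own buffer and added once, mirroring the R
      // reference `W_in %*% u + W_rec %*% s`.
      std::fill(rcur.begin(), rcur.end(), 0.0);
      for (int j = 0; j < hidden; ++j) {
        if (spikes[j] == 0.0) continue;
        const double sj = (j < half) ? 1.0 : -1.0;
        const double *col = p_rec + (size_t)j * hidden;
        for (int i = 0; i < hidden; ++i) rcur[i] += col[i] * sj;
      }
      for (int i = 0; i < hidden; ++i) cur[i] += rcur[i];
      // LIF step: exponential synapse, leaky membrane, threshold, reset
      for (int i = 0; i < hidden; ++i) {
        isyn[i] = syn_decay * isyn[i] + cur[i];
        double vi = mem_decay * v[i] + isyn[i];
        if (vi >= threshold) { spikes[i] = 1.0; vi = reset; }
        else spikes[i] = 0.0;
        if (vi < v_min) vi = v_min;
        v[i] = vi;
      }
      // non-spiking leaky-integrator readout
      std::fill(yadd.begin(), yadd.end(), 0.0);
      for (int j = 0; j < hidden; ++j) {
        if (spikes[j] == 0.0) continue;
        const double sj = (j < half) ? 1.0 : -1.0;
        const double *col = p_out + (size_t)j * out_dim;
        for (int k = 0; k < out_dim; ++k) yadd[k] += col[k] * sj;
      }
      int action = 0;
      double best = readout_decay * y[0] + yadd[0];
      y[0] = best;
      for (int k = 1; k < out_dim; ++k) {
        y[k] = readout_decay * y[k] + yadd[k];
        if (y[k] > best) { best = y[k]; action = k; }
      }
      // cart-pole Euler step (position updated with the old velocity)
      const double force = (action == 1) ? force_mag : -force_mag;
      const double cth = std::cos(theta), sth = std::sin(theta);
      const double temp = (force + pml * theta_dot * theta_dot * sth) / total_mass;
      const double theta_acc = (gravity * sth - cth * temp) /
        (half_length * (4.0 / 3.0 - mass_pole * cth * cth / total_mass));
      const double x_acc = temp - pml * theta_acc * cth / total_mass;
      x += dt * x_dot;
      x_dot += dt * x_acc;
      theta += dt * theta_dot;
      theta_dot += dt * theta_acc;
      ++steps;
      done = std::fabs(x) > x_limit || std::fabs(theta) > theta_limit ||
        steps >= max_steps;
    }
    returns[n] = (double)steps;
  }
  return returns;
}
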