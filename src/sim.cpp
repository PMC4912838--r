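// Generative model of presynaptic population activity: two-state Markov
// switching, multivariate OU membrane potentials (Euler-Maruyama), and
// exponential-link Bernoulli-bin spiking with refractoriness and release-
// probability thinning. All rates are per-ms, all times in ms. Uses R's RNG
// so set.seed() on the R side gives bitwise reproducibility.
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// Binary state path. z[t] is the state occupied during bin [t*dt, (t+1)*dt);
// z[0] = init, transitions applied between consecutive bins with
// probabilities p_on = Omega_plus*dt (0 -> 1) and p_off = Omega_minus*dt.
// [[Rcpp::export]]
IntegerVector cpp_sim_switch(double p_on, double p_off, double n_bins_d,
                             int init) {
  R_xlen_t n_bins = (R_xlen_t)n_bins_d;
  IntegerVector z(n_bins);
  int state = init;
  if (n_bins > 0) z[0] = state;
  for (R_xlen_t t = 1; t < n_bins; ++t) {
    double u = unif_rand();
    if (state == 1) {
      if (u < p_off) state = 0;
    } else {
      if (u < p_on) state = 1;
    }
    z[t] = state;
  }
  return z;
}

// Streaming epoch statistics of the switching chain; never materializes the
// path, so very long horizons (1e9+ bins) stay in O(1) memory. Only completed
// epochs (both endpoints observed) enter the dwell-time sums.
// [[Rcpp::export]]
List cpp_switch_stats(double p_on, double p_off, double n_bins_d, int init) {
  long long n_bins = (long long)n_bins_d;
  int state = init;
  long long cur_len = 1;
  bool cur_open = true; // first epoch is left-censored: drop it
  long long n_act = 0, n_qui = 0;
  double act_bins = 0.0, qui_bins = 0.0;
  long long n_activations = 0;
  double active_occ = (state == 1) ? 1.0 : 0.0;
  for (long long t = 1; t < n_bins; ++t) {
    if ((t & 0xFFFFFF) == 0) Rcpp::checkUserInterrupt();
    double u = unif_rand();
    int ns = state;
    if (state == 1) {
      if (u < p_off) ns = 0;
    } else {
      if (u < p_on) ns = 1;
    }
    if (ns != state) {
      if (!cur_open) {
        if (state == 1) { n_act++; act_bins += cur_len; }
        else           { n_qui++; qui_bins += cur_len; }
      }
      if (state == 0) n_activations++;
      cur_open = false;
      cur_len = 1;
    } else {
      cur_len++;
    }
    state = ns;
    if (state == 1) active_occ += 1.0;
  }
  return List::create(
    _["n_active_epochs"] = (double)n_act,
    _["n_quiescent_epochs"] = (double)n_qui,
    _["active_bins"] = act_bins,
    _["quiescent_bins"] = qui_bins,
    _["n_activations"] = (double)n_activations,
    _["active_occupancy"] = active_occ / (double)n_bins);
}

// Euler-Maruyama realization of the state-dependent mOU process
//   du = dt/tau * (ubar(z) - u) + sqrt(dt) * L eps,  LL' = Q
// z has length T with entries 0/1; ubar(z) = +ubar for z=1, -ubar for z=0.
// Column t of the result is the potential during bin t; column 0 equals u0.
// [[Rcpp::export]]
arma::mat cpp_sim_mou(const arma::ivec& z, double ubar, double tau,
                      const arma::mat& L, double dt, const arma::vec& u0) {
  arma::uword T = z.n_elem, N = u0.n_elem;
  arma::mat U(N, T);
  arma::vec u = u0;
  U.col(0) = u;
  const double a = dt / tau, sdt = std::sqrt(dt);
  arma::vec eps(N);
  bool noise = arma::any(arma::vectorise(arma::abs(L)) > 0);
  for (arma::uword t = 1; t < T; ++t) {
    double base = z[t] == 1 ? ubar : -ubar;
    for (arma::uword i = 0; i < N; ++i) eps[i] = norm_rand();
    u += a * (base - u);
    if (noise) u += sdt * (L * eps);
    U.col(t) = u;
  }
  return U;
}

// Bernoulli-bin spike generation with rate g*exp(beta*u), absolute refractory
// period on *generation*, and post-hoc thinning with transmission probability
// prel (a suppressed spike still starts the refractory period). Spike times
// are the left edge of the bin. Returns all generated events with a
// transmitted flag plus the largest per-bin spike probability encountered.
// [[Rcpp::export]]
List cpp_sim_spikes(const arma::mat& U, double g_ms, double beta, double dt,
                    double tau_refr, double prel) {
  arma::uword N = U.n_rows, T = U.n_cols;
  R_xlen_t refr_bins = (R_xlen_t)std::ceil(tau_refr / dt - 1e-12);
  std::vector<int> neuron;
  std::vector<double> time;
  std::vector<int> transmitted;
  double max_p = 0.0;
  for (arma::uword i = 0; i < N; ++i) {
    R_xlen_t next_ok = 0;
    for (arma::uword t = 0; t < T; ++t) {
      if ((R_xlen_t)t < next_ok) continue;
      double p = dt * g_ms * std::exp(beta * U(i, t));
      if (p > max_p) max_p = p;
      if (unif_rand() < p) {
        neuron.push_back((int)i);
        time.push_back(t * dt);
        transmitted.push_back(prel >= 1.0 ? 1 : (unif_rand() < prel ? 1 : 0));
        next_ok = (R_xlen_t)t + refr_bins;
      }
    }
  }
  return List::create(_["neuron"] = wrap(neuron), _["time"] = wrap(time),
                      _["transmitted"] = wrap(transmitted),
                      _["max_p"] = max_p);
}
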