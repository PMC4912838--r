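// Bootstrap particle filter for the switching mOU + exponential-link spiking
// model: prior-dynamics proposal, Poisson bin likelihood with refractory
// zeroing, log-weights, systematic resampling when ESS drops below a
// threshold. Serves as the independent oracle for the assumed-density filter.
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
List cpp_pf_run(const IntegerVector& spike_bin, const IntegerVector& spike_neuron,
                double n_bins_d, double dt,
                double ubar, double tau, const arma::mat& L_step,
                const arma::mat& L_stat, double g_ms, double beta,
                double tau_refr, double omp, double omm,
                double zeta0, int n_particles, double ess_frac) {
  R_xlen_t T = (R_xlen_t)n_bins_d;
  arma::uword N = L_stat.n_rows;
  int M = n_particles;
  const double p_on = omp * dt, p_off = omm * dt;

  // stationary initialization
  arma::ivec z(M);
  arma::mat u(N, M);
  arma::vec eps(N);
  for (int m = 0; m < M; ++m) {
    z[m] = (unif_rand() < zeta0) ? 1 : 0;
    for (arma::uword i = 0; i < N; ++i) eps[i] = norm_rand();
    u.col(m) = (z[m] == 1 ? ubar : -ubar) * arma::ones(N) + L_stat * eps;
  }
  arma::vec lw(M, arma::fill::zeros);
  arma::vec refr(N, arma::fill::zeros);
  std::vector<int> spk(N);

  NumericVector o_zeta(T), o_ess(T);
  arma::mat o_mean(N, T), o_sd(N, T);
  const double a = dt / tau, sdt = std::sqrt(dt);
  bool noise = arma::any(arma::vectorise(arma::abs(L_step)) > 0);
  R_xlen_t si = 0, ns = spike_bin.size();

  for (R_xlen_t t = 0; t < T; ++t) {
    if ((t & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    // observations in this bin
    std::fill(spk.begin(), spk.end(), 0);
    bool any_spk = false;
    R_xlen_t s0 = si;
    while (si < ns && spike_bin[si] == t) { spk[spike_neuron[si]] = 1; any_spk = true; ++si; }

    // propagate through the prior dynamics
    for (int m = 0; m < M; ++m) {
      if (z[m] == 1) { if (unif_rand() < p_off) z[m] = 0; }
      else           { if (unif_rand() < p_on)  z[m] = 1; }
      double base = z[m] == 1 ? ubar : -ubar;
      for (arma::uword i = 0; i < N; ++i) eps[i] = norm_rand();
      u.col(m) += a * (base - u.col(m));
      if (noise) u.col(m) += sdt * (L_step * eps);
    }

    // advance refractory clocks, then weight by the bin likelihood
    for (arma::uword i = 0; i < N; ++i)
      if (refr[i] > 0) refr[i] -= dt;
    for (int m = 0; m < M; ++m) {
      double l = 0.0;
      for (arma::uword i = 0; i < N; ++i) {
        if (refr[i] > 0) continue; // gamma treated as 0: flat likelihood
        double r = g_ms * std::exp(beta * u(i, m));
        l += spk[i] ? (std::log(r * dt) - r * dt) : (-r * dt);
      }
      lw[m] += l;
    }
    (void)s0;
    for (arma::uword i = 0; i < N; ++i)
      if (spk[i]) refr[i] = tau_refr;

    // normalize
    double mx = lw.max();
    if (!std::isfinite(mx))
      stop("particle filter degeneracy: all weights vanished at t = %f ms",
           (double)t * dt);
    arma::vec wn = arma::exp(lw - mx);
    double sw = arma::accu(wn);
    wn /= sw;
    double ess = 1.0 / arma::accu(arma::square(wn));
    o_ess[t] = ess;

    // posterior means / sds under the weighted ensemble
    double zh = 0.0;
    for (int m = 0; m < M; ++m) if (z[m] == 1) zh += wn[m];
    o_zeta[t] = zh;
    arma::vec m1 = u * wn;
    arma::vec m2 = arma::square(u) * wn;
    o_mean.col(t) = m1;
    arma::vec v = m2 - arma::square(m1);
    v.transform([](double x) { return x < 0 ? 0.0 : x; });
    o_sd.col(t) = arma::sqrt(v);

    // systematic resampling
    if (ess < ess_frac * M) {
      arma::vec cum = arma::cumsum(wn);
      double u0 = unif_rand() / M;
      arma::ivec nz(M);
      arma::mat nu(N, M);
      int j = 0;
      for (int m = 0; m < M; ++m) {
        double target = u0 + (double)m / M;
        while (j < M - 1 && cum[j] < target) ++j;
        nz[m] = z[j];
        nu.col(m) = u.col(j);
      }
      z = nz; u = nu;
      lw.zeros();
    }
  }
  return List::create(_["zeta"] = o_zeta, _["u_mean"] = o_mean,
                      _["u_sd"] = o_sd, _["ess"] = o_ess);
}
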