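// Assumed-density filter for spike-train observations of a switching mOU
// population. Posterior family: Bernoulli over the global state (zeta) times
// a state-conditioned multivariate normal (mu+/-, Sigma+/-). Explicit Euler
// on the drift terms, first-order jump updates at observed spikes, gamma
// terms zeroed while a neuron's refractory clock runs. All rates per-ms.
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

static const double ZETA_EPS = 1e-6;
static const double VAR_FLOOR = 1e-12;

// on-demand eigenvalue floor: only invoked when a posterior variance has
// been driven below the floor (possible for stiff link functions at finite dt)
static void floor_psd(arma::mat& S) {
  if (S.diag().min() >= VAR_FLOOR) return;
  arma::vec ev;
  arma::mat V;
  arma::eig_sym(ev, V, S);
  ev.transform([](double x) { return x < VAR_FLOOR ? VAR_FLOOR : x; });
  S = V * arma::diagmat(ev) * V.t();
}

static inline double clip_zeta(double z) {
  if (z < ZETA_EPS) return ZETA_EPS;
  if (z > 1.0 - ZETA_EPS) return 1.0 - ZETA_EPS;
  return z;
}

static void gammas(const arma::vec& mu_p, const arma::vec& mu_m,
                   const arma::mat& S_p, const arma::mat& S_m,
                   const arma::vec& refr, double g_ms, double beta,
                   arma::vec& gp, arma::vec& gm) {
  arma::uword N = mu_p.n_elem;
  for (arma::uword i = 0; i < N; ++i) {
    if (refr[i] > 0) { gp[i] = 0.0; gm[i] = 0.0; continue; }
    gp[i] = g_ms * std::exp(beta * mu_p[i] + 0.5 * beta * beta * S_p(i, i));
    gm[i] = g_ms * std::exp(beta * mu_m[i] + 0.5 * beta * beta * S_m(i, i));
  }
}

// [[Rcpp::export]]
List cpp_adf_run(const IntegerVector& spike_bin, const IntegerVector& spike_neuron,
                 double n_bins_d, double dt,
                 double ubar, double tau, const arma::mat& Q,
                 double g_ms, double beta, double tau_refr,
                 double omp, double omm, const arma::vec& w,
                 double zeta0, const arma::vec& mu_p0, const arma::vec& mu_m0,
                 const arma::mat& S_p0, const arma::mat& S_m0,
                 bool exact_jump, bool keep_moments) {
  R_xlen_t T = (R_xlen_t)n_bins_d;
  arma::uword N = mu_p0.n_elem;
  double zeta = clip_zeta(zeta0);
  arma::vec mu_p = mu_p0, mu_m = mu_m0;
  arma::mat S_p = S_p0, S_m = S_m0;
  arma::vec refr(N, arma::fill::zeros);
  arma::vec gp(N), gm(N);
  NumericVector o_zeta(T), o_mp(T), o_mm(T), o_vp(T), o_vm(T), o_rp(T), o_rm(T);
  arma::mat o_mup, o_mum, o_sp, o_sm;
  if (keep_moments) {
    o_mup.set_size(N, T); o_mum.set_size(N, T);
    o_sp.set_size(N, T);  o_sm.set_size(N, T);
  }
  R_xlen_t si = 0, ns = spike_bin.size();

  for (R_xlen_t t = 0; t < T; ++t) {
    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    // ---- drift (synchronous, from the pre-bin posterior) ----
    gammas(mu_p, mu_m, S_p, S_m, refr, g_ms, beta, gp, gm);
    double gbar_p = arma::accu(gp), gbar_m = arma::accu(gm);
    double fac_p = dt * omp * (1.0 - zeta) / zeta;       // state-mixing into +
    double fac_m = dt * omm * zeta / (1.0 - zeta);       // state-mixing into -
    if (fac_p > 1.0) fac_p = 1.0;                        // cap: full relaxation
    if (fac_m > 1.0) fac_m = 1.0;
    arma::vec dmu = mu_m - mu_p;                         // mu- - mu+
    arma::vec nmu_p = mu_p + dt * ((ubar - mu_p) / tau - beta * (S_p * gp))
                      + fac_p * dmu;
    arma::vec nmu_m = mu_m + dt * ((-ubar - mu_m) / tau - beta * (S_m * gm))
                      - fac_m * dmu;
    arma::mat nS_p = S_p + dt * (Q - (2.0 / tau) * S_p
                                 - beta * beta * (S_p * (S_p.each_col() % gp)))
                     + fac_p * ((S_m - S_p) + dmu * dmu.t());
    arma::mat nS_m = S_m + dt * (Q - (2.0 / tau) * S_m
                                 - beta * beta * (S_m * (S_m.each_col() % gm)))
                     + fac_m * ((S_p - S_m) + dmu * dmu.t());
    double nzeta = zeta + dt * (-zeta * (1.0 - zeta) * (gbar_p - gbar_m)
                                + (1.0 - zeta) * omp - zeta * omm);
    zeta = clip_zeta(nzeta);
    mu_p = nmu_p; mu_m = nmu_m;
    S_p = 0.5 * (nS_p + nS_p.t());
    S_m = 0.5 * (nS_m + nS_m.t());
    floor_psd(S_p);
    floor_psd(S_m);

    // ---- refractory clocks advance before this bin's spikes are applied ----
    for (arma::uword i = 0; i < N; ++i)
      if (refr[i] > 0) refr[i] -= dt;

    // ---- jump updates for spikes observed in this bin ----
    while (si < ns && spike_bin[si] == t) {
      int i = spike_neuron[si];
      if (refr[i] <= 0) {
        gammas(mu_p, mu_m, S_p, S_m, refr, g_ms, beta, gp, gm);
        double denom = zeta * gp[i] + (1.0 - zeta) * gm[i];
        if (denom > 0) {
          double nz;
          if (exact_jump) nz = zeta * gp[i] / denom;
          else nz = zeta + zeta * (1.0 - zeta) * (gp[i] - gm[i]) / denom;
          zeta = clip_zeta(nz);
          mu_p += beta * S_p.col(i);
          mu_m += beta * S_m.col(i);
        }
      }
      refr[i] = tau_refr;
      ++si;
    }

    if (!std::isfinite(zeta) || !mu_p.is_finite() || !S_p.is_finite() ||
        !mu_m.is_finite() || !S_m.is_finite())
      stop("assumed-density filter became non-finite at t = %f ms; use a smaller dt",
           (double)t * dt);

    // ---- record the filtered posterior at the end of the bin ----
    gammas(mu_p, mu_m, S_p, S_m, refr, g_ms, beta, gp, gm);
    o_zeta[t] = zeta;
    o_mp[t] = arma::dot(w, mu_p);
    o_mm[t] = arma::dot(w, mu_m);
    o_vp[t] = arma::as_scalar(w.t() * S_p * w);
    o_vm[t] = arma::as_scalar(w.t() * S_m * w);
    o_rp[t] = arma::dot(w, gp);
    o_rm[t] = arma::dot(w, gm);
    if (keep_moments) {
      o_mup.col(t) = mu_p; o_mum.col(t) = mu_m;
      o_sp.col(t) = S_p.diag(); o_sm.col(t) = S_m.diag();
    }
  }
  List out = List::create(
    _["zeta"] = o_zeta, _["m_plus"] = o_mp, _["m_minus"] = o_mm,
    _["v_plus"] = o_vp, _["v_minus"] = o_vm,
    _["r_plus"] = o_rp, _["r_minus"] = o_rm,
    _["S_plus_final"] = S_p, _["S_minus_final"] = S_m);
  if (keep_moments) {
    out["mu_plus"] = o_mup; out["mu_minus"] = o_mum;
    out["var_plus"] = o_sp; out["var_minus"] = o_sm;
  }
  return out;
}
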