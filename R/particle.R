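#' Bootstrap particle filter for the switching-mOU spiking model
#'
#' Sequential Monte-Carlo approximation of the exact posterior over the
#' global state and the membrane potentials given observed spike trains:
#' particles are propagated through the generative prior dynamics, weighted
#' by the Poisson bin likelihood of the observed spike/no-spike pattern (with
#' refractory zeroing and effective threshold rate \eqn{g\,p_{rel}}), and
#' systematically resampled whenever the effective sample size drops below
#' `ess_frac * n_particles`. Serves as the independent oracle for
#' [run_filter()].
#'
#' @param spikes data.frame with 0-based `neuron_id`, `time_ms`.
#' @param params a [population_params()] (single group).
#' @param n_particles number of particles (>= 100).
#' @param seed RNG seed.
#' @param dt bin width (ms).
#' @param duration_ms filtering horizon (default: covers the last spike).
#' @param ess_frac resampling threshold as a fraction of `n_particles`.
#' @return list of class `pf_result`: `time`, posterior `zeta`, posterior
#'   mean `u_mean` and s.d. `u_sd` (N x T), and the per-bin `ess`.
#' @export
pf_run <- function(spikes, params, n_particles = 10000, seed = NULL,
                   dt = 0.1, duration_ms = NULL, ess_frac = 0.5) {
  stopifnot(inherits(params, "population_params"))
  if (n_particles < 100) stop("n_particles must be at least 100")
  spikes <- as.data.frame(spikes)
  if (is.null(duration_ms))
    duration_ms <- if (nrow(spikes)) max(spikes$time_ms) + dt else dt
  n_bins <- ceiling(duration_ms / dt)
  b <- .bin_spikes(spikes, dt, n_bins)
  Q <- process_noise(params)
  N <- params$n_neurons
  Lq <- if (all(Q == 0)) matrix(0, N, N) else .chol_psd(Q)
  Ls <- .chol_psd(params$stationary_cov)
  .with_seed(seed, {
    r <- cpp_pf_run(b$bin, b$neuron, n_bins, dt, params$resting_half_gap,
                    params$time_constant, Lq, Ls,
                    .hz2ms(params$rate_at_threshold * params$release_prob),
                    params$spiking_steepness, params$refractory,
                    .hz2ms(params$rate_to_active),
                    .hz2ms(params$rate_to_quiescent),
                    .stationary_zeta(params), as.integer(n_particles),
                    ess_frac)
    structure(list(time = (seq_len(n_bins) - 1) * dt, dt = dt,
                   zeta = as.numeric(r$zeta), u_mean = r$u_mean,
                   u_sd = r$u_sd,
                   ess = pmin(as.numeric(r$ess), n_particles),
                   n_particles = n_particles), class = "pf_result")
  })
}

#' Compare the assumed-density filter with the particle-filter oracle
#'
#' Runs both filters on the same spike trains and summarizes their
#' disagreement: mean absolute and root-mean-square differences of the
#' posterior active-state probability and of the per-neuron posterior mean
#' potentials, each normalized by the corresponding particle-filter posterior
#' standard deviation (Bernoulli \eqn{\sqrt{\zeta(1-\zeta)}} for the state).
#'
#' @inheritParams pf_run
#' @param n_particles particles for the oracle.
#' @return list with elements `zeta` and `u`, each holding `mad_norm` and
#'   `rms_norm`, plus the raw traces of both filters.
#' @export
compare_adf_pf <- function(spikes, params, n_particles = 10000, seed = NULL,
                           dt = 0.1, duration_ms = NULL) {
  adf <- run_filter(spikes, params, dt = dt, duration_ms = duration_ms,
                    keep_moments = TRUE)
  pf <- pf_run(spikes, params, n_particles = n_particles, seed = seed,
               dt = dt, duration_ms = duration_ms)
  g <- adf$groups[[1]]
  u_adf <- g$mu_plus * rep(g$zeta, each = params$n_neurons) +
    g$mu_minus * rep(1 - g$zeta, each = params$n_neurons)
  dz <- adf$groups[[1]]$zeta - pf$zeta
  sdz <- sqrt(pmax(pf$zeta * (1 - pf$zeta), 1e-12))
  du <- u_adf - pf$u_mean
  sdu <- pmax(pf$u_sd, 1e-9)
  list(
    zeta = list(mad_norm = mean(abs(dz)) / mean(sdz),
                rms_norm = sqrt(mean(dz^2)) / sqrt(mean(sdz^2))),
    u = list(mad_norm = mean(abs(du)) / mean(sdu),
             rms_norm = sqrt(mean(du^2)) / sqrt(mean(sdu^2))),
    adf_zeta = adf$groups[[1]]$zeta, pf_zeta = pf$zeta,
    adf_u = u_adf, pf_u = pf$u_mean, pf_u_sd = pf$u_sd)
}
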