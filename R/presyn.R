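#' Parameters of one presynaptic neuron group
#'
#' Describes the generative model of a group of presynaptic neurons sharing a
#' single binary global state: the state switches to active with rate
#' `rate_to_active` (\eqn{\Omega_+}, Hz) and back to quiescent with rate
#' `rate_to_quiescent` (\eqn{\Omega_-}, Hz); membrane potentials follow a
#' multivariate Ornstein-Uhlenbeck process with time constant `time_constant`
#' (ms) decaying towards \eqn{+\bar u} (active) or \eqn{-\bar u} (quiescent),
#' with stationary within-state covariance `stationary_cov` (mV^2); spiking is
#' an exponential-link Poisson process with rate
#' \eqn{g\,e^{\beta u}} (Hz at threshold `rate_at_threshold`), an absolute
#' refractory period `refractory` (ms) acting on spike generation, and each
#' generated spike transmitted with probability `release_prob`.
#'
#' Potentials are measured relative to the spiking threshold (rate equals `g`
#' at u = 0). The process-noise matrix of the OU dynamics is
#' \eqn{Q = 2\bar\Sigma/\tau}.
#'
#' @param n_neurons number of neurons N.
#' @param rate_to_active,rate_to_quiescent switching rates \eqn{\Omega_\pm}
#'   (Hz). Both zero means the state never switches (used by the `ind` and
#'   `cor2` statistics together with `resting_half_gap = 0`).
#' @param resting_half_gap \eqn{\bar u} (mV); the active/quiescent resting
#'   potentials are \eqn{\pm\bar u}.
#' @param time_constant OU time constant \eqn{\tau} (ms).
#' @param stationary_cov stationary within-state covariance \eqn{\bar\Sigma}
#'   (N x N, mV^2), or a scalar variance expanded to a diagonal matrix.
#' @param rate_at_threshold firing rate g at threshold (Hz).
#' @param spiking_steepness \eqn{\beta} (1/mV).
#' @param refractory absolute refractory period \eqn{\tau_{refr}} (ms).
#' @param release_prob transmission probability \eqn{p_{rel}} in `[0, 1]`.
#' @return An object of class `population_params`.
#' @seealso [equicorr_cov()], [load_preset()], [simulate_population()]
#' @export
population_params <- function(n_neurons, rate_to_active, rate_to_quiescent,
                              resting_half_gap, time_constant, stationary_cov,
                              rate_at_threshold, spiking_steepness,
                              refractory = 3, release_prob = 1) {
  n_neurons <- as.integer(n_neurons)
  stopifnot(n_neurons >= 1)
  if (rate_to_active < 0 || rate_to_quiescent < 0)
    stop("switching rates must be non-negative")
  if (time_constant <= 0) stop("time_constant must be positive")
  if (refractory < 0) stop("refractory must be non-negative")
  if (rate_at_threshold < 0) stop("rate_at_threshold must be non-negative")
  if (release_prob < 0 || release_prob > 1)
    stop("release_prob must lie in [0, 1]")
  if (is.matrix(stationary_cov)) {
    S <- stationary_cov
  } else {
    stopifnot(length(stationary_cov) == 1)
    S <- diag(as.numeric(stationary_cov), n_neurons)
  }
  if (nrow(S) != n_neurons || ncol(S) != n_neurons)
    stop("stationary_cov must be ", n_neurons, " x ", n_neurons)
  .check_cov(S)
  structure(list(
    n_neurons = n_neurons,
    rate_to_active = rate_to_active,
    rate_to_quiescent = rate_to_quiescent,
    resting_half_gap = resting_half_gap,
    time_constant = time_constant,
    stationary_cov = S,
    rate_at_threshold = rate_at_threshold,
    spiking_steepness = spiking_steepness,
    refractory = refractory,
    release_prob = release_prob),
    class = "population_params")
}

.check_cov <- function(S) {
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("covariance matrix must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop("covariance matrix must be positive semidefinite")
  invisible(TRUE)
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf(
    "presynaptic group: N = %d, Omega+/- = %.3g/%.3g Hz, ubar = %.3g mV,\n",
    x$n_neurons, x$rate_to_active, x$rate_to_quiescent, x$resting_half_gap))
  cat(sprintf(
    "  tau = %.3g ms, Sigma_ii = %.3g mV^2, g = %.3g Hz, beta = %.3g /mV, tau_refr = %.3g ms, p_rel = %.3g\n",
    x$time_constant, x$stationary_cov[1, 1], x$rate_at_threshold,
    x$spiking_steepness, x$refractory, x$release_prob))
  invisible(x)
}

#' Equicorrelated covariance matrix
#'
#' \eqn{\bar\Sigma = \sigma^2 [(1-\rho) I + \rho \mathbf{1}\mathbf{1}^T]}.
#' The correlation must satisfy \eqn{\rho \ge -1/(N-1)} for the matrix to be
#' positive semidefinite.
#'
#' @param n dimension N.
#' @param var common variance \eqn{\sigma^2} (mV^2).
#' @param rho common pairwise correlation.
#' @export
equicorr_cov <- function(n, var, rho) {
  n <- as.integer(n)
  if (n > 1 && rho < -1 / (n - 1) - 1e-12)
    stop("rho must be >= -1/(N-1) = ", format(-1 / (n - 1)),
         " for a valid covariance")
  if (rho > 1) stop("rho must be <= 1")
  var * ((1 - rho) * diag(n) + rho * matrix(1, n, n))
}

#' A population of independent cell assemblies
#'
#' Groups are statistically independent of one another: each has its own
#' global state variable and its own OU noise. Neuron indices are global and
#' 0-based, assigned consecutively by group.
#'
#' @param groups list of [population_params()] objects.
#' @export
assembly_population <- function(groups) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, TRUE, "population_params")))
  sizes <- vapply(groups, function(g) g$n_neurons, 1L)
  structure(list(
    groups = groups,
    n_neurons = sum(sizes),
    group_of = rep(seq_along(groups), sizes)),
    class = "assembly_population")
}

#' @export
print.assembly_population <- function(x, ...) {
  cat(sprintf("assembly population: %d groups, %d neurons total\n",
              length(x$groups), x$n_neurons))
  invisible(x)
}

.as_groups <- function(pop) {
  if (inherits(pop, "population_params")) list(pop)
  else if (inherits(pop, "assembly_population")) pop$groups
  else stop("expected a population_params or assembly_population object")
}

#' Stationary probability of the active state
#'
#' Long-run probability \eqn{\Omega_+/(\Omega_+ + \Omega_-)} of the two-state
#' Markov switching process.
#' @param params a [population_params()] object.
#' @export
stationary_state_prob <- function(params) {
  s <- params$rate_to_active + params$rate_to_quiescent
  if (s <= 0)
    stop("stationary distribution undefined: both switching rates are zero")
  params$rate_to_active / s
}

#' State-conditioned expected firing rate
#'
#' Expected rate of the exponential-link spiking model under a normal
#' membrane-potential distribution:
#' \eqn{\gamma = g\,\exp(\beta\mu + \beta^2\Sigma_{ii}/2)} (Hz). This is the
#' generation rate; multiply by `release_prob` for the transmission rate.
#'
#' @param mean_potential \eqn{\mu} (mV), vectorized.
#' @param potential_var \eqn{\Sigma_{ii}} (mV^2), vectorized.
#' @param params a [population_params()] object.
#' @export
expected_rate <- function(mean_potential, potential_var, params) {
  if (any(potential_var < 0)) stop("potential_var must be non-negative")
  b <- params$spiking_steepness
  params$rate_at_threshold * exp(b * mean_potential + 0.5 * b^2 * potential_var)
}

#' Process-noise matrix of the OU dynamics
#'
#' \eqn{Q = 2\bar\Sigma/\tau} (mV^2/ms), so that the stationary covariance is
#' \eqn{\bar\Sigma = Q\tau/2}.
#' @param params a [population_params()] object.
#' @export
process_noise <- function(params) {
  .check_cov(params$stationary_cov)
  2 * params$stationary_cov / params$time_constant
}

.check_dt_rates <- function(params, dt) {
  mx <- .hz2ms(max(params$rate_to_active, params$rate_to_quiescent))
  if (dt * mx >= 0.1)
    stop("dt too coarse for the switching rates: dt * max(Omega) must be < 0.1")
  if (dt > 0.2 * params$time_constant)
    stop("dt too coarse relative to the membrane time constant")
  invisible(TRUE)
}

#' Simulate the global switching state
#'
#' Binary path of the two-state Markov chain, one entry per time bin of width
#' `dt`; per-bin transition probabilities are \eqn{\Omega_\pm \cdot dt}.
#'
#' @param params a [population_params()] object.
#' @param duration_s length of the path in seconds.
#' @param dt bin width (ms).
#' @param seed optional RNG seed.
#' @param init initial state (0/1); default drawn from the stationary
#'   distribution.
#' @return integer vector of 0 (quiescent) / 1 (active) with attribute `dt`.
#' @export
simulate_switching <- function(params, duration_s, dt = 0.1, seed = NULL,
                               init = NULL) {
  .check_dt_rates(params, dt)
  n_bins <- ceiling(duration_s * 1000 / dt)
  .with_seed(seed, {
    if (is.null(init)) {
      p <- if (params$rate_to_active + params$rate_to_quiescent > 0)
        stationary_state_prob(params) else 0.5
      init <- as.integer(runif(1) < p)
    }
    z <- cpp_sim_switch(.hz2ms(params$rate_to_active) * dt,
                        .hz2ms(params$rate_to_quiescent) * dt, n_bins,
                        as.integer(init))
    attr(z, "dt") <- dt
    z
  })
}

#' Streaming dwell-time statistics of the switching process
#'
#' Simulates the chain without materializing the path and returns epoch
#' statistics: mean dwell times (ms) of completed active and quiescent epochs,
#' the long-run activation rate (quiescent-to-active transitions per second),
#' and the active-state occupancy.
#'
#' @inheritParams simulate_switching
#' @export
switching_stats <- function(params, duration_s, dt = 1, seed = NULL,
                            init = NULL) {
  .check_dt_rates(params, dt)
  n_bins <- ceiling(duration_s * 1000 / dt)
  .with_seed(seed, {
    if (is.null(init))
      init <- as.integer(runif(1) < stationary_state_prob(params))
    s <- cpp_switch_stats(.hz2ms(params$rate_to_active) * dt,
                          .hz2ms(params$rate_to_quiescent) * dt, n_bins,
                          as.integer(init))
    list(mean_active_ms = s$active_bins * dt / max(1, s$n_active_epochs),
         mean_quiescent_ms = s$quiescent_bins * dt / max(1, s$n_quiescent_epochs),
         n_active_epochs = s$n_active_epochs,
         n_quiescent_epochs = s$n_quiescent_epochs,
         activation_rate_hz = s$n_activations / duration_s,
         active_occupancy = s$active_occupancy)
  })
}

#' Simulate membrane potentials given a state path
#'
#' Euler-Maruyama realization of the state-dependent multivariate OU process:
#' decay with time constant \eqn{\tau} towards \eqn{\pm\bar u} and Gaussian
#' process noise with covariance \eqn{Q\,dt} per bin. With the state clamped,
#' the empirical stationary mean is \eqn{\bar u(z)} and the covariance
#' \eqn{\bar\Sigma}.
#'
#' @param state_path integer 0/1 vector (see [simulate_switching()]); its `dt`
#'   attribute is used unless `dt` is given.
#' @param params a [population_params()] object.
#' @param seed optional RNG seed.
#' @param dt bin width (ms).
#' @param u0 initial potentials; default drawn from the state-conditioned
#'   stationary normal.
#' @return N x T matrix of potentials (mV).
#' @export
simulate_membrane <- function(state_path, params, seed = NULL,
                              dt = attr(state_path, "dt"), u0 = NULL) {
  if (is.null(dt)) stop("dt not given and state_path carries no dt attribute")
  if (dt > 0.2 * params$time_constant)
    stop("dt too coarse relative to the membrane time constant")
  N <- params$n_neurons
  Q <- process_noise(params)
  Lq <- if (all(Q == 0)) matrix(0, N, N) else .chol_psd(Q)
  .with_seed(seed, {
    if (is.null(u0)) {
      base <- params$resting_half_gap * (2 * state_path[1] - 1)
      Ls <- .chol_psd(params$stationary_cov)
      u0 <- as.numeric(base + Ls %*% rnorm(N))
    }
    U <- cpp_sim_mou(as.integer(state_path), params$resting_half_gap,
                     params$time_constant, Lq, dt, as.numeric(u0))
    attr(U, "dt") <- dt
    U
  })
}

#' Generate spikes from membrane potentials
#'
#' Bernoulli-bin approximation of the exponential-link Poisson process with
#' per-bin probability \eqn{dt\, g\, e^{\beta u}}. The absolute refractory
#' period suppresses spike *generation*; release-probability thinning is
#' applied afterwards, and a suppressed spike still starts the refractory
#' period. A warning is issued when the per-bin probability exceeds 0.1.
#'
#' @param potentials N x T matrix (see [simulate_membrane()]).
#' @param params a [population_params()] object.
#' @param seed optional RNG seed.
#' @param dt bin width (ms).
#' @return `data.table` with 0-based `neuron_id`, `time_ms`, and logical
#'   `transmitted`. All generated events are returned; transmitted events are
#'   the ones the postsynaptic side observes.
#' @export
simulate_spikes <- function(potentials, params, seed = NULL,
                            dt = attr(potentials, "dt")) {
  if (is.null(dt)) stop("dt not given and potentials carry no dt attribute")
  .with_seed(seed, {
    s <- cpp_sim_spikes(potentials, .hz2ms(params$rate_at_threshold),
                        params$spiking_steepness, dt, params$refractory,
                        params$release_prob)
    if (s$max_p > 0.1)
      warning(sprintf("per-bin spike probability reached %.2f (> 0.1); consider a smaller dt",
                      s$max_p))
    out <- data.table::data.table(neuron_id = as.integer(s$neuron),
                                  time_ms = as.numeric(s$time),
                                  transmitted = as.logical(s$transmitted))
    data.table::setorder(out, time_ms, neuron_id)
    out[]
  })
}

#' Simulate a full presynaptic population trajectory
#'
#' Composes state switching, membrane dynamics and spiking for a single group
#' or an [assembly_population()] whose groups evolve independently. The
#' trajectory records the transmitted spikes (what the postsynaptic neuron
#' sees), the equally-weighted mean membrane potential (`signal`), and,
#' optionally, the full potential matrix.
#'
#' @param pop [population_params()] or [assembly_population()].
#' @param duration_s duration (s).
#' @param dt bin width (ms).
#' @param seed RNG seed; the same seed reproduces the trajectory exactly.
#' @param keep_potentials keep the N x T potential matrix (memory heavy for
#'   long runs).
#' @param keep_generated also keep suppressed (non-transmitted) spikes in
#'   `spikes_generated`.
#' @return object of class `trajectory`.
#' @export
simulate_population <- function(pop, duration_s, dt = 0.1, seed = NULL,
                                keep_potentials = TRUE,
                                keep_generated = FALSE) {
  groups <- .as_groups(pop)
  n_bins <- ceiling(duration_s * 1000 / dt)
  .with_seed(seed, {
    states <- matrix(0L, length(groups), n_bins)
    U_all <- if (keep_potentials) NULL else NA
    sig <- numeric(n_bins)
    spk <- vector("list", length(groups))
    Us <- vector("list", length(groups))
    offset <- 0L
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      z <- simulate_switching(g, duration_s, dt = dt)
      states[gi, ] <- as.integer(z)
      U <- simulate_membrane(z, g, dt = dt)
      sg <- simulate_spikes(U, g, dt = dt)
      sg$neuron_id <- sg$neuron_id + offset
      spk[[gi]] <- sg
      sig <- sig + .colSums(U, nrow(U), ncol(U))
      if (keep_potentials) Us[[gi]] <- U
      offset <- offset + g$n_neurons
    }
    n_total <- offset
    all_spk <- data.table::rbindlist(spk)
    data.table::setorder(all_spk, time_ms, neuron_id)
    out <- structure(list(
      dt = dt, duration_ms = n_bins * dt, n_neurons = as.integer(n_total),
      groups = groups,
      group_of = rep(seq_along(groups),
                     vapply(groups, function(g) g$n_neurons, 1L)),
      states = states,
      potentials = if (keep_potentials) do.call(rbind, Us) else NULL,
      signal = sig / n_total,
      spikes = all_spk[all_spk$transmitted, c("neuron_id", "time_ms")],
      spikes_generated = if (keep_generated) all_spk else NULL,
      seed = seed), class = "trajectory")
    out
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d neurons in %d group(s), %.3g s at dt = %g ms, %d transmitted spikes\n",
    x$n_neurons, length(x$groups), x$duration_ms / 1000, x$dt,
    nrow(x$spikes)))
  invisible(x)
}
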