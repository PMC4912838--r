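#' Readout configuration for the optimal response
#'
#' Describes how the filtered posterior is turned into a postsynaptic
#' response: synaptic weights, the postsynaptic time constant of the
#' first-order low-pass (0 = instantaneous), and the readout mode. Mode
#' `"voltage"` reads out the posterior mean of the weighted potential sum,
#' `"rate"` the posterior mean of the weighted firing-rate sum, and
#' `"sigmoid"` the posterior expectation of a sigmoidal function of the
#' weighted potential sum, \eqn{1/(1 + e^{\beta_f x - \theta_f})} as printed
#' (decreasing in x; set `decreasing = FALSE` for the increasing convention).
#'
#' @param weights synaptic weight vector (length N).
#' @param tau_post postsynaptic time constant (ms), 0 allowed.
#' @param mode one of `"voltage"`, `"rate"`, `"sigmoid"`.
#' @param beta_f,theta_f sigmoid slope (1/mV) and threshold (mV), used by
#'   mode `"sigmoid"`.
#' @param decreasing sign convention of the sigmoid exponent.
#' @param n_samples Monte-Carlo samples per time bin for mode `"sigmoid"`.
#' @export
readout_params <- function(weights, tau_post = 0,
                           mode = c("voltage", "rate", "sigmoid"),
                           beta_f = 1, theta_f = 0, decreasing = TRUE,
                           n_samples = 200) {
  mode <- match.arg(mode)
  stopifnot(all(is.finite(weights)), tau_post >= 0)
  structure(list(weights = as.numeric(weights), tau_post = tau_post,
                 mode = mode, beta_f = beta_f, theta_f = theta_f,
                 decreasing = decreasing, n_samples = as.integer(n_samples)),
            class = "readout_params")
}

.stationary_zeta <- function(params) {
  s <- params$rate_to_active + params$rate_to_quiescent
  if (s <= 0) 0.5 else params$rate_to_active / s
}

#' Stationary-prior initialization of the filter posterior
#'
#' \eqn{\zeta = \Omega_+/(\Omega_+ + \Omega_-)}, \eqn{\mu_\pm = \pm\bar u},
#' \eqn{\Sigma_\pm = \bar\Sigma}, refractory clocks at zero. When both
#' switching rates are zero (no state dynamics) \eqn{\zeta = 1/2}.
#'
#' @param params a [population_params()] object.
#' @return object of class `posterior_state`.
#' @export
init_posterior <- function(params) {
  N <- params$n_neurons
  structure(list(
    zeta = .stationary_zeta(params),
    mu_plus = rep(params$resting_half_gap, N),
    mu_minus = rep(-params$resting_half_gap, N),
    S_plus = params$stationary_cov,
    S_minus = params$stationary_cov,
    refractory = rep(0, N)), class = "posterior_state")
}

.adf_gamma <- function(mu, Sdiag, refr, g_ms, beta) {
  g <- g_ms * exp(beta * mu + 0.5 * beta^2 * Sdiag)
  g[refr > 0] <- 0
  g
}

#' One assumed-density filtering step (reference implementation)
#'
#' Advances the posterior by one bin of width `dt`: explicit-Euler drift
#' (decay towards the prior, covariance relaxation towards \eqn{Q\tau/2},
#' no-spike evidence, and state-mixing), followed by the first-order jump
#' updates for the spikes observed in the bin
#' (\eqn{\Delta\zeta = \zeta(1-\zeta)(\gamma_i^+ - \gamma_i^-)/\langle\Gamma\rangle_{ii}},
#' \eqn{\Delta\mu_\pm = \beta\,\Sigma_\pm e_i}). While a neuron's refractory
#' clock runs its likelihood contribution is omitted
#' (\eqn{\gamma_i = \Gamma_{ii} = 0}). The release probability enters as an
#' effective threshold rate \eqn{g\,p_{rel}}.
#'
#' This pure-R step is the reference against which the compiled filter in
#' [run_filter()] is tested; it is too slow for long inputs.
#'
#' @param state a `posterior_state`.
#' @param spikes_in_bin integer vector of 0-based neuron indices spiking in
#'   this bin (at most one entry per neuron).
#' @param dt bin width (ms).
#' @param params a [population_params()] object.
#' @param zeta_jump `"linear"` applies the first-order jump as written;
#'   `"exact"` uses the exact-Bayes multiplicative update
#'   \eqn{\zeta' = \zeta\gamma_i^+/\langle\Gamma\rangle_{ii}}.
#' @return the updated `posterior_state`.
#' @export
adf_step <- function(state, spikes_in_bin, dt, params,
                     zeta_jump = c("linear", "exact")) {
  zeta_jump <- match.arg(zeta_jump)
  if (anyDuplicated(spikes_in_bin))
    stop("at most one spike per neuron per bin")
  eps <- 1e-6
  clip <- function(z) min(max(z, eps), 1 - eps)
  g_ms <- .hz2ms(params$rate_at_threshold * params$release_prob)
  beta <- params$spiking_steepness
  tau <- params$time_constant
  ub <- params$resting_half_gap
  omp <- .hz2ms(params$rate_to_active)
  omm <- .hz2ms(params$rate_to_quiescent)
  Q <- process_noise(params)
  z <- state$zeta; mp <- state$mu_plus; mm <- state$mu_minus
  Sp <- state$S_plus; Sm <- state$S_minus; refr <- state$refractory

  gp <- .adf_gamma(mp, diag(Sp), refr, g_ms, beta)
  gm <- .adf_gamma(mm, diag(Sm), refr, g_ms, beta)
  fac_p <- min(1, dt * omp * (1 - z) / z)
  fac_m <- min(1, dt * omm * z / (1 - z))
  dmu <- mm - mp
  nmp <- mp + dt * ((ub - mp) / tau - beta * as.numeric(Sp %*% gp)) + fac_p * dmu
  nmm <- mm + dt * ((-ub - mm) / tau - beta * as.numeric(Sm %*% gm)) - fac_m * dmu
  nSp <- Sp + dt * (Q - (2 / tau) * Sp - beta^2 * (Sp %*% (gp * Sp))) +
    fac_p * ((Sm - Sp) + tcrossprod(dmu))
  nSm <- Sm + dt * (Q - (2 / tau) * Sm - beta^2 * (Sm %*% (gm * Sm))) +
    fac_m * ((Sp - Sm) + tcrossprod(dmu))
  nz <- z + dt * (-z * (1 - z) * (sum(gp) - sum(gm)) + (1 - z) * omp - z * omm)
  z <- clip(nz); mp <- nmp; mm <- nmm
  floor_psd <- function(S) {
    if (min(diag(S)) >= 1e-12) return(S)
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% (pmax(e$values, 1e-12) * t(e$vectors))
  }
  Sp <- floor_psd((nSp + t(nSp)) / 2)
  Sm <- floor_psd((nSm + t(nSm)) / 2)
  refr <- pmax(refr - dt, 0)

  for (i0 in spikes_in_bin) {
    i <- i0 + 1L
    if (refr[i] <= 0) {
      gp <- .adf_gamma(mp, diag(Sp), refr, g_ms, beta)
      gm <- .adf_gamma(mm, diag(Sm), refr, g_ms, beta)
      den <- z * gp[i] + (1 - z) * gm[i]
      if (den > 0) {
        z <- clip(if (zeta_jump == "exact") z * gp[i] / den
                  else z + z * (1 - z) * (gp[i] - gm[i]) / den)
        mp <- mp + beta * Sp[, i]
        mm <- mm + beta * Sm[, i]
      }
    }
    refr[i] <- params$refractory
  }
  if (!is.finite(z) || any(!is.finite(mp)) || any(!is.finite(Sp)))
    stop("assumed-density filter became non-finite; use a smaller dt")
  structure(list(zeta = z, mu_plus = mp, mu_minus = mm, S_plus = Sp,
                 S_minus = Sm, refractory = refr), class = "posterior_state")
}

.run_filter_group <- function(spikes, params, dt, n_bins, weights, engine,
                              zeta_jump, keep_moments, init = NULL) {
  b <- .bin_spikes(spikes, dt, n_bins)
  if (is.null(init)) init <- init_posterior(params)
  g_ms <- .hz2ms(params$rate_at_threshold * params$release_prob)
  if (engine == "cpp") {
    r <- cpp_adf_run(b$bin, b$neuron, n_bins, dt,
                     params$resting_half_gap, params$time_constant,
                     process_noise(params), g_ms, params$spiking_steepness,
                     params$refractory, .hz2ms(params$rate_to_active),
                     .hz2ms(params$rate_to_quiescent), as.numeric(weights),
                     init$zeta, init$mu_plus, init$mu_minus,
                     init$S_plus, init$S_minus,
                     zeta_jump == "exact", keep_moments)
  } else {
    st <- init
    r <- list(zeta = numeric(n_bins), m_plus = numeric(n_bins),
              m_minus = numeric(n_bins), v_plus = numeric(n_bins),
              v_minus = numeric(n_bins), r_plus = numeric(n_bins),
              r_minus = numeric(n_bins))
    if (keep_moments) {
      r$mu_plus <- matrix(0, params$n_neurons, n_bins)
      r$mu_minus <- matrix(0, params$n_neurons, n_bins)
      r$var_plus <- matrix(0, params$n_neurons, n_bins)
      r$var_minus <- matrix(0, params$n_neurons, n_bins)
    }
    idx <- split(b$neuron, b$bin)
    for (t in seq_len(n_bins)) {
      sp <- idx[[as.character(t - 1L)]]
      st <- adf_step(st, if (is.null(sp)) integer(0) else sp, dt, params,
                     zeta_jump)
      gp <- .adf_gamma(st$mu_plus, diag(st$S_plus), st$refractory, g_ms,
                       params$spiking_steepness)
      gm <- .adf_gamma(st$mu_minus, diag(st$S_minus), st$refractory, g_ms,
                       params$spiking_steepness)
      r$zeta[t] <- st$zeta
      r$m_plus[t] <- sum(weights * st$mu_plus)
      r$m_minus[t] <- sum(weights * st$mu_minus)
      r$v_plus[t] <- as.numeric(weights %*% st$S_plus %*% weights)
      r$v_minus[t] <- as.numeric(weights %*% st$S_minus %*% weights)
      r$r_plus[t] <- sum(weights * gp)
      r$r_minus[t] <- sum(weights * gm)
      if (keep_moments) {
        r$mu_plus[, t] <- st$mu_plus; r$mu_minus[, t] <- st$mu_minus
        r$var_plus[, t] <- diag(st$S_plus); r$var_minus[, t] <- diag(st$S_minus)
      }
    }
    r$S_plus_final <- st$S_plus; r$S_minus_final <- st$S_minus
  }
  r$weights <- weights
  r$params <- params
  r
}

#' Run the assumed-density filter over spike trains
#'
#' Filters the observed (transmitted) spike trains through the switching-mOU
#' assumed-density filter and records, at every bin, the posterior
#' active-state probability \eqn{\zeta}, the state-conditioned weighted means
#' and variances of the potentials, and the state-conditioned expected rates.
#' For an [assembly_population()] one independent filter runs per group and
#' the combined readout traces sum the group contributions.
#'
#' @param spikes data.frame/data.table with 0-based `neuron_id` and `time_ms`
#'   (sorted), e.g. `trajectory$spikes` or [read_spikes()] output.
#' @param pop [population_params()] or [assembly_population()].
#' @param dt bin width (ms); defaults to 0.1.
#' @param duration_ms filtering horizon; defaults to covering the last spike.
#' @param weights synaptic weights over all neurons (default \eqn{1/N}).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation looping [adf_step()], for testing only).
#' @param zeta_jump see [adf_step()].
#' @param keep_moments keep full per-neuron posterior moment trajectories.
#' @return object of class `adf_trajectory` with elements `time` (bin left
#'   edges, ms), `mean` (posterior mean of the weighted potential sum, mV),
#'   `rate_hz` (posterior mean of the weighted rate sum, Hz), per-group
#'   summaries in `groups`, and `dt`.
#' @export
run_filter <- function(spikes, pop, dt = 0.1, duration_ms = NULL,
                       weights = NULL, engine = c("cpp", "r"),
                       zeta_jump = c("linear", "exact"),
                       keep_moments = FALSE) {
  engine <- match.arg(engine)
  zeta_jump <- match.arg(zeta_jump)
  groups <- .as_groups(pop)
  sizes <- vapply(groups, function(g) g$n_neurons, 1L)
  n_total <- sum(sizes)
  spikes <- as.data.frame(spikes)
  if (nrow(spikes) > 0) {
    if (any(spikes$neuron_id < 0 | spikes$neuron_id >= n_total))
      stop("neuron_id out of range for this population")
    if (is.unsorted(spikes$time_ms)) spikes <- spikes[order(spikes$time_ms), ]
  }
  if (is.null(duration_ms))
    duration_ms <- if (nrow(spikes)) max(spikes$time_ms) + dt else dt
  if (nrow(spikes) && max(spikes$time_ms) > duration_ms)
    stop("spike outside the filtering window [0, duration]")
  n_bins <- ceiling(duration_ms / dt)
  if (is.null(weights)) weights <- rep(1 / n_total, n_total)
  stopifnot(length(weights) == n_total)
  ends <- cumsum(sizes); starts <- c(1L, head(ends, -1) + 1L)
  res <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    lo0 <- starts[gi] - 1L; hi0 <- ends[gi] - 1L
    sg <- spikes[spikes$neuron_id >= lo0 & spikes$neuron_id <= hi0, , drop = FALSE]
    sg$neuron_id <- sg$neuron_id - lo0
    res[[gi]] <- .run_filter_group(sg, groups[[gi]], dt, n_bins,
                                   weights[starts[gi]:ends[gi]], engine,
                                   zeta_jump, keep_moments)
  }
  mean_tr <- Reduce(`+`, lapply(res, function(r)
    r$zeta * r$m_plus + (1 - r$zeta) * r$m_minus))
  rate_tr <- Reduce(`+`, lapply(res, function(r)
    r$zeta * r$r_plus + (1 - r$zeta) * r$r_minus)) * 1000
  structure(list(
    time = (seq_len(n_bins) - 1) * dt, dt = dt, n_neurons = n_total,
    weights = weights, groups = res, mean = mean_tr, rate_hz = rate_tr),
    class = "adf_trajectory")
}

#' @export
print.adf_trajectory <- function(x, ...) {
  cat(sprintf("adf trajectory: %d neurons, %d group(s), %d bins at dt = %g ms\n",
              x$n_neurons, length(x$groups), length(x$time), x$dt))
  invisible(x)
}

#' Posterior mean of the weighted potential sum
#'
#' For a single `posterior_state`,
#' \eqn{\sum_i w_i(\zeta\mu_i^+ + (1-\zeta)\mu_i^-)}; for an
#' `adf_trajectory`, the per-bin trace (already computed with the filter's
#' weights).
#'
#' @param state a `posterior_state` or `adf_trajectory`.
#' @param weights weight vector (required for a `posterior_state`).
#' @export
posterior_mean_potential <- function(state, weights = NULL) {
  if (inherits(state, "adf_trajectory")) return(state$mean)
  stopifnot(inherits(state, "posterior_state"), !is.null(weights),
            length(weights) == length(state$mu_plus))
  sum(weights * (state$zeta * state$mu_plus +
                   (1 - state$zeta) * state$mu_minus))
}

.trace <- function(time, value, dt) {
  structure(list(time = time, value = value, dt = dt), class = "opt_trace")
}

#' @export
print.opt_trace <- function(x, ...) {
  cat(sprintf("trace: %d samples at dt = %g ms, range [%.3g, %.3g]\n",
              length(x$value), x$dt, min(x$value), max(x$value)))
  invisible(x)
}

#' Optimal voltage response
#'
#' First-order low-pass (time constant `tau_post`) of the posterior mean of
#' the weighted potential sum; `tau_post = 0` returns the instantaneous
#' readout. This is the response minimizing mean squared error to the linear
#' computation on the presynaptic potentials.
#'
#' @param traj an `adf_trajectory` from [run_filter()].
#' @param readout a [readout_params()] with mode `"voltage"` (or a number,
#'   taken as `tau_post`).
#' @return an `opt_trace` (time in ms, value in mV).
#' @export
optimal_response <- function(traj, readout = 0) {
  tau <- if (inherits(readout, "readout_params")) readout$tau_post else readout
  .trace(traj$time, .lowpass(traj$mean, traj$dt, tau), traj$dt)
}

#' Optimal rate readout
#'
#' Low-pass of the posterior mean of the weighted firing-rate sum
#' \eqn{\sum_i w_i [\zeta\gamma_i^+ + (1-\zeta)\gamma_i^-]} (Hz), for
#' computations defined on presynaptic firing rates instead of potentials.
#'
#' @inheritParams optimal_response
#' @export
rate_readout <- function(traj, readout = 0) {
  tau <- if (inherits(readout, "readout_params")) readout$tau_post else readout
  .trace(traj$time, .lowpass(traj$rate_hz, traj$dt, tau), traj$dt)
}

.sigmoid_f <- function(x, beta_f, theta_f, decreasing) {
  s <- if (decreasing) 1 else -1
  1 / (1 + exp(s * (beta_f * x - theta_f)))
}

#' Optimal readout of a sigmoidal computation
#'
#' Posterior expectation of a sigmoid of the weighted potential sum. Under the
#' assumed posterior the weighted sum is, per group, a mixture of two
#' univariate normals; the expectation is estimated by one-dimensional
#' Monte-Carlo sampling (`readout$n_samples` per bin) and then low-passed.
#' Intended for short traces.
#'
#' @param traj an `adf_trajectory`.
#' @param readout a [readout_params()] with mode `"sigmoid"`.
#' @param seed optional RNG seed for the sampler.
#' @export
nonlinear_readout <- function(traj, readout, seed = NULL) {
  stopifnot(inherits(readout, "readout_params"), readout$mode == "sigmoid")
  S <- readout$n_samples
  T_ <- length(traj$time)
  .with_seed(seed, {
    # accumulate over sample chunks to keep memory at O(T * chunk)
    chunk <- max(1L, min(S, as.integer(ceiling(2e6 / T_))))
    v <- numeric(T_)
    done <- 0L
    while (done < S) {
      k <- min(chunk, S - done)
      x <- matrix(0, T_, k)
      for (r in traj$groups) {
        on <- matrix(runif(T_ * k), T_, k) < r$zeta
        mu <- ifelse(on, r$m_plus, r$m_minus)
        sd_ <- sqrt(pmax(ifelse(on, r$v_plus, r$v_minus), 0))
        x <- x + mu + sd_ * matrix(rnorm(T_ * k), T_, k)
      }
      v <- v + rowSums(.sigmoid_f(x, readout$beta_f, readout$theta_f,
                                  readout$decreasing))
      done <- done + k
    }
    v <- v / S
    .trace(traj$time, .lowpass(v, traj$dt, readout$tau_post), traj$dt)
  })
}
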