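.bin_counts <- function(spikes, dt, n_bins, neurons = NULL) {
  spikes <- as.data.frame(spikes)
  if (!is.null(neurons) && nrow(spikes))
    spikes <- spikes[spikes$neuron_id %in% neurons, , drop = FALSE]
  if (!nrow(spikes)) return(numeric(n_bins))
  b <- pmin(as.integer(floor(spikes$time_ms / dt + 1e-9)), n_bins - 1L)
  tabulate(b + 1L, nbins = n_bins)
}

# leaky integrator v_t = (1 - dt/tau) v_{t-1} + drive_t, v_0 state init
.leaky <- function(drive, dt, tau, init = 0) {
  as.numeric(stats::filter(drive, 1 - dt / tau, method = "recursive",
                           init = init))
}

#' Linear dendrite model
#'
#' Responds to every incoming spike with an identical exponentially decaying
#' postsynaptic potential: \eqn{\dot v = (\bar v_\ell - v)/\tau_\ell +
#' w_\ell s(t)}.
#'
#' @param psp_weight PSP amplitude \eqn{w_\ell} (mV per spike).
#' @param decay decay time constant \eqn{\tau_\ell} (ms), > 0.
#' @param baseline resting output \eqn{\bar v_\ell} (mV).
#' @export
linear_model <- function(psp_weight, decay, baseline = 0) {
  stopifnot(decay > 0)
  structure(list(psp_weight = psp_weight, decay = decay, baseline = baseline),
            class = "linear_model")
}

#' Sigmoidal nonlinearity parameters
#'
#' \eqn{y = a_g / (1 + e^{-\beta_g (x - \theta_g)}) - \bar v_g}; the output is
#' bounded in \eqn{(-\bar v_g, a_g - \bar v_g)}.
#'
#' @param amplitude \eqn{a_g} (mV).
#' @param steepness \eqn{\beta_g} (1/mV).
#' @param threshold \eqn{\theta_g} (mV).
#' @param offset \eqn{\bar v_g} (mV).
#' @export
sigmoid_params <- function(amplitude, steepness, threshold, offset = 0) {
  stopifnot(is.finite(amplitude))
  structure(list(amplitude = amplitude, steepness = steepness,
                 threshold = threshold, offset = offset),
            class = "sigmoid_params")
}

.apply_sigmoid <- function(x, s) {
  s$amplitude / (1 + exp(-s$steepness * (x - s$threshold))) - s$offset
}

#' Model with linear dendrites and a nonlinear soma
#'
#' The total spike train is integrated linearly with unit weight and zero
#' baseline (these are interchangeable with the sigmoid's slope and
#' threshold) and passed through a somatic sigmoid; five free parameters.
#'
#' @param decay inner integration time constant (ms).
#' @param sigmoid a [sigmoid_params()].
#' @export
somatic_model <- function(decay, sigmoid) {
  stopifnot(decay > 0, inherits(sigmoid, "sigmoid_params"))
  structure(list(decay = decay, sigmoid = sigmoid), class = "somatic_model")
}

#' Two-layer dendritic subunit model
#'
#' Each subunit integrates the spikes of its input neurons linearly (unit
#' weight, zero baseline) and transforms the result through its sigmoid; the
#' soma averages the subunit outputs. `wiring = "clustered"` maps each cell
#' assembly to one subunit (parameters then conventionally shared across
#' subunits); `"random"` assigns neurons irrespective of assembly.
#'
#' @param mapping list of integer vectors of 0-based neuron ids, one per
#'   subunit; a neuron may feed at most one subunit.
#' @param decay inner time constant(s), length 1 (shared) or one per subunit.
#' @param sigmoid a single [sigmoid_params()] (shared) or a list, one per
#'   subunit.
#' @param wiring `"clustered"` or `"random"` (label only).
#' @export
subunit_model <- function(mapping, decay, sigmoid,
                          wiring = c("clustered", "random")) {
  wiring <- match.arg(wiring)
  stopifnot(is.list(mapping), length(mapping) >= 1)
  all_n <- unlist(mapping)
  if (anyDuplicated(all_n))
    stop("wiring error: neuron mapped to more than one subunit")
  k <- length(mapping)
  if (length(decay) == 1) decay <- rep(decay, k)
  stopifnot(length(decay) == k, all(decay > 0))
  if (inherits(sigmoid, "sigmoid_params")) sigmoid <- rep(list(sigmoid), k)
  stopifnot(length(sigmoid) == k,
            all(vapply(sigmoid, inherits, TRUE, "sigmoid_params")))
  structure(list(mapping = mapping, decay = decay, sigmoid = sigmoid,
                 wiring = wiring), class = "subunit_model")
}

#' Reduced near-optimal sigmoidal integrator
#'
#' Tracks the log-odds \eqn{\nu} of the assembly being active by (optionally
#' leaky) linear integration of incoming spikes,
#' \eqn{\dot\nu = B\,s(t) - C - A(\nu - \nu_0)}, and reads out
#' \eqn{v = \bar u_- + (\bar u_+ - \bar u_-)\,\sigma(\nu)}. With
#' `leak = "none"` the integration is the quasi-static limit (constant drift
#' \eqn{-C}, each spike incrementing \eqn{\nu} by exactly B).
#'
#' @param spike_gain log-likelihood-ratio jump B per spike.
#' @param drift no-spike evidence drift C (1/ms).
#' @param u_plus,u_minus active/quiescent resting potentials (mV).
#' @param leak `"proportional"` (towards `leak_target` with rate `leak_rate`)
#'   or `"none"`.
#' @param leak_rate A (1/ms).
#' @param leak_target prior log-odds \eqn{\nu_0}.
#' @param nu_init initial \eqn{\nu}.
#' @seealso [reduced_from_params()] for the theory-derived parameters.
#' @export
reduced_optimal_model <- function(spike_gain, drift, u_plus, u_minus,
                                  leak = c("proportional", "none"),
                                  leak_rate = 0, leak_target = 0,
                                  nu_init = NULL) {
  leak <- match.arg(leak)
  stopifnot(spike_gain >= 0, drift >= 0, leak_rate >= 0)
  if (is.null(nu_init))
    nu_init <- if (leak == "proportional") leak_target else 0
  structure(list(spike_gain = spike_gain, drift = drift, u_plus = u_plus,
                 u_minus = u_minus, leak = leak, leak_rate = leak_rate,
                 leak_target = leak_target, nu_init = nu_init),
            class = "reduced_optimal_model")
}

#' Theory-derived parameters of the reduced integrator
#'
#' From the generative parameters of one assembly: spike gain
#' \eqn{B = \beta(\bar u_+ - \bar u_-)} (the log likelihood ratio of a spike
#' under the two states at their stationary statistics), no-spike drift
#' \eqn{C = \bar\gamma_+ - \bar\gamma_-} (difference of total transmitted
#' population rates), leak rate \eqn{A = \Omega_+ + \Omega_-} (relaxation
#' rate of the prior), and leak target at the prior log-odds.
#'
#' @param params a [population_params()] object with switching dynamics.
#' @param leak `"proportional"` or `"none"`.
#' @export
reduced_from_params <- function(params, leak = c("proportional", "none")) {
  leak <- match.arg(leak)
  ub <- params$resting_half_gap
  gp <- expected_rate(ub, params$stationary_cov[1, 1], params) *
    params$release_prob
  gm <- expected_rate(-ub, params$stationary_cov[1, 1], params) *
    params$release_prob
  z0 <- .stationary_zeta(params)
  reduced_optimal_model(
    spike_gain = params$spiking_steepness * 2 * ub,
    drift = .hz2ms(params$n_neurons * (gp - gm)),
    u_plus = ub, u_minus = -ub, leak = leak,
    leak_rate = .hz2ms(params$rate_to_active + params$rate_to_quiescent),
    leak_target = stats::qlogis(min(max(z0, 1e-12), 1 - 1e-12)))
}

#' Response of the linear dendrite model
#'
#' @param spikes data.frame with 0-based `neuron_id`, `time_ms`.
#' @param model a [linear_model()].
#' @param dt bin width (ms).
#' @param duration_ms trace length (default: covers the last spike).
#' @return an `opt_trace`.
#' @export
linear_response <- function(spikes, model, dt, duration_ms = NULL) {
  spikes <- as.data.frame(spikes)
  if (is.null(duration_ms))
    duration_ms <- if (nrow(spikes)) max(spikes$time_ms) + dt else dt
  n_bins <- ceiling(duration_ms / dt)
  n <- .bin_counts(spikes, dt, n_bins)
  v <- model$baseline + .leaky(model$psp_weight * n, dt, model$decay)
  .trace((seq_len(n_bins) - 1) * dt, v, dt)
}

#' Response of the somatic-nonlinearity model
#'
#' @inheritParams linear_response
#' @param model a [somatic_model()].
#' @export
somatic_response <- function(spikes, model, dt, duration_ms = NULL) {
  inner <- linear_response(spikes, linear_model(1, model$decay, 0), dt,
                           duration_ms)
  .trace(inner$time, .apply_sigmoid(inner$value, model$sigmoid), dt)
}

#' Response of the two-layer subunit model
#'
#' @inheritParams linear_response
#' @param model a [subunit_model()].
#' @export
subunit_response <- function(spikes, model, dt, duration_ms = NULL) {
  spikes <- as.data.frame(spikes)
  if (is.null(duration_ms))
    duration_ms <- if (nrow(spikes)) max(spikes$time_ms) + dt else dt
  n_bins <- ceiling(duration_ms / dt)
  out <- numeric(n_bins)
  for (j in seq_along(model$mapping)) {
    nj <- .bin_counts(spikes, dt, n_bins, neurons = model$mapping[[j]])
    hj <- .leaky(nj, dt, model$decay[j])
    out <- out + .apply_sigmoid(hj, model$sigmoid[[j]])
  }
  .trace((seq_len(n_bins) - 1) * dt, out / length(model$mapping), dt)
}

#' Response of the reduced near-optimal integrator
#'
#' @inheritParams linear_response
#' @param model a [reduced_optimal_model()].
#' @export
reduced_optimal_response <- function(spikes, model, dt, duration_ms = NULL) {
  spikes <- as.data.frame(spikes)
  if (is.null(duration_ms))
    duration_ms <- if (nrow(spikes)) max(spikes$time_ms) + dt else dt
  n_bins <- ceiling(duration_ms / dt)
  n <- .bin_counts(spikes, dt, n_bins)
  if (model$leak == "none") {
    nu <- model$nu_init + cumsum(model$spike_gain * n - model$drift * dt)
  } else {
    a <- model$leak_rate * dt
    drive <- model$spike_gain * n - model$drift * dt +
      a * model$leak_target
    nu <- as.numeric(stats::filter(drive, 1 - a, method = "recursive",
                                   init = model$nu_init))
  }
  zeta <- stats::plogis(nu)
  v <- model$u_minus + (model$u_plus - model$u_minus) * zeta
  out <- .trace((seq_len(n_bins) - 1) * dt, v, dt)
  attr(out, "nu") <- nu
  out
}

#' Fraction of variance explained
#'
#' \eqn{1 - \bar\epsilon = 1 - \mathrm{MSE}/\mathrm{Var}(signal)}: 0 is
#' achieved by predicting the time-average of the signal, 1 by a perfect
#' prediction. MSE uses 1/T, the variance 1/(T-1).
#'
#' @param estimate,signal numeric vectors (or `opt_trace`s) of equal length.
#' @export
performance <- function(estimate, signal) {
  if (inherits(estimate, "opt_trace")) estimate <- estimate$value
  if (inherits(signal, "opt_trace")) signal <- signal$value
  stopifnot(length(estimate) == length(signal))
  v <- var(signal)
  if (!is.finite(v) || v <= 0)
    stop("signal variance is zero: normalization undefined")
  1 - mean((estimate - signal)^2) / v
}

# ---------------------------------------------------------------------------
# Least-squares fitting. All sigmoid-family models profile their linear
# parameters (output scale and offset) out at every objective evaluation, so
# only 1-3 nonlinear parameters per (sub)unit are searched numerically.
# ---------------------------------------------------------------------------

.profiled_rss <- function(cols, y) {
  X <- cbind(1, cols)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(list(rss = Inf))
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

.nm <- function(par, fn, maxit) {
  stats::optim(par, fn, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-9))
}

#' Fit a dendritic model to a spike train and target signal
#'
#' Minimizes the mean squared error between the model output and `signal`
#' over the training bins. Linear parameters
#' (output gain and offset) are profiled out exactly; the remaining nonlinear
#' parameters (time constants, sigmoid slope and threshold) are optimized by
#' multi-start Nelder-Mead with a fixed seed. The `subunit_model` with
#' per-subunit parameters is optimized by cyclic backfitting over subunits.
#'
#' @param model a template model object carrying the structure (wiring,
#'   initial parameter guesses are derived internally).
#' @param spikes training spikes (data.frame, 0-based `neuron_id`,
#'   `time_ms`).
#' @param signal numeric target, one value per bin of width `dt`.
#' @param dt bin width (ms).
#' @param n_starts number of optimizer restarts.
#' @param seed RNG seed for the restarts.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param init optional named list overriding the internal initial guesses
#'   (`tau`, `beta`, `theta`).
#' @return list of class `dendrite_fit` with the fitted `model`, `train_mse`,
#'   and `train_error` (fraction of variance unexplained).
#' @export
fit_model <- function(model, spikes, signal, dt, n_starts = 5, seed = NULL,
                      maxit = 400, init = NULL) {
  UseMethod("fit_model")
}

.fit_result <- function(model, rss, y) {
  structure(list(model = model, train_mse = rss / length(y),
                 train_error = rss / length(y) / var(y)),
            class = "dendrite_fit")
}

#' @export
print.dendrite_fit <- function(x, ...) {
  cat(sprintf("fitted %s: train MSE %.4g (fraction unexplained %.3f)\n",
              class(x$model)[1], x$train_mse, x$train_error))
  invisible(x)
}

#' @export
fit_model.linear_model <- function(model, spikes, signal, dt, n_starts = 5,
                                   seed = NULL, maxit = 400, init = NULL) {
  n_bins <- length(signal)
  n <- .bin_counts(spikes, dt, n_bins)
  obj <- function(ltau) .profiled_rss(.leaky(n, dt, exp(ltau)), signal)$rss
  # coarse log-grid then local refinement: the profile is smooth in log(tau)
  grid <- log(c(2, 5, 10, 20, 50, 100, 200, 500))
  grid <- grid[exp(grid) > dt * 1.5]
  vals <- vapply(grid, obj, 1)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  o <- optimize(obj, c(lo, hi))
  tau <- exp(o$minimum)
  pr <- .profiled_rss(.leaky(n, dt, tau), signal)
  fitted <- linear_model(psp_weight = pr$coef[2], decay = tau,
                         baseline = pr$coef[1])
  .fit_result(fitted, pr$rss, signal)
}

# shared machinery for sigmoid-family fits: given nonlinear pars of one unit
# (log tau, log beta, theta) produce its sigmoid column sigma(beta (h - theta))
.sig_col <- function(n, dt, par) {
  h <- .leaky(n, dt, exp(par[1]))
  stats::plogis(exp(par[2]) * (h - par[3]))
}

.sig_inits <- function(n_starts, base, seed) {
  .with_seed(seed, {
    inits <- list(base)
    if (n_starts > 1)
      for (k in seq_len(n_starts - 1))
        inits[[k + 1]] <- base + c(rnorm(2, 0, 0.4), rnorm(1, 0, 0.5 * max(1, abs(base[3]))))
    inits
  })
}

.default_sig_init <- function(init) {
  base <- c(log(50), log(1), 5)
  if (!is.null(init)) {
    if (!is.null(init$tau)) base[1] <- log(init$tau)
    if (!is.null(init$beta)) base[2] <- log(init$beta)
    if (!is.null(init$theta)) base[3] <- init$theta
  }
  base
}

#' @export
fit_model.somatic_model <- function(model, spikes, signal, dt, n_starts = 5,
                                    seed = NULL, maxit = 400, init = NULL) {
  n_bins <- length(signal)
  n <- .bin_counts(spikes, dt, n_bins)
  obj <- function(p) .profiled_rss(.sig_col(n, dt, p), signal)$rss
  best <- NULL
  for (p0 in .sig_inits(n_starts, .default_sig_init(init), seed)) {
    o <- .nm(p0, obj, maxit)
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- best$par
  pr <- .profiled_rss(.sig_col(n, dt, p), signal)
  fitted <- somatic_model(exp(p[1]),
                          sigmoid_params(amplitude = pr$coef[2],
                                         steepness = exp(p[2]),
                                         threshold = p[3],
                                         offset = -pr$coef[1]))
  .fit_result(fitted, pr$rss, signal)
}

#' @export
fit_model.subunit_model <- function(model, spikes, signal, dt, n_starts = 5,
                                    seed = NULL, maxit = 400, init = NULL) {
  n_bins <- length(signal)
  k <- length(model$mapping)
  ns <- lapply(model$mapping, function(nn)
    .bin_counts(spikes, dt, n_bins, neurons = nn))
  shared <- model$wiring == "clustered"
  base <- .default_sig_init(init)
  if (shared) {
    obj <- function(p) {
      col <- Reduce(`+`, lapply(ns, .sig_col, dt = dt, par = p)) / k
      .profiled_rss(col, signal)$rss
    }
    best <- NULL
    for (p0 in .sig_inits(n_starts, base, seed)) {
      o <- .nm(p0, obj, maxit)
      if (is.null(best) || o$value < best$value) best <- o
    }
    p <- best$par
    col <- Reduce(`+`, lapply(ns, .sig_col, dt = dt, par = p)) / k
    pr <- .profiled_rss(col, signal)
    # soma averages the k identical subunits: amplitude is the profiled gain,
    # the intercept c0 enters as a common offset -c0 in every subunit
    sig <- sigmoid_params(amplitude = pr$coef[2], steepness = exp(p[2]),
                          threshold = p[3], offset = -pr$coef[1])
    fitted <- subunit_model(model$mapping, exp(p[1]), sig, model$wiring)
    return(.fit_result(fitted, pr$rss, signal))
  }
  # per-subunit parameters: multi-start + cyclic backfitting, linear profile
  # over all subunit amplitudes and a common intercept at every step
  fit_once <- function(pars) {
    for (pass in 1:3) {
      for (j in seq_len(k)) {
        others <- lapply(seq_len(k)[-j], function(l)
          .sig_col(ns[[l]], dt, pars[[l]]) / k)
        Xo <- do.call(cbind, others)
        oj <- function(pj) .profiled_rss(cbind(.sig_col(ns[[j]], dt, pj) / k, Xo),
                                         signal)$rss
        pars[[j]] <- .nm(pars[[j]], oj, maxit %/% 2)$par
      }
    }
    cols <- do.call(cbind, lapply(seq_len(k), function(j)
      .sig_col(ns[[j]], dt, pars[[j]]) / k))
    list(pars = pars, pr = .profiled_rss(cols, signal))
  }
  best <- NULL
  inits <- .sig_inits(n_starts, base, seed)
  for (p0 in inits) {
    r <- fit_once(rep(list(p0), k))
    if (is.null(best) || r$pr$rss < best$pr$rss) best <- r
  }
  # the design columns are sigma_j / k, so the profiled gains are already the
  # per-subunit amplitudes as seen before the soma's 1/k averaging
  sigs <- lapply(seq_len(k), function(j)
    sigmoid_params(amplitude = best$pr$coef[j + 1],
                   steepness = exp(best$pars[[j]][2]),
                   threshold = best$pars[[j]][3],
                   offset = -best$pr$coef[1]))
  fitted <- subunit_model(model$mapping,
                          vapply(best$pars, function(p) exp(p[1]), 1),
                          sigs, model$wiring)
  .fit_result(fitted, best$pr$rss, signal)
}

#' @export
fit_model.reduced_optimal_model <- function(model, spikes, signal, dt,
                                            n_starts = 5, seed = NULL,
                                            maxit = 400, init = NULL) {
  n_bins <- length(signal)
  make <- function(p) reduced_optimal_model(
    spike_gain = exp(p[1]), drift = exp(p[2]), u_plus = model$u_plus,
    u_minus = model$u_minus, leak = model$leak,
    leak_rate = if (model$leak == "proportional") exp(p[3]) else 0,
    leak_target = model$leak_target, nu_init = model$nu_init)
  obj <- function(p) {
    m <- make(p)
    v <- reduced_optimal_response(spikes, m, dt, n_bins * dt)$value
    sum((v - signal)^2)
  }
  p0 <- c(log(max(model$spike_gain, 1e-3)), log(max(model$drift, 1e-6)),
          if (model$leak == "proportional") log(max(model$leak_rate, 1e-6)))
  best <- NULL
  inits <- .with_seed(seed, {
    ii <- list(p0)
    if (n_starts > 1)
      for (kk in seq_len(n_starts - 1)) ii[[kk + 1]] <- p0 + rnorm(length(p0), 0, 0.3)
    ii
  })
  for (pp in inits) {
    o <- .nm(pp, obj, maxit)
    if (is.null(best) || o$value < best$value) best <- o
  }
  .fit_result(make(best$par), best$value, signal)
}

# mean-aggregate x over blocks of k bins (drops the tail remainder)
.agg_mean <- function(x, k) {
  if (k == 1) return(x)
  T2 <- (length(x) %/% k) * k
  colMeans(matrix(x[seq_len(T2)], nrow = k))
}

#' Benchmark the simplified models against the optimal response
#'
#' For each run: simulates a training + test sequence from the scenario,
#' computes the optimal (assumed-density-filter) response, fits the linear,
#' somatic, random-subunit and clustered-subunit models to the training
#' signal (the true equally-weighted mean of the presynaptic potentials), and
#' evaluates every model's fraction of variance explained on the held-out
#' test segment. Fitting and evaluation run on a coarser grid (`dt_fit`) than
#' the simulation/filter grid (`dt`) to keep the optimization tractable; the
#' signal is smooth on that scale.
#'
#' @param pop an [assembly_population()] scenario (e.g.
#'   `load_preset("fig4")`).
#' @param n_runs number of independent runs.
#' @param train_s,test_s training and test durations (s).
#' @param dt simulation/filter bin (ms).
#' @param dt_fit fitting/evaluation bin (ms); must be a multiple of `dt`.
#' @param seed master seed; per-run seeds are derived from it.
#' @param n_starts optimizer restarts per model.
#' @return `data.table` (class `benchmark_result`) with columns `run`,
#'   `model`, `performance`; a summary of paired comparisons against the
#'   optimal response is attached as attribute `"comparisons"`.
#' @export
benchmark_models <- function(pop, n_runs = 20, train_s = 240, test_s = 120,
                             dt = 0.5, dt_fit = 2, seed = 1, n_starts = 3) {
  groups <- .as_groups(pop)
  k_agg <- round(dt_fit / dt)
  stopifnot(abs(k_agg * dt - dt_fit) < 1e-9, k_agg >= 1)
  sizes <- vapply(groups, function(g) g$n_neurons, 1L)
  n_total <- sum(sizes)
  ends <- cumsum(sizes); starts <- c(0L, head(ends, -1))
  clustered_map <- lapply(seq_along(groups), function(g)
    seq.int(starts[g], ends[g] - 1L))
  run_seeds <- .with_seed(seed, sample.int(2^30, n_runs))
  total_s <- train_s + test_s
  # theory-derived initial guesses from the first group's statistics
  red <- reduced_from_params(groups[[1]])
  init_sub <- list(tau = 1 / max(red$leak_rate, 1e-4), beta = red$spike_gain,
                   theta = max(0.5, (red$drift / max(red$leak_rate, 1e-4) -
                                       red$leak_target) / red$spike_gain))
  init_som <- init_sub
  init_som$theta <- init_sub$theta * length(groups)
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    rs <- run_seeds[r]
    sim <- simulate_population(pop, total_s, dt = dt, seed = rs,
                               keep_potentials = FALSE)
    n_bins <- length(sim$signal)
    traj <- run_filter(sim$spikes, pop, dt = dt, duration_ms = n_bins * dt)
    sig_f <- .agg_mean(sim$signal, k_agg)
    opt_f <- .agg_mean(traj$mean, k_agg)
    nb_f <- length(sig_f)
    tr <- seq_len(floor(train_s * 1000 / dt_fit))
    te <- setdiff(seq_len(nb_f), tr)
    spikes_tr <- sim$spikes[sim$spikes$time_ms < train_s * 1000, ]
    rand_map <- .with_seed(rs + 1L, {
      perm <- sample.int(n_total) - 1L
      split(perm, rep(seq_along(groups), sizes))
    })
    templates <- list(
      linear = linear_model(1, 20, 0),
      somatic = somatic_model(50, sigmoid_params(1, 1, 1, 0)),
      random = subunit_model(rand_map, 50, sigmoid_params(1, 1, 1, 0),
                             wiring = "random"),
      clustered = subunit_model(clustered_map, 50, sigmoid_params(1, 1, 1, 0),
                                wiring = "clustered"))
    inits <- list(linear = NULL, somatic = init_som, random = init_sub,
                  clustered = init_sub)
    perf <- c(optimal = performance(opt_f[te], sig_f[te]))
    for (mn in names(templates)) {
      f <- fit_model(templates[[mn]], spikes_tr, sig_f[tr], dt_fit,
                     n_starts = n_starts, seed = rs + 2L,
                     init = inits[[mn]])
      resp <- switch(mn,
        linear = linear_response(sim$spikes, f$model, dt_fit, nb_f * dt_fit),
        somatic = somatic_response(sim$spikes, f$model, dt_fit, nb_f * dt_fit),
        subunit_response(sim$spikes, f$model, dt_fit, nb_f * dt_fit))
      perf[mn] <- performance(resp$value[te], sig_f[te])
    }
    out[[r]] <- data.table::data.table(run = r, model = names(perf),
                                       performance = unname(perf))
  }
  res <- data.table::rbindlist(out)
  if (n_runs >= 2) {
    wide <- data.table::dcast(res, run ~ model, value.var = "performance")
    cmp <- lapply(c("linear", "somatic", "random", "clustered"), function(mn) {
      tt <- t.test(wide[[mn]], wide$optimal, paired = TRUE)
      data.table::data.table(model = mn, mean_diff = unname(tt$estimate),
                             t = unname(tt$statistic), p = tt$p.value)
    })
    data.table::setattr(res, "comparisons", data.table::rbindlist(cmp))
  }
  data.table::setattr(res, "class", c("benchmark_result", class(res)))
  res[]
}

#' @export
print.benchmark_result <- function(x, ...) {
  s <- x[, list(mean = mean(performance), sd = sd(performance)),
         by = "model"]
  cat("cross-validated performance (fraction of variance explained):\n")
  print(as.data.frame(s), row.names = FALSE)
  cmp <- attr(x, "comparisons")
  if (!is.null(cmp)) {
    cat("paired comparisons vs optimal:\n")
    print(as.data.frame(cmp), row.names = FALSE)
  }
  invisible(x)
}
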