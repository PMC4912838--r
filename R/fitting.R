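#' Uncaging-style stimulation protocol
#'
#' A burst of stimulation events, each targeting one synaptic site. Sites
#' flagged non-responsive are treated as non-stimulated downstream.
#'
#' @param events data.frame with `time_ms` (nondecreasing) and 0-based
#'   `site`.
#' @param n_sites number of sites.
#' @param isi nominal inter-stimulus interval (ms), informational.
#' @param responsive logical vector, one flag per site.
#' @export
stimulus_protocol <- function(events, n_sites,
                              isi = NULL, responsive = rep(TRUE, n_sites)) {
  events <- as.data.frame(events)
  stopifnot(all(c("time_ms", "site") %in% names(events)),
            length(responsive) == n_sites)
  if (nrow(events)) {
    if (is.unsorted(events$time_ms)) stop("event times must be nondecreasing")
    if (any(events$site < 0 | events$site >= n_sites))
      stop("site index out of range")
  }
  structure(list(events = events, n_sites = as.integer(n_sites), isi = isi,
                 responsive = as.logical(responsive)),
            class = "stimulus_protocol")
}

#' Convenience constructor for an equally spaced stimulus train
#'
#' @param n_stim number of stimuli.
#' @param isi inter-stimulus interval (ms).
#' @param t0 time of the first stimulus (ms).
#' @param sites site of each stimulus (default: distinct sites 0..n_stim-1).
#' @param n_sites total number of sites.
#' @export
burst_protocol <- function(n_stim, isi, t0 = 0, sites = seq_len(n_stim) - 1L,
                           n_sites = max(sites) + 1L) {
  stimulus_protocol(data.frame(time_ms = t0 + (seq_len(n_stim) - 1) * isi,
                               site = sites),
                    n_sites = n_sites, isi = isi)
}

#' Map a stimulation protocol to presynaptic spike trains
#'
#' Each event becomes a single spike of the presynaptic neuron of its site;
#' events on non-responsive sites are dropped. Responsive sites are
#' renumbered to consecutive 0-based neuron ids (the attribute
#' `"site_to_neuron"` records the mapping).
#'
#' @param protocol a [stimulus_protocol()].
#' @return data.frame with `neuron_id`, `time_ms`.
#' @export
protocol_to_spikes <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  keep_sites <- which(protocol$responsive) - 1L
  map <- rep(NA_integer_, protocol$n_sites)
  map[keep_sites + 1L] <- seq_along(keep_sites) - 1L
  ev <- protocol$events
  ev <- ev[ev$site %in% keep_sites, , drop = FALSE]
  out <- data.frame(neuron_id = map[ev$site + 1L], time_ms = ev$time_ms)
  out <- out[order(out$time_ms, out$neuron_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "site_to_neuron") <- map
  attr(out, "n_neurons") <- length(keep_sites)
  out
}

.gauss_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  r <- max(1L, ceiling(4 * sigma_samples))
  k <- exp(-0.5 * ((-r:r) / sigma_samples)^2)
  k <- k / sum(k)
  xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + length(x))]
}

#' Preprocess recorded voltage traces
#'
#' Repetitions are averaged, smoothed with a Gaussian kernel (s.d. `sigma_ms`)
#' and decimated from `sample_khz` to `target_khz`. Individual repetitions
#' are processed identically and kept for [intrinsic_variability()].
#'
#' @param reps numeric vector (single trace) or matrix with one repetition
#'   per column; all repetitions must have equal length.
#' @param sample_khz source sampling rate (kHz).
#' @param sigma_ms Gaussian kernel s.d. (ms).
#' @param target_khz output sampling rate (kHz).
#' @return object of class `recorded_trace`: averaged processed `values`,
#'   processed `reps`, `sample_khz` (= `target_khz`) and the preprocessing
#'   record.
#' @export
preprocess_trace <- function(reps, sample_khz = 50, sigma_ms = 0.2,
                             target_khz = 2) {
  if (is.list(reps)) {
    if (length(unique(lengths(reps))) != 1)
      stop("repetitions must all have the same length")
    reps <- do.call(cbind, reps)
  }
  if (!is.matrix(reps)) reps <- matrix(reps, ncol = 1)
  stopifnot(sigma_ms > 0, target_khz <= sample_khz)
  fac <- sample_khz / target_khz
  if (abs(fac - round(fac)) > 1e-9)
    stop("sample_khz must be an integer multiple of target_khz")
  fac <- as.integer(round(fac))
  sg <- sigma_ms * sample_khz
  proc <- apply(reps, 2, .gauss_smooth, sigma_samples = sg)
  idx <- seq.int(1, by = fac, length.out = nrow(reps) %/% fac)
  proc <- proc[idx, , drop = FALSE]
  structure(list(values = rowMeans(proc), reps = proc,
                 sample_khz = target_khz,
                 preprocessing = list(sigma_ms = sigma_ms,
                                      source_khz = sample_khz,
                                      factor = fac)),
            class = "recorded_trace")
}

#' Intrinsic (trial-to-trial) variability of a trace set
#'
#' Lower bound on any model's normalized fitting error: the mean across
#' repetitions of the per-repetition mean squared deviation from the
#' repetition average, normalized by the variance of the average trace,
#' \deqn{\bar\epsilon_{min} = \frac{1}{L-1}\sum_l \frac{1}{T}\sum_t
#'   (v^*_{t,l} - \bar v^*_t)^2 \ / \ \mathrm{Var}[\bar v^*]}
#' (outer 1/(L-1), inner 1/T, variance with 1/(T-1), as printed).
#'
#' @param reps matrix with one repetition per column (>= 2 columns), or a
#'   `recorded_trace`.
#' @export
intrinsic_variability <- function(reps) {
  if (inherits(reps, "recorded_trace")) reps <- reps$reps
  stopifnot(is.matrix(reps))
  L <- ncol(reps)
  if (L < 2) stop("at least 2 repetitions are required")
  vbar <- rowMeans(reps)
  v <- var(vbar)
  if (!is.finite(v) || v <= 0)
    stop("variance of the average trace is zero: normalization undefined")
  sum(colMeans((reps - vbar)^2)) / (L - 1) / v
}

#' Classify a spine as responsive from its unitary response
#'
#' Least-squares fit of the double-exponential
#' \eqn{\phi(t) = \phi_0 (e^{-(t-t_0)/\tau_1} - e^{-(t-t_0)/\tau_2})}
#' (zero before \eqn{t_0}; \eqn{\tau_1} decay, \eqn{\tau_2} rise). The spine
#' is non-responsive if the rise time \eqn{\tau_2 > 15} ms or the start time
#' \eqn{t_0 > 5} ms, or if the fit fails.
#'
#' @param trace numeric unitary response, or a `recorded_trace` (its averaged
#'   `values` are used).
#' @param sample_khz sampling rate of `trace` (kHz); ignored for a
#'   `recorded_trace`. Time zero is the stimulation time.
#' @param n_starts optimizer restarts.
#' @return list with `responsive`, `phi0`, `t0`, `tau1`, `tau2`, `sse`, `ok`.
#' @export
classify_spine <- function(trace, sample_khz = 2, n_starts = 4) {
  if (inherits(trace, "recorded_trace")) {
    sample_khz <- trace$sample_khz
    trace <- trace$values
  }
  tt <- (seq_along(trace) - 1) / sample_khz
  shape <- function(p) { # p = (t0, log tau1, log tau2)
    s <- exp(-(tt - p[1]) / exp(p[2])) - exp(-(tt - p[1]) / exp(p[3]))
    s[tt < p[1]] <- 0
    s
  }
  obj <- function(p) {
    if (exp(p[3]) >= exp(p[2])) return(1e12) # require rise faster than decay
    s <- shape(p)
    ss <- sum(s^2)
    if (!is.finite(ss) || ss <= 0) return(1e12)
    phi0 <- sum(s * trace) / ss
    sum((trace - phi0 * s)^2)
  }
  ipk <- which.max(trace)
  t_pk <- tt[min(ipk, length(tt))]
  starts <- list(c(max(0, t_pk - 5), log(20), log(2)),
                 c(0, log(30), log(1)),
                 c(max(0, t_pk / 2), log(50), log(5)),
                 c(1, log(15), log(0.5)))
  best <- NULL
  for (p0 in starts[seq_len(min(n_starts, length(starts)))]) {
    o <- tryCatch(.nm(p0, obj, 600), error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e12)
    return(list(responsive = FALSE, phi0 = NA_real_, t0 = NA_real_,
                tau1 = NA_real_, tau2 = NA_real_, sse = NA_real_, ok = FALSE))
  p <- best$par
  s <- shape(p)
  phi0 <- sum(s * trace) / sum(s^2)
  t0 <- p[1]; tau1 <- exp(p[2]); tau2 <- exp(p[3])
  list(responsive = (tau2 <= 15 && t0 <= 5), phi0 = phi0, t0 = t0,
       tau1 = tau1, tau2 = tau2, sse = best$value, ok = TRUE)
}

# unit-weight, baseline-subtracted optimal-response basis for one condition
.condition_basis <- function(spikes, pop, dt, duration_ms) {
  n <- sum(vapply(.as_groups(pop), function(g) g$n_neurons, 1L))
  traj <- run_filter(spikes, pop, dt = dt, duration_ms = duration_ms,
                     weights = rep(1, n))
  traj$mean - traj$mean[1]
}

#' Fit the optimal response to stimulation-protocol traces
#'
#' Jointly fits, across all conditions of one cell, the synaptic weight `w`
#' (shared by all presynaptic neurons) and the postsynaptic time constant
#' `tau_post` of the optimal response under the chosen presynaptic statistics
#' preset, plus one structure parameter: the functional cluster size N for
#' the state-switching presets (`NC`, `HP`; integer grid search, ties towards
#' smaller N) or the pairwise correlation `rho` for `cor2` (grid on
#' \eqn{[-1/(N-1), 1)}). `ind` has no structure parameter (2 free parameters;
#' the others have 3). For fixed structure, `w` enters linearly and is
#' profiled out; `tau_post` is optimized on a log grid plus local refinement.
#'
#' Predictions and data are compared baseline-subtracted (both start at their
#' pre-stimulus value); the pooled mean squared error across conditions is
#' normalized by the pooled variance of the (repetition-averaged) data.
#'
#' @param conditions list of conditions; each is a list with elements
#'   `protocol` (a [stimulus_protocol()]) and `trace` (a `recorded_trace`,
#'   or a numeric vector with `sample_khz` given alongside).
#' @param preset one of `"NC"`, `"HP"`, `"cor2"`, `"ind"`.
#' @param dt filter bin width (ms).
#' @param N_grid integer candidate cluster sizes (state-switching presets);
#'   values below the number of stimulated neurons are raised to it.
#' @param rho_grid candidate correlations for `cor2`.
#' @param tau_grid candidate `tau_post` values (ms); 0 is always included.
#' @return object of class `fit_result`.
#' @export
fit_optimal_to_traces <- function(conditions, preset = c("NC", "HP", "cor2", "ind"),
                                  dt = 0.1, N_grid = NULL, rho_grid = NULL,
                                  tau_grid = c(0, 1, 2, 5, 10, 20, 50)) {
  preset <- match.arg(preset)
  conds <- lapply(conditions, function(cd) {
    spk <- protocol_to_spikes(cd$protocol)
    tr <- cd$trace
    if (inherits(tr, "recorded_trace")) {
      khz <- tr$sample_khz; reps <- tr$reps; y <- tr$values
    } else {
      khz <- cd$sample_khz; reps <- NULL; y <- as.numeric(tr)
    }
    list(spikes = spk, n_stim = attr(spk, "n_neurons"), y = y - y[1],
         reps = reps, khz = khz,
         duration_ms = length(y) / khz)
  })
  n_stim_max <- max(vapply(conds, `[[`, 1L, "n_stim"))
  if (preset %in% c("NC", "HP")) {
    if (is.null(N_grid)) N_grid <- 1:200
    grid <- sort(unique(pmax(as.integer(N_grid), n_stim_max)))
  } else if (preset == "cor2") {
    if (is.null(rho_grid))
      rho_grid <- seq(-1 / (n_stim_max + 19), 0.95, length.out = 20)
    grid <- rho_grid
  } else grid <- NA # ind: no structure parameter

  y_all <- unlist(lapply(conds, `[[`, "y"))
  eval_structure <- function(gval) {
    bases <- lapply(conds, function(cd) {
      # NC/HP: all conditions share the fitted cluster size; cor2: the
      # cluster adds a fixed 20 unstimulated neurons and rho is fitted;
      # ind: only the stimulated neurons exist
      pop <- switch(preset,
        NC = load_preset("NC", n_neurons = gval),
        HP = load_preset("HP", n_neurons = gval),
        cor2 = load_preset("cor2", n_neurons = cd$n_stim + 20L, rho = gval),
        ind = load_preset("ind", n_neurons = cd$n_stim))
      .condition_basis(cd$spikes, pop, dt, cd$duration_ms)
    })
    fit_tau <- function(tau) {
      pred <- mapply(function(b, cd) {
        p <- .lowpass(b, dt, tau)
        p <- p - p[1]
        stride <- (1 / cd$khz) / dt
        idx <- round(seq.int(1, by = stride, length.out = length(cd$y)))
        p[pmin(idx, length(p))]
      }, bases, conds, SIMPLIFY = FALSE)
      pv <- unlist(pred)
      den <- sum(pv^2)
      w <- if (den > 0) sum(pv * y_all) / den else 0
      list(rss = sum((y_all - w * pv)^2), w = w)
    }
    rs <- vapply(tau_grid, function(tv) fit_tau(tv)$rss, 1)
    i <- which.min(rs)
    tau <- tau_grid[i]
    if (i > 1 && i < length(tau_grid)) {
      o <- optimize(function(lt) fit_tau(exp(lt))$rss,
                    log(c(max(tau_grid[i - 1], dt * 1.5), tau_grid[i + 1])))
      if (o$objective < rs[i]) tau <- exp(o$minimum)
    }
    ft <- fit_tau(tau)
    list(rss = ft$rss, w = ft$w, tau = tau)
  }

  fits <- lapply(grid, eval_structure)
  rss <- vapply(fits, `[[`, 1, "rss")
  ibest <- which.min(rss) # which.min takes the first minimum: smaller N wins ties
  best <- fits[[ibest]]
  n_obs <- length(y_all)
  mu <- mean(y_all)
  var_pooled <- sum((y_all - mu)^2) / (n_obs - 1)
  k <- if (preset == "ind") 2L else 3L
  eps_min <- {
    rr <- lapply(conds, `[[`, "reps")
    if (all(!vapply(rr, is.null, TRUE)) &&
        all(vapply(rr, ncol, 1L) >= 2)) {
      allreps <- do.call(rbind, rr)
      tryCatch(intrinsic_variability(allreps), error = function(e) NA_real_)
    } else NA_real_
  }
  structure(list(
    preset = preset, w = best$w, tau_post = best$tau,
    N = if (preset %in% c("NC", "HP")) grid[ibest] else NA_integer_,
    rho = if (preset == "cor2") grid[ibest] else NA_real_,
    eps_fitting = best$rss / n_obs / var_pooled,
    eps_min = eps_min,
    rss = best$rss, n_obs = n_obs, n_free_params = k,
    bic = -n_obs / 2 * log(best$rss / n_obs) - k / 2 * log(n_obs),
    likelihood = "gaussian residuals, variance profiled out"),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("optimal-response fit, preset %s: w = %.4g mV, tau_post = %.3g ms",
              x$preset, x$w, x$tau_post))
  if (!is.na(x$N)) cat(sprintf(", N = %d", x$N))
  if (!is.na(x$rho)) cat(sprintf(", rho = %.3g", x$rho))
  cat(sprintf("\n  eps_fitting = %.4g, eps_min = %.4g, BIC = %.4g (%d free params)\n",
              x$eps_fitting, x$eps_min, x$bic, x$n_free_params))
  invisible(x)
}

#' Normalized fitting error of a prediction
#'
#' \eqn{\bar\epsilon_{fitting} = \mathrm{MSE}/\mathrm{Var}(data)} with MSE
#' using 1/T and the variance 1/(T-1). Zero for a perfect prediction.
#'
#' @param prediction,data numeric vectors of equal length.
#' @export
fitting_error <- function(prediction, data) {
  stopifnot(length(prediction) == length(data))
  v <- var(data)
  if (!is.finite(v) || v <= 0)
    stop("data variance is zero: normalization undefined")
  mean((prediction - data)^2) / v
}

#' BIC difference between two fits
#'
#' Gaussian-residual BIC with the noise variance profiled out, on the scale
#' where each unit of difference corresponds to an e-fold likelihood ratio:
#' score = -(n/2) ln(RSS/n) - (k/2) ln(n); one extra parameter at equal
#' residuals costs ln(n)/2. Positive values favour `fit_a`.
#'
#' @param fit_a,fit_b `fit_result` objects, or lists with elements `rss` and
#'   `n_free_params`.
#' @param n_obs number of observations (default taken from `fit_a`).
#' @export
bic_compare <- function(fit_a, fit_b, n_obs = fit_a$n_obs) {
  sc <- function(f) -n_obs / 2 * log(f$rss / n_obs) -
    f$n_free_params / 2 * log(n_obs)
  sc(fit_a) - sc(fit_b)
}
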