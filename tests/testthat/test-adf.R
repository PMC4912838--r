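test_that("posterior initialization is the stationary prior", {
  p <- tiny_params(rate_to_active = 3, rate_to_quiescent = 3)
  st <- init_posterior(p)
  expect_equal(st$zeta, 0.5)
  hp <- load_preset("HP")
  expect_equal(init_posterior(hp)$zeta, 0.027 / 10.027)
  expect_equal(st$S_plus, p$stationary_cov)
  expect_equal(st$S_minus, p$stationary_cov)
  expect_equal(st$mu_plus, rep(2, 2))
})

test_that("without observations the filter relaxes to the prior fixed point", {
  p <- tiny_params(rate_at_threshold = 0) # g = 0: no spike evidence
  st <- init_posterior(p)
  st$zeta <- 0.9
  st$mu_plus <- c(6, -1)
  st$S_plus <- diag(c(4, 4))
  for (i in 1:8000) st <- adf_step(st, integer(0), 0.1, p)
  expect_equal(st$zeta, stationary_state_prob(p), tolerance = 1e-4)
  # stationary conditional means solve the coupled linear system of decay
  # towards +-ubar and state mixing (at zeta* the mixing prefactors are
  # Omega- into the + state and Omega+ into the - state); they are the
  # *lagged* conditional means, not +-ubar, because the potential follows
  # the state with time constant tau
  omm <- 0.01; omp <- 0.005 # per-ms mixing rates at zeta* = 1/3
  A <- matrix(c(1 / 20 + omm, -omm, -omp, 1 / 20 + omp), 2, byrow = TRUE)
  mfix <- solve(A, c(2 / 20, -2 / 20))
  expect_equal(st$mu_plus, rep(mfix[1], 2), tolerance = 1e-3)
  expect_equal(st$mu_minus, rep(mfix[2], 2), tolerance = 1e-3)
  # covariances reach a fixed point of the drift: one more step is a no-op
  st2 <- adf_step(st, integer(0), 0.1, p)
  expect_lt(max(abs(st2$S_plus - st$S_plus)), 1e-6)
})

test_that("state evidence has the right sign", {
  # symmetric states: no-spike evidence term vanishes, zeta stays put
  p <- tiny_params(resting_half_gap = 0, rate_to_active = 5,
                   rate_to_quiescent = 5)
  st <- adf_step(init_posterior(p), integer(0), 0.1, p)
  expect_equal(st$zeta, 0.5, tolerance = 1e-12)
  # a spike where gamma+ > gamma- must increase zeta
  hp <- load_preset("HP")
  st0 <- init_posterior(hp)
  st1 <- adf_step(st0, 0L, 0.1, hp)
  expect_gt(st1$zeta, st0$zeta)
  # exact-Bayes jump agrees in direction and roughly in size
  st2 <- adf_step(st0, 0L, 0.1, hp, zeta_jump = "exact")
  expect_gt(st2$zeta, st0$zeta)
  expect_error(adf_step(st0, c(0L, 0L), 0.1, hp), "one spike per neuron")
})

test_that("compiled filter matches the pure-R reference bitwise-tight", {
  for (nm in c("fig2s1", "NC", "cor2")) {
    p <- load_preset(nm, n_neurons = if (nm == "fig2s1") NULL else 3)
    tr <- simulate_population(p, 0.5, dt = 0.1, seed = 17)
    a <- run_filter(tr$spikes, p, dt = 0.1, duration_ms = 500, engine = "cpp")
    b <- run_filter(tr$spikes, p, dt = 0.1, duration_ms = 500, engine = "r")
    expect_equal(a$mean, b$mean, tolerance = 1e-12)
    expect_equal(a$groups[[1]]$zeta, b$groups[[1]]$zeta, tolerance = 1e-12)
    expect_equal(a$groups[[1]]$S_plus_final, b$groups[[1]]$S_plus_final,
                 tolerance = 1e-10)
  }
})

test_that("independent statistics factorize: marginals and additivity", {
  ind <- load_preset("ind", n_neurons = 3)
  spk <- spikes_df(c(0, 1, 1, 2), c(10, 12, 30, 31))
  joint <- run_filter(spk, ind, dt = 0.1, duration_ms = 100,
                      keep_moments = TRUE)
  for (i in 0:2) {
    ind1 <- load_preset("ind", n_neurons = 1)
    si <- spk[spk$neuron_id == i, ]
    si$neuron_id <- 0L
    solo <- run_filter(si, ind1, dt = 0.1, duration_ms = 100,
                       keep_moments = TRUE)
    expect_equal(joint$groups[[1]]$mu_plus[i + 1, ],
                 solo$groups[[1]]$mu_plus[1, ], tolerance = 1e-9)
  }
  # response additivity across neurons (baseline-corrected)
  r <- function(s) optimal_response(
    run_filter(s, ind, dt = 0.1, duration_ms = 100))$value
  base <- r(no_spikes)
  sA <- spikes_df(0, 20); sB <- spikes_df(1, 35)
  lhs <- r(rbind(sA, sB))
  rhs <- r(sA) + r(sB) - base
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs - base)), 1e-6)
})

test_that("posterior mean potential matches a sampling oracle", {
  st <- structure(list(zeta = 0.3, mu_plus = c(2, 1), mu_minus = c(-2, 0.5),
                       S_plus = equicorr_cov(2, 1, 0.5),
                       S_minus = diag(2), refractory = c(0, 0)),
                  class = "posterior_state")
  w <- c(0.7, 0.3)
  expect_equal(posterior_mean_potential(
    structure(modifyList(st, list(zeta = 1)), class = "posterior_state"), w),
    sum(w * st$mu_plus))
  sym <- structure(modifyList(st, list(zeta = 0.5, mu_minus = -st$mu_plus)),
                   class = "posterior_state")
  expect_equal(posterior_mean_potential(sym, w), 0)
  set.seed(42)
  M <- 2e5
  on <- runif(M) < st$zeta
  Lp <- t(chol(st$S_plus)); Lm <- t(chol(st$S_minus))
  draws <- vapply(seq_len(M), function(m) {
    mu <- if (on[m]) st$mu_plus else st$mu_minus
    L <- if (on[m]) Lp else Lm
    sum(w * (mu + L %*% rnorm(2)))
  }, 1)
  expect_lt(abs(mean(draws) - posterior_mean_potential(st, w)),
            3 * sd(draws) / sqrt(M))
})

test_that("an empty spike train is evidence for quiescence", {
  hp <- load_preset("HP")
  traj <- run_filter(no_spikes, hp, dt = 0.1, duration_ms = 2000)
  z <- traj$groups[[1]]$zeta
  expect_lt(z[length(z)], init_posterior(hp)$zeta)
  expect_true(all(diff(z) <= 1e-12))
})

test_that("filtering is deterministic given identical inputs", {
  hp <- load_preset("HP")
  tr <- simulate_population(hp, 2, dt = 0.1, seed = 3)
  a <- run_filter(tr$spikes, hp, dt = 0.1, duration_ms = 2000)
  b <- run_filter(tr$spikes, hp, dt = 0.1, duration_ms = 2000)
  expect_identical(a$mean, b$mean)
})

test_that("zeta stays in [0,1] and covariances stay symmetric PSD", {
  # long-horizon stability property (nominally 1000 s); run at 15-100 s to stay
  # inside the test budget (documented scale-down). The high-beta presets
  # need the finer dt that their own spiking statistics demand.
  for (nm in single_group_presets) {
    p <- load_preset(nm)
    stiff <- nm %in% c("cor2", "fig2ab")
    dtv <- if (stiff) 0.1 else 0.5
    # fig2ab is N = 70: the O(N^3) per-bin cost dominates the whole suite,
    # so it gets the shortest horizon
    dur <- if (nm == "fig2ab") 15 else if (stiff) 50 else 100
    tr <- suppressWarnings(
      simulate_population(p, dur, dt = dtv, seed = 23,
                          keep_potentials = FALSE))
    traj <- run_filter(tr$spikes, p, dt = dtv, duration_ms = tr$duration_ms)
    g <- traj$groups[[1]]
    expect_true(all(g$zeta >= 1e-6 & g$zeta <= 1 - 1e-6), label = nm)
    # per-bin PSD probe: the recorded quadratic forms w'Sw must stay >= 0
    expect_true(all(g$v_plus >= -1e-10 & g$v_minus >= -1e-10), label = nm)
    expect_lt(max(abs(g$S_plus_final - t(g$S_plus_final))), 1e-10)
    ev <- eigen(g$S_plus_final, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("halving dt changes the response by less than 1% RMS", {
  for (nm in single_group_presets) {
    p <- load_preset(nm)
    # base dt chosen inside each preset's own validity regime; shorter
    # horizon for the N = 70 preset (O(N^3) per bin)
    dtv <- if (nm %in% c("cor2", "fig2ab")) 0.05 else 0.1
    dur <- if (nm == "fig2ab") 3 else 10
    tr <- suppressWarnings(
      simulate_population(p, dur, dt = dtv, seed = 29,
                          keep_potentials = FALSE))
    a <- run_filter(tr$spikes, p, dt = dtv, duration_ms = tr$duration_ms)
    b <- run_filter(tr$spikes, p, dt = dtv / 2, duration_ms = tr$duration_ms)
    vb <- b$mean[seq(2, length(b$mean), by = 2)] # align bin end times
    va <- a$mean[seq_len(length(vb))]
    rel <- sqrt(mean((va - vb)^2)) / sd(va)
    expect_lt(rel, 0.01, label = nm)
  }
})

test_that("burst integration is supralinear for HP, sublinear for cor2", {
  hp <- load_preset("HP")
  burst <- spikes_df(0:5, 50 + 0:5)
  single <- spikes_df(0, 50)
  expect_gt(response_amplitude(burst, hp),
            6 * response_amplitude(single, hp))
  c2 <- load_preset("cor2", n_neurons = 10, rho = 0.5)
  expect_lt(response_amplitude(burst, c2),
            6 * response_amplitude(single, c2))
})

test_that("rate readout: constants and stronger burst nonlinearity", {
  p0 <- tiny_params(spiking_steepness = 0, rate_at_threshold = 4)
  traj <- run_filter(no_spikes, p0, dt = 0.1, duration_ms = 50)
  expect_equal(rate_readout(traj)$value, rep(4, 500), tolerance = 1e-9)

  hp <- load_preset("HP")
  burst <- spikes_df(0:5, 50 + 0:5)
  single <- spikes_df(0, 50)
  ampl <- function(spk, fun) {
    tr <- fun(run_filter(spk, hp, dt = 0.1, duration_ms = 200))$value
    max(tr - tr[1])
  }
  nl_rate <- ampl(burst, rate_readout) / (6 * ampl(single, rate_readout))
  nl_volt <- ampl(burst, optimal_response) / (6 * ampl(single, optimal_response))
  expect_gte(nl_rate, nl_volt)
})

test_that("sigmoid readout matches quadrature and its limits", {
  p <- load_preset("fig2s1")
  tr <- simulate_population(p, 0.2, dt = 0.1, seed = 31)
  traj <- run_filter(tr$spikes, p, dt = 0.1, duration_ms = 200)
  ro <- readout_params(weights = 1, mode = "sigmoid", beta_f = 1,
                       theta_f = 1, n_samples = 200000)
  # evaluate the heavy Monte-Carlo readout only at a handful of bins
  idx <- seq(1, length(traj$time), by = 200)
  g <- traj$groups[[1]]
  gs <- g
  for (fld in c("zeta", "m_plus", "m_minus", "v_plus", "v_minus",
                "r_plus", "r_minus"))
    gs[[fld]] <- g[[fld]][idx]
  tsub <- structure(list(time = traj$time[idx], dt = traj$dt,
                         groups = list(gs), n_neurons = 1),
                    class = "adf_trajectory")
  out <- nonlinear_readout(tsub, ro, seed = 77)
  # quadrature oracle over the two-component normal mixture
  quad <- vapply(idx, function(t) {
    f <- function(x) optidend:::.sigmoid_f(x, 1, 1, TRUE) *
      (g$zeta[t] * dnorm(x, g$m_plus[t], sqrt(g$v_plus[t])) +
         (1 - g$zeta[t]) * dnorm(x, g$m_minus[t], sqrt(g$v_minus[t])))
    integrate(f, -Inf, Inf)$value
  }, 1)
  expect_equal(out$value, quad, tolerance = 2e-3)

  # variance -> 0: readout equals the sigmoid of the posterior mean
  g0 <- g
  g0$v_plus[] <- 1e-18; g0$v_minus[] <- 1e-18
  tz <- structure(list(time = traj$time, dt = 0.1, groups = list(g0),
                       n_neurons = 1), class = "adf_trajectory")
  out0 <- nonlinear_readout(tz, readout_params(1, mode = "sigmoid",
                                               beta_f = 2, theta_f = 0,
                                               n_samples = 10), seed = 1)
  mix <- g0$zeta * g0$m_plus + (1 - g0$zeta) * g0$m_minus
  # mixture of two point masses, not a point mass: compare where states agree
  conf <- g0$zeta > 0.999 | g0$zeta < 0.001
  expect_equal(out0$value[conf],
               optidend:::.sigmoid_f(mix, 2, 0, TRUE)[conf], tolerance = 1e-2)

  # beta_f = 0 is constant 1/(1+e^{-theta_f}) under the printed convention
  outc <- nonlinear_readout(traj, readout_params(1, mode = "sigmoid",
                                                 beta_f = 0, theta_f = 1.5,
                                                 n_samples = 10), seed = 2)
  expect_equal(outc$value, rep(1 / (1 + exp(-1.5)), length(traj$time)))
})
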