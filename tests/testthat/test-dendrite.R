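test_that("linear model: PSP shape, superposition, baseline", {
  m <- linear_model(psp_weight = 1.5, decay = 10, baseline = -0.5)
  one <- linear_response(spikes_df(0, 5), m, dt = 0.1, duration_ms = 50)
  i0 <- 51 # bin of the spike
  expect_equal(one$value[i0] - m$baseline, 1.5)
  expect_equal(one$value[i0 + 100] - m$baseline,
               1.5 * (1 - 0.1 / 10)^100, tolerance = 1e-12)
  expect_true(all(one$value[seq_len(i0 - 1)] == m$baseline))

  a <- linear_response(spikes_df(0, 5), m, 0.1, 50)$value
  b <- linear_response(spikes_df(3, 17), m, 0.1, 50)$value
  ab <- linear_response(spikes_df(c(0, 3), c(5, 17)), m, 0.1, 50)$value
  expect_equal(ab, a + b - m$baseline, tolerance = 1e-12)
  none <- linear_response(no_spikes, m, 0.1, 20)
  expect_equal(none$value, rep(-0.5, 200))
})

test_that("somatic sigmoid: bounds, degenerate slope, monotonicity", {
  s <- sigmoid_params(amplitude = 3, steepness = 2, threshold = 1, offset = 1)
  m <- somatic_model(decay = 15, sigmoid = s)
  flat <- somatic_model(15, sigmoid_params(3, 0, 1, 1))
  expect_equal(somatic_response(no_spikes, flat, 0.5, 10)$value,
               rep(3 / 2 - 1, 20))
  spk <- spikes_df(rep(0, 20), seq(1, 96, by = 5))
  r <- somatic_response(spk, m, 0.5, 100)$value
  expect_true(all(r > -1 & r < 2)) # (-offset, amplitude - offset)
  r_more <- somatic_response(rbind(spk, spikes_df(0, 50)), m, 0.5, 100)$value
  expect_true(all(r_more - r >= -1e-12))
})

test_that("subunit model: wiring validation and clustered symmetry", {
  expect_error(subunit_model(list(0:2, 2:4), 10, sigmoid_params(1, 1, 0)),
               "wiring error")
  s <- sigmoid_params(2, 1.5, 2, 0.7)
  m4 <- subunit_model(list(0:1, 2:3, 4:5, 6:7), 12, s)
  m1 <- subunit_model(list(0:1), 12, s)
  # identical spike trains into every subunit: average equals one subunit
  tt <- c(3, 9, 21)
  spk4 <- do.call(rbind, lapply(0:3, function(g)
    spikes_df(2 * g, tt)))
  r4 <- subunit_response(spk4, m4, 0.5, 40)$value
  r1 <- subunit_response(spikes_df(0, tt), m1, 0.5, 40)$value
  expect_equal(r4, r1, tolerance = 1e-12)
  # permuting neurons within a subunit changes nothing
  r4b <- subunit_response(do.call(rbind, lapply(0:3, function(g)
    spikes_df(2 * g + 1, tt))), m4, 0.5, 40)$value
  expect_equal(r4, r4b)
})

test_that("sigmoid subunits are supralinear on the upstroke, sublinear on the shoulder", {
  s <- sigmoid_params(amplitude = 1, steepness = 1, threshold = 5, offset = 0)
  m <- subunit_model(list(0:9), decay = 50, sigmoid = s)
  resp <- function(spk) subunit_response(spk, m, 0.5, 120)$value
  delta_amp <- function(background, k) {
    burst <- spikes_df(seq_len(k) - 1, rep(100, k))
    base <- resp(background)
    both <- resp(rbind(background, burst))
    max(both - base)
  }
  # sparse input, drive near 0 (convex upstroke): 4 synchronous spikes beat
  # 4x a single spike
  expect_gt(delta_amp(no_spikes, 4), 4 * delta_amp(no_spikes, 1))
  # asynchronous background holding the drive just past threshold (the
  # saturating shoulder): the same burst now adds less than the linear
  # prediction
  bg_t <- seq(0.5, 99, by = 8)
  bg <- spikes_df(seq_along(bg_t) %% 10, bg_t)
  expect_gt(delta_amp(bg, 1), 1e-6) # not fully saturated
  expect_lt(delta_amp(bg, 4), 4 * delta_amp(bg, 1))
})

test_that("reduced integrator: drift, spike increments, leak", {
  m <- reduced_optimal_model(spike_gain = 2, drift = 0.01, u_plus = 2,
                             u_minus = -2, leak = "none", nu_init = 0)
  r0 <- reduced_optimal_response(no_spikes, m, 0.5, 100)
  nu <- attr(r0, "nu")
  expect_equal(diff(nu), rep(-0.01 * 0.5, 199))
  expect_true(all(diff(r0$value) < 0))
  r1 <- reduced_optimal_response(spikes_df(0, 50), m, 0.5, 100)
  nu1 <- attr(r1, "nu")
  expect_equal(nu1[101] - (nu[101]), 2) # the spike adds exactly B
  # proportional leak relaxes nu to the leak target without input
  ml <- reduced_optimal_model(2, 0, 2, -2, leak = "proportional",
                              leak_rate = 0.05, leak_target = -3, nu_init = 1)
  rl <- reduced_optimal_response(no_spikes, ml, 0.5, 400)
  expect_equal(attr(rl, "nu")[800], -3, tolerance = 1e-3)
})

test_that("performance matches hand-computed values", {
  expect_equal(performance(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  # predicting the time-average: the printed formulas (MSE with 1/T,
  # variance with 1/(T-1)) give exactly 1/T, which is 0 only as T grows
  expect_equal(performance(rep(2.5, 4), c(1, 2, 3, 4)), 1 / 4)
  x <- sin(seq_len(2000))
  expect_equal(performance(rep(mean(x), 2000), x), 1 / 2000)
  # frozen brute-force arithmetic: MSE = 0.5, Var = 5/3, 1 - 0.3 = 0.7
  expect_equal(performance(c(1, 1, 4, 4), c(1, 2, 3, 4)), 0.7)
  expect_error(performance(c(1, 2), c(3, 3)), "variance")
})

test_that("fitting a linear model recovers its own parameters", {
  ind <- load_preset("ind", n_neurons = 5)
  tr <- simulate_population(ind, 240, dt = 1, seed = 41,
                            keep_potentials = FALSE)
  truth <- linear_model(psp_weight = 0.8, decay = 35, baseline = -1)
  sig <- linear_response(tr$spikes, truth, 1, tr$duration_ms)$value
  f <- fit_model(linear_model(1, 10, 0), tr$spikes, sig, 1)
  expect_lt(abs(f$model$psp_weight - 0.8) / 0.8, 0.05)
  expect_lt(abs(f$model$decay - 35) / 35, 0.05)
  expect_lt(abs(f$model$baseline + 1), 0.05)
  expect_lt(f$train_error, 1e-6)
})

test_that("benchmark output has the contracted shape and is deterministic", {
  pop <- load_preset("fig4")
  res <- benchmark_models(pop, n_runs = 1, train_s = 10, test_s = 5,
                          dt = 1, dt_fit = 4, seed = 8, n_starts = 1)
  expect_setequal(res$model,
                  c("optimal", "linear", "somatic", "random", "clustered"))
  expect_equal(nrow(res), 5)
  expect_true(all(is.finite(res$performance)))
  res2 <- benchmark_models(pop, n_runs = 1, train_s = 10, test_s = 5,
                           dt = 1, dt_fit = 4, seed = 8, n_starts = 1)
  expect_equal(res$performance, res2$performance)
})

test_that("with a single independent assembly the linear model is optimal", {
  ind <- load_preset("ind", n_neurons = 6)
  tr <- simulate_population(ind, 60, dt = 0.5, seed = 47,
                            keep_potentials = FALSE)
  traj <- run_filter(tr$spikes, ind, dt = 0.5, duration_ms = tr$duration_ms)
  spikes_tr <- tr$spikes[tr$spikes$time_ms < 40000, ]
  f <- fit_model(linear_model(1, 20, 0), spikes_tr, traj$mean[1:80000], 0.5)
  lin <- linear_response(tr$spikes, f$model, 0.5, tr$duration_ms)
  te <- 80001:length(traj$mean)
  p_lin <- performance(lin$value[te], tr$signal[te])
  p_opt <- performance(traj$mean[te], tr$signal[te])
  expect_lt(abs(p_lin - p_opt), 0.02)
})
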