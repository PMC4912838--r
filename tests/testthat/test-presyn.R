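test_that("stationary state probability follows the two-state closed form", {
  expect_equal(stationary_state_prob(tiny_params(rate_to_active = 5,
                                                 rate_to_quiescent = 5)), 0.5)
  expect_equal(stationary_state_prob(tiny_params(rate_to_active = 0)), 0)
  expect_equal(stationary_state_prob(load_preset("NC")), 4 / 14)
  expect_error(stationary_state_prob(tiny_params(rate_to_active = 0,
                                                 rate_to_quiescent = 0)),
               "undefined")
})

test_that("state-conditioned expected rates reproduce the NC/HP values", {
  nc <- load_preset("NC")
  hp <- load_preset("HP")
  # frozen from the log-linear closed form g*exp(beta*mu + beta^2*var/2)
  expect_equal(expected_rate(10, 10, nc), exp(1.05), tolerance = 1e-12)
  expect_equal(round(expected_rate(10, 10, nc), 2), 2.86)
  expect_equal(round(expected_rate(-10, 10, nc), 2), 0.39)
  expect_equal(round(expected_rate(2.3, 1, hp), 1), 9.5)
  expect_equal(round(expected_rate(-2.3, 1, hp), 1), 0.6)
  b0 <- tiny_params(spiking_steepness = 0, rate_at_threshold = 7)
  expect_equal(expected_rate(c(-3, 0, 12), c(0, 5, 50), b0), rep(7, 3))
  expect_error(expected_rate(0, -1, nc), "non-negative")
})

test_that("process noise is 2*Sigma/tau and round-trips", {
  p <- tiny_params(stationary_cov = diag(2), time_constant = 20)
  Q <- process_noise(p)
  expect_equal(diag(Q), c(0.1, 0.1))
  expect_equal(Q * p$time_constant / 2, p$stationary_cov)
  p2 <- tiny_params()
  p2$stationary_cov[1, 2] <- 99 # break symmetry behind the constructor's back
  expect_error(process_noise(p2), "symmetric")
  p3 <- tiny_params()
  p3$stationary_cov <- matrix(c(1, 2, 2, 1), 2) # eigenvalues 3, -1
  expect_error(process_noise(p3), "semidefinite")
  expect_error(population_params(2, 1, 1, 1, 20, matrix(c(1, 2, 2, 1), 2),
                                 1, 1), "semidefinite")
})

test_that("switching dwell times match 1/Omega within Monte-Carlo error", {
  nc <- load_preset("NC")
  s <- switching_stats(nc, 3000, dt = 1, seed = 101)
  se_a <- 100 / sqrt(s$n_active_epochs)
  se_q <- 250 / sqrt(s$n_quiescent_epochs)
  expect_lt(abs(s$mean_active_ms - 100), 3 * se_a)
  expect_lt(abs(s$mean_quiescent_ms - 250), 3 * se_q)
  expect_lt(abs(s$active_occupancy - 4 / 14), 0.02)
})

test_that("absorbing quiescent state stays quiescent and dt guard fires", {
  p <- tiny_params(rate_to_active = 0)
  z <- simulate_switching(p, 1, dt = 0.5, seed = 1, init = 0L)
  expect_true(all(z == 0L))
  expect_error(simulate_switching(tiny_params(rate_to_quiescent = 500), 1,
                                  dt = 0.5), "too coarse")
})

test_that("clamped membrane statistics match the OU closed forms", {
  p <- tiny_params(n_neurons = 1, stationary_cov = matrix(2),
                   resting_half_gap = 3, time_constant = 20)
  T_s <- 200
  U <- simulate_membrane(rep(1L, T_s * 1e4), p, seed = 7, dt = 0.1)
  u <- U[1, ]
  se_mean <- sqrt(2 * 2 * 20 / (T_s * 1000)) # var of the time average ~ 2*Sigma*tau/T
  expect_lt(abs(mean(u) - 3), 3 * se_mean)
  expect_lt(abs(var(u) - 2) / 2, 0.05)
  lag <- 50 # 5 ms at dt = 0.1
  ac <- cor(u[-(1:lag)], u[seq_len(length(u) - lag)])
  expect_lt(abs(ac - exp(-5 / 20)), 0.02)
})

test_that("zero process noise gives deterministic exponential relaxation", {
  p <- tiny_params(n_neurons = 1, stationary_cov = matrix(0),
                   resting_half_gap = 2, time_constant = 10)
  U <- simulate_membrane(rep(1L, 500), p, seed = 1, dt = 0.1, u0 = 8)
  expected <- 2 + (8 - 2) * (1 - 0.1 / 10)^(0:499)
  expect_equal(U[1, ], expected, tolerance = 1e-12)
})

test_that("spiking respects the link function, refractoriness and thinning", {
  p <- tiny_params(n_neurons = 1, stationary_cov = matrix(1))
  U <- matrix(-1e6, 1, 1000)
  attr(U, "dt") <- 0.1
  expect_equal(nrow(simulate_spikes(U, p, seed = 1)), 0L)

  hp1 <- load_preset("HP", n_neurons = 1)
  hp1$release_prob <- 1
  T_s <- 1000
  U <- simulate_membrane(rep(1L, T_s * 1e4), hp1, seed = 5, dt = 0.1)
  sp <- simulate_spikes(U, hp1, seed = 6, dt = 0.1)
  expect_true(all(diff(sp$time_ms) >= hp1$refractory - 1e-9))
  # dead-time corrected rate gamma/(1 + gamma*tau_refr) for the renewal process
  gam <- expected_rate(2.3, 1, hp1)
  r_exp <- gam / (1 + gam * hp1$refractory / 1000)
  r_emp <- nrow(sp) / T_s
  expect_lt(abs(r_emp - r_exp), 3 * sqrt(r_exp / T_s))

  hp2 <- hp1
  hp2$release_prob <- 0.2
  sp2 <- simulate_spikes(U, hp2, seed = 6, dt = 0.1)
  r_tr <- sum(sp2$transmitted) / T_s
  expect_lt(abs(r_tr - 0.2 * r_exp), 3 * sqrt(0.2 * r_exp / T_s))
})

test_that("population simulation: group independence, occupancy, determinism", {
  pop <- assembly_population(list(load_preset("NC", n_neurons = 2),
                                  load_preset("NC", n_neurons = 2)))
  tr <- simulate_population(pop, 100, dt = 0.5, seed = 11,
                            keep_potentials = FALSE)
  occ <- rowMeans(tr$states)
  expect_lt(abs(mean(occ) - 100 / 350), 0.08)
  # spike-count correlation across groups over 250 ms windows
  bins <- seq(0, tr$duration_ms, by = 250)
  c1 <- table(cut(tr$spikes$time_ms[tr$spikes$neuron_id < 2], bins))
  c2 <- table(cut(tr$spikes$time_ms[tr$spikes$neuron_id >= 2], bins))
  r <- cor(as.numeric(c1), as.numeric(c2))
  expect_lt(abs(r), 3 / sqrt(length(bins) - 1))

  tr2 <- simulate_population(pop, 100, dt = 0.5, seed = 11,
                             keep_potentials = FALSE)
  expect_identical(tr$spikes, tr2$spikes)
  expect_identical(tr$states, tr2$states)
  expect_identical(tr$signal, tr2$signal)
})

test_that("equicorrelated constructor enforces the rho lower bound", {
  expect_error(equicorr_cov(10, 1, -1 / 9 - 1e-6), "-1/\\(N-1\\)|>=")
  S <- equicorr_cov(10, 1, -1 / 9) # boundary: PSD but singular
  expect_silent(optidend:::.check_cov(S))
  expect_equal(equicorr_cov(3, 2, 0.5)[1, 2], 1)
})

test_that("presets carry the documented parameters and reject unknowns", {
  hp <- load_preset("HP")
  expect_equal(hp$rate_at_threshold, 2)
  expect_equal(hp$spiking_steepness, 0.6)
  nc <- load_preset("NC")
  expect_equal(2 * nc$resting_half_gap, 20) # active-quiescent gap, mV
  expect_equal(nc$stationary_cov[1, 2], 5)
  f4 <- load_preset("fig4")
  expect_s3_class(f4, "assembly_population")
  expect_equal(f4$n_neurons, 40L)
  f1 <- load_preset("fig1bc")
  expect_length(f1$groups, 20)
  err <- tryCatch(load_preset("XYZ"), error = conditionMessage)
  expect_match(err, "NC")
  expect_match(err, "HP")
  expect_match(err, "cor2")
})
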