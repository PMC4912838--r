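# shared test utilities; all fixtures are built in code

# peak deviation of the optimal voltage response from its pre-stimulus value
response_amplitude <- function(spikes, pop, dt = 0.1, duration_ms = 200,
                               tau_post = 0) {
  traj <- run_filter(spikes, pop, dt = dt, duration_ms = duration_ms)
  v <- optimal_response(traj, tau_post)$value
  max(v - v[1])
}

spikes_df <- function(neuron_id, time_ms) {
  data.frame(neuron_id = as.integer(neuron_id), time_ms = time_ms)
}

no_spikes <- spikes_df(integer(0), numeric(0))

# a small two-neuron group with gentle dynamics for fast exact tests
tiny_params <- function(...) {
  args <- list(n_neurons = 2, rate_to_active = 5, rate_to_quiescent = 10,
               resting_half_gap = 2, time_constant = 20,
               stationary_cov = equicorr_cov(2, 1, 0.3),
               rate_at_threshold = 5, spiking_steepness = 0.5,
               refractory = 2, release_prob = 1)
  args[names(list(...))] <- list(...)
  do.call(population_params, args)
}

single_group_presets <- c("NC", "HP", "ind", "cor2", "fig2ab", "fig2cd",
                          "fig3a", "fig3b", "fig2s1")
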