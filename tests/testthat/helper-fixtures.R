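# Small simulation configurations used across the test files. Short
# recordings keep the suite fast; the full-length protocol is exercised in
# the acceptance tests.

# Noiseless short paced recording; grid-aligned rise (frame_rate 100,
# stim_start 1 s, time_to_peak 0.05 s) so transient apexes fall exactly on
# sample times.
quiet_cfg <- function(...) {
  args <- list(...)
  defaults <- list(frame_rate = 100, pacing_freq = 0.5, paced_duration = 20,
                   pause_duration = 6, caffeine_tail = 10,
                   amplitude_mean = 1.0, amplitude_cv = 0, time_to_peak = 0.05,
                   k_serca = 3.5, k_ncx = 1.5, caffeine_amplitude = 1.4,
                   f0_baseline = 500, background_level = 100, noise_sd = 0,
                   stim_start = 1, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Noisy short recording at a given dF/F0-scale SNR.
noisy_cfg <- function(snr = 20, ...) {
  quiet_cfg(noise_sd = 500 * 1.0 / snr, amplitude_cv = 0.1, ...)
}

default_params <- function(...) {
  args <- list(...)
  defaults <- list(min_spikes = 5L, rng_seed = 1L)
  do.call(analysis_params, utils::modifyList(defaults, args))
}

# dF/F0 trace of a simulated cell, via the standard pipeline steps.
sim_ntrace <- function(cfg) {
  sim <- simulate_trace(cfg)
  tr <- subtract_background(sim$trace)
  list(ntrace = normalize_trace(tr), truth = sim$truth, trace = tr)
}
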