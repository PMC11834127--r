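# Shared fixture builders. All cohorts are generated in code at test time.

# zero-noise, no incidental events: downstream measurements must equal
# generator truth up to numerical error
quiet_config <- function(n_participants = 2, trials_per_cell = 2,
                         seed = 11, ...) {
  simulation_config(
    n_participants = n_participants, trials_per_cell = trials_per_cell,
    asem_trial_sd = 0, noise_sd_eye = 0, noise_sd_cursor = 0,
    saccade_rate = 0, blink_prob = 0,
    latency_population = list(c = c(0, 0), mu = c(0, 0), sigma = c(0.3, 0),
                              beta0 = c(0.315, 0.04),
                              beta1 = c(-0.03, 0.01), resid_sd = 0),
    seed = seed, ...)
}

small_noisy_config <- function(n_participants = 3, trials_per_cell = 3,
                               seed = 21, ...) {
  simulation_config(n_participants = n_participants,
                    trials_per_cell = trials_per_cell, seed = seed, ...)
}

# synthetic pursuit trace (deg) at 1 kHz: fixation then constant-velocity
# pursuit, optionally with injected saccades
pursuit_trace <- function(duration = 2, rate = 1000, velocity = 8,
                          onset = 0.8) {
  t <- seq(0, duration, by = 1 / rate)
  v <- ifelse(t < onset, 0, velocity)
  list(time = t, x = cumsum(v) / rate, rate = rate)
}

trial_id_chr <- function(participant, trial)
  sprintf("%s_t%03d", participant, trial)

# per-sample threshold-scan oracle for saccade labels: the strict joint
# criterion at each sample, independent of interval logic
saccade_label_oracle <- function(velocity, acceleration,
                                 vel_threshold = 30,
                                 acc_threshold = 1000) {
  velocity > vel_threshold & abs(acceleration) > acc_threshold
}
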