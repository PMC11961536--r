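# Shared fixtures, built in code.

# Noise-free parameters for a given scenario/titer.
quiet_params <- function(scenario = "control", titer = NULL, ...) {
  sim_params(scenario, titer = titer, noise_sd_f = 0, noise_sd_D = 0, ...)
}

# A tiny hand-built experiment on an explicit grid, for boundary-convention
# and accessor tests. Values are simple functions of time.
toy_experiment <- function(tmax = 400, dt = 10) {
  grid <- seq(0, tmax, by = dt)
  sch <- default_schedule()
  traces <- lapply(c(3L, 5L, 7L, 9L, 11L), function(n) {
    overtone_trace(n, grid,
                   delta_f = -n * grid / tmax,
                   delta_D = (12 - n) * grid / tmax)
  })
  qcmd_experiment(traces, sch, sensor_id = "toy")
}

# Random valid film states for property loops.
random_film_states <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    film_state(thickness = runif(1, 0, 400),
               softness = runif(1, 0.05, 1),
               rigid_mass = runif(1, 0, 500),
               coverage = runif(1, 0.05, 1),
               resonance_sign = sample(c(-1, 1), 1))
  })
}
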