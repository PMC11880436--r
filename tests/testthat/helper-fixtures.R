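# Shared fixtures: small, fast objects reused across test files.

fix_biphasic <- function(tau_K = 0.01, target_area = 0, dt = 5e-4) {
  make_biphasic_kernel(tau_K, target_area, dt = dt)
}

fix_protocol <- function(A = 1, s_mean = 0, tau_f = 0.1, tau_s = 1,
                         dt = 5e-4) {
  sawtooth_protocol(A, s_mean, tau_f, tau_s, dt = dt)
}

fix_tiny_net <- function(seed = 3L) {
  energy_network(4, 3, 2, seed = seed)
}

fix_toy_setup <- function(seed = 42L) {
  task <- generate_toy_task(seed = seed)
  list(
    task = task,
    train = task_matrices(task, "train"),
    test = task_matrices(task, "test"),
    kernel = make_sine_kernel(0.02, dt = 0.002, unit_gain = TRUE),
    schedule = nudge_schedule(beta_max = 0.5, tau_f = 0.1, tau_s = 0.9,
                              steps_per_cycle = 60L)
  )
}
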