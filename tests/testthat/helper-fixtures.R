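# Shared fixtures: the reference band-pass / low-pass controllers and small
# simulation configurations used across test files.

ref_bandpass <- function(A = 16, omega1 = 0.02, omega2 = 5, ...) {
  controller_filter("band_pass", A = A, omega1 = omega1, omega2 = omega2, ...)
}

ref_lowpass <- function(A = 64, omega0 = 5, ...) {
  controller_filter("low_pass", A = A, omega0 = omega0, ...)
}

# Closed-form step response of the rank-2 band-pass filter (attractant sign):
# deviation(t) = -step * K * (exp(-w1 t) - exp(-w2 t)) / (w2 - w1).
bandpass_step_closed_form <- function(t, step, A, omega1, omega2) {
  K <- A * (omega1 + omega2)
  -step * K * (exp(-omega1 * t) - exp(-omega2 * t)) / (omega2 - omega1)
}

quick_config <- function(controller, n = 50, duration = 100, seed = 1, ...) {
  simulation_config(controller, n_bacteria = n, duration = duration,
                    seed = seed, ...)
}
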