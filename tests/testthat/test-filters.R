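test_that("low-pass controller has the first-order lag form", {
  lp <- make_lowpass(64, 5)
  expect_equal(tf_dcgain(lp), 64)
  expect_equal(Mod(tf_eval(lp, 1i * 5)), 64 / sqrt(2), tolerance = 1e-12)
  expect_equal(Mod(tf_eval(lp, 1i * 50)), 64 * 5 / sqrt(2525), tolerance = 1e-12)
  expect_error(make_lowpass(64, 0), "omega0")
})

test_that("band-pass controllers are peak-normalised with zero DC gain", {
  bp <- make_bandpass(16, 0.02, 5)
  expect_equal(tf_dcgain(bp), 0)
  expect_equal(Mod(tf_eval(bp, 1i * sqrt(0.02 * 5))), 16, tolerance = 1e-12)
  bp4 <- make_bandpass(16, 0.02, 5, rank = 4)
  expect_equal(tf_dcgain(bp4), 0)
  expect_equal(Mod(tf_eval(bp4, 1i * sqrt(0.02 * 5))), 16, tolerance = 1e-9)
  expect_error(make_bandpass(16, 5, 0.02), "omega1")

  # low-frequency asymptote: +20 dB/decade for rank 2, +40 for rank 4
  w <- 10^seq(-4, -3, length.out = 20)
  slope2 <- stats::coef(stats::lm(freq_response(bp, w)$magnitude_db ~ log10(w)))[2]
  slope4 <- stats::coef(stats::lm(freq_response(bp4, w)$magnitude_db ~ log10(w)))[2]
  expect_equal(unname(slope2), 20, tolerance = 0.01)
  expect_equal(unname(slope4), 40, tolerance = 0.01)
})

test_that("gain normalization holds across the cut-off grid", {
  for (w1 in 10^seq(log10(1e-3), log10(0.3), length.out = 4)) {
    for (w2 in 10^seq(log10(0.3), log10(100), length.out = 4)) {
      if (w2 <= w1) next
      for (rk in c(2, 4)) {
        pk <- tf_peak_gain(make_bandpass(7, w1, w2, rank = rk))
        expect_equal(pk$peak, 7, tolerance = 1e-6)
        expect_equal(pk$omega_peak, sqrt(w1 * w2), tolerance = 1e-4)
      }
    }
  }
})

test_that("zero-order-hold stepping is exact for piecewise-constant input", {
  A <- 16; w1 <- 0.02; w2 <- 5
  cf <- ref_bandpass(A, w1, w2)
  dt <- 0.5
  n <- 400
  out <- numeric(n)
  for (k in seq_len(n)) {
    cf <- lti_step_update(cf, -0.1, dt)
    out[k] <- cf$output
  }
  expect_equal(out, bandpass_step_closed_form(seq_len(n) * dt, -0.1, A, w1, w2),
               tolerance = 1e-10)
})

test_that("constant inputs drive band-pass output to zero and low-pass to its DC gain", {
  cf <- ref_bandpass()
  for (k in seq_len(ceiling(10 / 0.02 / 0.5))) cf <- lti_step_update(cf, 0.3, 0.5)
  expect_lt(abs(cf$output), 1e-4 * cf$A)
  lp <- ref_lowpass(A = 64, omega0 = 5)
  for (k in seq_len(100)) lp <- lti_step_update(lp, 0.01, 0.5)  # 50 s >> 10/omega0
  expect_equal(lp$output, -64 * 0.01, tolerance = 1e-6)  # attractant sign: subtracted
})

test_that("sinusoidal drive reproduces the frequency response amplitude", {
  A <- 16; w1 <- 0.02; w2 <- 5
  w <- sqrt(w1 * w2)
  cf <- ref_bandpass(A, w1, w2)
  dt <- 0.05
  t_settle <- 400
  period <- 2 * pi / w
  n <- ceiling((t_settle + 2 * period) / dt)
  out <- numeric(n)
  for (k in seq_len(n)) {
    cf <- lti_step_update(cf, 0.01 * sin(w * k * dt), dt)
    out[k] <- cf$output
  }
  steady <- out[seq_len(n) * dt > t_settle]
  expect_equal(max(abs(steady)), A * 0.01, tolerance = 0.01)
})

test_that("step response matches the double-exponential closed form", {
  cf <- ref_bandpass()
  traj <- step_response(cf, step = -0.1, T = 200, dt = 0.01)
  expect_equal(traj$deviation_um[1], 0)
  expect_equal(traj$deviation_um,
               bandpass_step_closed_form(traj$time_s, -0.1, 16, 0.02, 5),
               tolerance = 1e-8)
  # attractant removal raises CheY-P
  expect_gt(max(traj$deviation_um), 0)
  # peak time at the stationary point of the double exponential
  tm <- timing_summary(traj)
  expect_equal(tm$peak_time_s, log(5 / 0.02) / (5 - 0.02), tolerance = 0.01)
})

test_that("adaptation time is governed by the down cut-off frequency", {
  tau_of <- function(w1, w2) {
    traj <- step_response(controller_filter("band_pass", A = 16, omega1 = w1,
                                            omega2 = w2),
                          step = -0.1, T = 30 / w1, dt = min(0.02 / w2, 0.5 / w1))
    timing_summary(traj)
  }
  sums <- lapply(c(1, 10, 100), function(w2) tau_of(0.02, w2))
  taus <- vapply(sums, function(s) s$tau1_s, numeric(1))
  # stimulus-referenced tau1 carries the peak-time shift at small omega2, so
  # allow 15%; the decay phase itself (peak to half) is governed by omega1
  # alone to within 10%
  expect_lt(diff(range(taus)) / mean(taus), 0.15)
  decay <- taus - vapply(sums, function(s) s$peak_time_s, numeric(1))
  expect_lt(diff(range(decay)) / mean(decay), 0.10)
  # near-symmetric filter: both times scale as 1/omega1
  s1 <- tau_of(0.1, 0.100001)
  s2 <- tau_of(0.2, 0.200002)
  expect_equal(s1$tau1_s / s2$tau1_s, 2, tolerance = 1e-3)
  expect_equal(s1$tau2_s / s2$tau2_s, 2, tolerance = 1e-3)
  # too-short trajectory cannot yield an adaptation time
  short <- step_response(ref_bandpass(), step = -0.1, T = 5, dt = 0.01)
  expect_error(timing_summary(short), "decayed")
})
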