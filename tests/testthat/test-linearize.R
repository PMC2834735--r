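test_that("find_equilibrium matches closed forms", {
  pos <- designed_pathway("positive")
  eq <- find_equilibrium(as_pathway_model(pos), 0.5, guess = c(1, 1))
  expect_equal(eq, unname(designed_equilibrium(0.5, pos)), tolerance = 1e-9)

  lin <- pathway_model(deriv = function(x, u) -x + u,
                       output = function(x, u) x, state_dim = 1)
  expect_equal(find_equilibrium(lin, 1), 1, tolerance = 1e-10)

  pse <- designed_pathway("pseudo")
  eq0 <- find_equilibrium(as_pathway_model(pse), 0, guess = c(0.5, 3))
  expect_equal(eq0[2], pse$Y_T, tolerance = 1e-8)  # pure autophosphorylation
})

test_that("linearization reproduces the analytic Jacobians of the positive pathway", {
  p <- designed_pathway("positive")
  u0 <- 0.5
  eq <- designed_equilibrium(u0, p)
  ssm <- linearize_model(as_pathway_model(p), u0, guess = eq)
  A_exact <- rbind(c(-p$d_v, 0),
                   c(p$k_phos * (p$Y_T - eq[["y"]]),
                     -(p$k_phos * eq[["v"]] + p$k_dephos * u0)))
  B_exact <- c(p$c_v, -p$k_dephos * eq[["y"]])
  expect_equal(unname(ssm$A), unname(A_exact), tolerance = 1e-6)
  expect_equal(drop(ssm$B), B_exact, tolerance = 1e-6)
  expect_equal(drop(ssm$C), c(0, 1), tolerance = 1e-9)
  expect_equal(ssm$D, 0, tolerance = 1e-9)
  # linearizing an already-linear system returns its own matrices
  A0 <- matrix(c(-1, 0.5, 0, -2), 2, 2)
  B0 <- c(1, 0.3)
  linmod <- pathway_model(deriv = function(x, u) drop(A0 %*% x) + B0 * u,
                          output = function(x, u) x[1] + 2 * x[2],
                          state_dim = 2)
  ssl <- linearize_model(linmod, 0.7)
  expect_equal(unname(ssl$A), unname(A0), tolerance = 1e-8)
  expect_equal(drop(ssl$B), B0, tolerance = 1e-8)
})

test_that("transfer functions: zero DC gain for the adaptive design, nonzero for pseudo", {
  pos <- designed_pathway("positive")
  tf_pos <- transfer_function(linearize_model(as_pathway_model(pos), 0.5))
  pk <- tf_peak_gain(tf_pos)
  expect_lt(abs(tf_dcgain(tf_pos)), 1e-9 * pk$peak)

  # scalar low-pass realization dx/dt = -w0 x + A w0 u, y = x
  A_amp <- 3; w0 <- 0.8
  sc <- pathway_model(deriv = function(x, u) -w0 * x + A_amp * w0 * u,
                      output = function(x, u) x, state_dim = 1)
  tf_sc <- transfer_function(linearize_model(sc, 0.4))
  expect_equal(tf_sc$num, A_amp * w0, tolerance = 1e-8)
  expect_equal(tf_sc$den, c(1, w0), tolerance = 1e-8)

  # pseudo: H(0) equals the slope of the equilibrium output in the input
  pse <- as_pathway_model(designed_pathway("pseudo"))
  tf_pse <- transfer_function(linearize_model(pse, 0.5))
  h <- 1e-4
  slope <- (find_equilibrium(pse, 0.5 + h, guess = c(2.5, 2.7))[2] -
            find_equilibrium(pse, 0.5 - h, guess = c(2.5, 2.7))[2]) / (2 * h)
  expect_gt(abs(tf_dcgain(tf_pse)), 0)
  expect_equal(tf_dcgain(tf_pse), slope, tolerance = 1e-4)
})

test_that("DC-gain identity: H(0) equals the equilibrium input-output slope for every model", {
  models <- list(
    positive = designed_pathway("positive"),
    negative = designed_pathway("negative"),
    pseudo = designed_pathway("pseudo"),
    universal = universal_pathway(y_t = c(4, 6),
                                  C = matrix(c(0, 0.5, 0, 0), 2, 2),
                                  C_u = c(0.3, 0), C_self = c(0.01, 0.2),
                                  D_self = c(0.05, 0.1), D_u = c(0, 0.4))
  )
  for (nm in names(models)) {
    m <- as_pathway_model(models[[nm]])
    u0 <- 0.4
    x0 <- find_equilibrium(m, u0, guess = rep(1, m$state_dim))
    tf <- transfer_function(linearize_model(m, u0, guess = x0))
    h <- 1e-4
    y_hi <- m$output(find_equilibrium(m, u0 + h, guess = x0), u0 + h)
    y_lo <- m$output(find_equilibrium(m, u0 - h, guess = x0), u0 - h)
    slope <- (y_hi - y_lo) / (2 * h)
    scale <- max(abs(slope), tf_peak_gain(tf)$peak)
    expect_lt(abs(tf_dcgain(tf) - slope), 1e-4 * scale)
  }
})

test_that("frequency response values and sentinels are correct", {
  bp <- make_bandpass(16, 0.02, 5)
  fr <- freq_response(bp, sqrt(0.02 * 5))
  expect_equal(fr$magnitude_db, 20 * log10(16), tolerance = 1e-9)
  lp <- make_lowpass(64, 5)
  fr0 <- freq_response(lp, 5)
  expect_equal(fr0$magnitude_db, 20 * log10(64 / sqrt(2)), tolerance = 1e-9)
  expect_equal(fr0$phase_deg, -45, tolerance = 1e-9)
  # differentiator numerator: +90 degree phase lead at low frequency
  expect_equal(freq_response(bp, 1e-8)$phase_deg, 90, tolerance = 1e-3)
  expect_equal(freq_response(bp, 0)$magnitude_db, -Inf)
  bt <- bode_table(bp)
  expect_true(all(diff(bt$phase_deg) < 180))  # unwrapped
})

test_that("freq_response agrees with an independent LTI oracle", {
  skip_if_not_installed("signal")
  bp <- make_bandpass(16, 0.02, 5)
  w <- 10^seq(-3, 2, length.out = 30)
  ours <- Mod(tf_eval(bp, 1i * w))
  oracle <- Mod(signal::freqs(bp$num, bp$den, W = w)$H)
  expect_equal(ours, oracle, tolerance = 1e-10)
})

test_that("filter classification separates adaptive, non-adaptive and degenerate systems", {
  pos_tf <- transfer_function(linearize_model(as_pathway_model(designed_pathway("positive")), 0.5))
  pse_tf <- transfer_function(linearize_model(as_pathway_model(designed_pathway("pseudo")), 0.5))
  expect_identical(classify_filter(pos_tf), "band_pass")
  expect_identical(classify_filter(pse_tf), "low_pass")
  expect_identical(classify_filter(transfer_fn(5, 1)), "other")
  expect_identical(classify_filter(make_lowpass(64, 5)), "low_pass")
  expect_identical(classify_filter(make_bandpass(16, 0.02, 5, rank = 4)), "band_pass")
  expect_error(classify_filter(transfer_fn(1, c(1, -1))), "stable")
})

test_that("all default parameterizations are stable and the linearization is faithful", {
  for (variant in c("positive", "negative", "pseudo")) {
    tf <- transfer_function(linearize_model(as_pathway_model(designed_pathway(variant)), 0.5))
    expect_true(all(Re(tf_poles(tf)) < 0))
  }
  # +/- 1% occupancy step: nonlinear vs linearized trajectory within 2% of
  # the response amplitude over 500 s
  p <- designed_pathway("positive")
  u0 <- 0.5
  eq <- designed_equilibrium(u0, p)
  ssm <- linearize_model(as_pathway_model(p), u0, guess = eq)
  for (delta in c(0.01, -0.01)) {
    dt <- 0.1
    n_step <- 5000
    d <- bactaxis:::zoh_discretize(ssm, dt)
    xl <- c(0, 0)
    lin <- numeric(n_step)
    v <- eq[["v"]]; y <- eq[["y"]]
    nl <- numeric(n_step)
    for (k in seq_len(n_step)) {
      xl <- drop(d$Ad %*% xl) + drop(d$Bd) * delta
      lin[k] <- drop(d$C %*% xl)
      st <- bactaxis:::rk4_designed(v, y, u0 + delta, p, dt, 2)
      v <- st$v; y <- st$y
      nl[k] <- y - eq[["y"]]
    }
    amp <- max(abs(nl))
    expect_gt(amp, 0)
    expect_lt(max(abs(nl - lin)), 0.02 * amp)
  }
})
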