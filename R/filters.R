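# Canonical controller filters: first-order low-pass and differentiator-plus-
# two-lags band-pass transfer functions, exact zero-order-hold time stepping,
# and step-response timing (adaptation and response times).

#' First-order low-pass controller transfer function
#'
#' `H(s) = A w0 / (s + w0)`: a single inertia link. DC gain `A`, corner at
#' `w0`, -20 dB/decade roll-off above it. Models a non-adaptive pathway whose
#' steady-state CheY-P tracks the input occupancy level.
#'
#' @param A Maximum amplification (uM of CheY-P deviation per unit occupancy).
#' @param omega0 Cut-off angular frequency (1/s), positive.
#' @return A [transfer_fn()].
#' @export
make_lowpass <- function(A, omega0) {
  if (A < 0) stop("A must be >= 0")
  if (omega0 <= 0) stop("omega0 must be > 0")
  transfer_fn(c(A * omega0), c(1, omega0))
}

#' Band-pass controller transfer function
#'
#' Rank 2: `H(s) = K s / ((s + w1)(s + w2))` with `K = A (w1 + w2)`, so the
#' Bode magnitude peaks at exactly `A` at `w = sqrt(w1 w2)`. Rank 4 squares
#' both the differentiator and the two lags,
#' `H(s) = K4 s^2 / ((s + w1)^2 (s + w2)^2)` with `K4 = A (w1 + w2)^2`,
#' sharing max amplification and cut-off frequencies with the rank-2 form.
#' In both cases `H(0) = 0`: the controller differentiates slow signals and
#' is therefore perfectly adapting.
#'
#' @param A Maximum amplification (peak Bode magnitude, uM per unit occupancy).
#' @param omega1 Down (slow) cut-off angular frequency (1/s).
#' @param omega2 Up (fast) cut-off angular frequency (1/s); `omega1 < omega2`.
#' @param rank 2 or 4.
#' @return A [transfer_fn()].
#' @export
make_bandpass <- function(A, omega1, omega2, rank = 2) {
  if (A < 0) stop("A must be >= 0")
  if (!(omega1 > 0 && omega2 > omega1)) stop("need 0 < omega1 < omega2")
  if (rank == 2) {
    K <- A * (omega1 + omega2)
    transfer_fn(c(K, 0), c(1, omega1 + omega2, omega1 * omega2))
  } else if (rank == 4) {
    K4 <- A * (omega1 + omega2)^2
    den <- pracma::polymul(pracma::polymul(c(1, omega1), c(1, omega1)),
                           pracma::polymul(c(1, omega2), c(1, omega2)))
    transfer_fn(c(K4, 0, 0), den)
  } else stop("rank must be 2 or 4")
}

# Controllable-canonical state-space realization of a transfer function.
tf_to_ss <- function(tf) {
  n <- length(tf$den) - 1
  if (n == 0) return(state_space_model(matrix(0, 0, 0), matrix(0, 0, 1),
                                       matrix(0, 1, 0), D = tf$num[1]))
  b <- c(rep(0, length(tf$den) - length(tf$num)), tf$num)  # pad to n + 1
  a <- tf$den[-1]
  D <- b[1]
  A <- rbind(-a, cbind(diag(1, n - 1, n - 1), rep(0, n - 1)))
  if (n == 1) A <- matrix(-a, 1, 1)
  B <- matrix(c(1, rep(0, n - 1)), n, 1)
  C <- matrix(b[-1] - a * D, 1, n)
  state_space_model(A, B, C, D)
}

# Exact zero-order-hold discretization: x[k+1] = Ad x[k] + Bd u[k].
zoh_discretize <- function(ss, dt) {
  n <- nrow(ss$A)
  if (n == 0) return(list(Ad = ss$A, Bd = ss$B, C = ss$C, D = ss$D))
  M <- rbind(cbind(ss$A, ss$B), matrix(0, 1, n + 1)) * dt
  E <- as.matrix(Matrix::expm(M))
  list(Ad = E[1:n, 1:n, drop = FALSE], Bd = E[1:n, n + 1, drop = FALSE],
       C = ss$C, D = ss$D)
}

#' Controller filter with internal LTI state
#'
#' Bundles a low-pass or band-pass transfer function with its
#' controllable-canonical state-space realization, an internal state vector
#' for time stepping, an output-sign convention and the CheY-P baseline.
#' With the attractant convention a rise in occupancy lowers CheY-P (more
#' running up-gradient); the repellent convention flips the sign.
#'
#' @param kind `"low_pass"` or `"band_pass"`.
#' @param A Maximum amplification (uM per unit occupancy).
#' @param omega0 Low-pass cut-off (1/s); required for `kind = "low_pass"`.
#' @param omega1,omega2 Band-pass cut-offs (1/s); required for band-pass.
#' @param rank Band-pass rank, 2 (default) or 4.
#' @param sign `"attractant"` or `"repellent"` output-sign convention.
#' @param baseline CheY-P baseline (uM, default 2.71, i.e. 20% CW bias).
#' @return Object of class `"controller_filter"` with fields `tf`, `ss`,
#'   `state`, `output` (last output deviation, uM) and the parameters.
#' @export
controller_filter <- function(kind = c("band_pass", "low_pass"), A = 16,
                              omega0 = NULL, omega1 = NULL, omega2 = NULL,
                              rank = 2, sign = c("attractant", "repellent"),
                              baseline = 2.71) {
  kind <- match.arg(kind)
  sign <- match.arg(sign)
  tf <- if (kind == "low_pass") {
    if (is.null(omega0)) stop("low_pass filter requires omega0")
    make_lowpass(A, omega0)
  } else {
    if (is.null(omega1) || is.null(omega2)) stop("band_pass filter requires omega1 and omega2")
    make_bandpass(A, omega1, omega2, rank)
  }
  ss <- tf_to_ss(tf)
  structure(list(kind = kind, A = A, omega0 = omega0, omega1 = omega1,
                 omega2 = omega2, rank = rank, sign = sign,
                 baseline = baseline, tf = tf, ss = ss,
                 state = rep(0, nrow(ss$A)), output = 0),
            class = "controller_filter")
}

# Sign multiplier applied to the raw filter response before it is added to
# the CheY-P baseline.
controller_sign_factor <- function(cf) if (cf$sign == "attractant") -1 else 1

#' Advance a controller filter by one time step
#'
#' Exact zero-order-hold update of the filter state over `dt` with the input
#' held constant: for a linear time-invariant system driven by piecewise-
#' constant input this discretization is exact, with no integration error.
#' The input is the occupancy deviation from the filter's reference (for
#' band-pass filters the reference is immaterial since `H(0) = 0`).
#'
#' @param filter A [controller_filter()].
#' @param input Occupancy (deviation) held constant over the step.
#' @param dt Step length (s), positive.
#' @return The filter with updated `state`, `output` (signed CheY-P deviation,
#'   uM) and `cheyp` (baseline + output, clipped below at 0).
#' @export
lti_step_update <- function(filter, input, dt) {
  stopifnot(inherits(filter, "controller_filter"), dt > 0)
  if (is.null(filter$disc) || !identical(filter$disc_dt, dt)) {
    filter$disc <- zoh_discretize(filter$ss, dt)
    filter$disc_dt <- dt
  }
  d <- filter$disc
  x_new <- drop(d$Ad %*% filter$state) + drop(d$Bd) * input
  filter$state <- x_new
  filter$output <- controller_sign_factor(filter) *
    (drop(d$C %*% x_new) + d$D * input)
  filter$cheyp <- max(filter$baseline + filter$output, 0)
  filter
}

#' Step response of a controller filter
#'
#' Response of the filter to a step in receptor occupancy applied at `t = 0`
#' (state initially at rest, i.e. adapted). Computed by exact zero-order-hold
#' stepping, which for a constant input reproduces the continuous-time
#' response at every sample. The returned deviation carries the filter's
#' sign convention: with the attractant convention a downward occupancy step
#' (attractant removal) produces a positive CheY-P deviation.
#'
#' @param filter A [controller_filter()].
#' @param step Occupancy jump (signed; e.g. `-0.1` for attractant removal).
#' @param T Duration (s).
#' @param dt Sample interval (s, default 0.01 for sharp timing resolution).
#' @return Data frame with columns `time_s`, `deviation_um` (signed CheY-P
#'   deviation) and `cheyp_um` (baseline + deviation, clipped at 0).
#' @export
step_response <- function(filter, step, T, dt = 0.01) {
  stopifnot(inherits(filter, "controller_filter"), T > 0, dt > 0)
  d <- zoh_discretize(filter$ss, dt)
  nstep <- ceiling(T / dt)
  x <- rep(0, nrow(filter$ss$A))
  dev <- numeric(nstep + 1)
  dev[1] <- controller_sign_factor(filter) * d$D * step
  for (k in seq_len(nstep)) {
    x <- drop(d$Ad %*% x) + drop(d$Bd) * step
    dev[k + 1] <- controller_sign_factor(filter) * (drop(d$C %*% x) + d$D * step)
  }
  t <- seq(0, nstep) * dt
  data.frame(time_s = t, deviation_um = dev,
             cheyp_um = pmax(filter$baseline + dev, 0))
}

#' Timing summary of a step response
#'
#' Locates the dominant peak of the deviation and measures, from the stimulus
#' at `t = 0`:
#' \describe{
#'   \item{response time `tau2`}{time at which the deviation first reaches
#'     half of its peak on the rising side;}
#'   \item{adaptation time `tau1`}{time at which the deviation has decayed
#'     back to half of its peak on the falling side.}
#' }
#' Crossings are located by linear interpolation between samples. For a
#' band-pass filter with `w1 << w2`, `tau2 ~ log(2)/w2` is fast and
#' `tau1 ~ log(2)/w1` is slow, so `tau1 >> tau2`.
#'
#' @param traj A step-response data frame from [step_response()] (columns
#'   `time_s` and `deviation_um`).
#' @return Object of class `"step_response_summary"`: list with `tau1_s`,
#'   `tau2_s`, `peak_um` (signed peak deviation) and `peak_time_s`.
#' @export
timing_summary <- function(traj) {
  t <- traj$time_s
  y <- traj$deviation_um
  s <- sign(y[which.max(abs(y))])
  y <- y * s                                  # analyse the dominant lobe as positive
  k <- which.max(y)
  peak <- y[k]
  if (peak <= 0) stop("no positive peak in step response")
  half <- peak / 2
  cross_time <- function(idx) {
    i <- idx[1]
    if (i == 1) return(t[1])
    t[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  rise <- which(y[seq_len(k)] >= half)
  if (length(rise) == 0) stop("no rising half-peak crossing found")
  tau2 <- cross_time(rise)
  after <- which(y >= half)
  j <- after[length(after)]                   # last sample still above half
  if (j >= length(t))
    stop("trajectory too short: deviation has not decayed to half peak")
  tau1 <- t[j] + (y[j] - half) / (y[j] - y[j + 1]) * (t[j + 1] - t[j])
  structure(list(tau1_s = tau1, tau2_s = tau2, peak_um = s * peak,
                 peak_time_s = t[k]),
            class = "step_response_summary")
}

#' @export
print.step_response_summary <- function(x, ...) {
  cat(sprintf("step response: peak %.4g uM at %.4g s; tau2 (response) %.4g s; tau1 (adaptation) %.4g s\n",
              x$peak_um, x$peak_time_s, x$tau2_s, x$tau1_s))
  invisible(x)
}
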