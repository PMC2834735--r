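# Equilibrium finding, state-space linearization, rational transfer functions
# and Bode (frequency-domain) analysis.

#' Rational transfer function
#'
#' Single-input single-output transfer function `H(s) = num(s) / den(s)` with
#' real polynomial coefficients stored in descending powers of `s`. The
#' denominator is normalised to be monic and leading zero coefficients are
#' trimmed.
#'
#' @param num,den Numeric coefficient vectors, descending powers of `s`.
#' @return Object of class `"transfer_fn"` with fields `num`, `den`.
#' @export
transfer_fn <- function(num, den) {
  trim <- function(p) {
    i <- which(abs(p) > 0)
    if (length(i) == 0) return(0)
    p[i[1]:length(p)]
  }
  den <- trim(den)
  if (length(den) == 1 && den[1] == 0) stop("denominator is identically zero")
  num <- trim(num / den[1])
  den <- den / den[1]
  if (length(num) > length(den))
    stop("improper transfer function: numerator degree exceeds denominator degree")
  structure(list(num = num, den = den), class = "transfer_fn")
}

#' @export
print.transfer_fn <- function(x, ...) {
  fmt <- function(p) {
    n <- length(p) - 1
    terms <- mapply(function(c, k) {
      if (c == 0) return(NA_character_)
      co <- formatC(c, digits = 6, format = "g")
      if (k == 0) co else if (k == 1) paste0(co, " s") else paste0(co, " s^", k)
    }, p, rev(seq_along(p)) - 1)
    terms <- terms[!is.na(terms)]
    if (length(terms) == 0) "0" else paste(terms, collapse = " + ")
  }
  cat("H(s) = (", fmt(x$num), ") / (", fmt(x$den), ")\n", sep = "")
  invisible(x)
}

#' Evaluate a transfer function at complex frequencies
#'
#' @param tf A [transfer_fn()].
#' @param s Complex (or real) scalar/vector of Laplace-variable values.
#' @return Complex vector `H(s)`.
#' @export
tf_eval <- function(tf, s) {
  polyv <- function(p, x) {
    acc <- rep(0 + 0i, length(x))
    for (c in p) acc <- acc * x + c
    acc
  }
  polyv(tf$num, as.complex(s)) / polyv(tf$den, as.complex(s))
}

#' Poles of a transfer function
#' @param tf A [transfer_fn()].
#' @return Complex vector of denominator roots (empty for a pure gain).
#' @export
tf_poles <- function(tf) {
  if (length(tf$den) < 2) return(complex(0))
  polyroot(rev(tf$den))
}

#' DC gain `H(0)`
#' @param tf A [transfer_fn()].
#' @return Real number (possibly `Inf` for an integrating system).
#' @export
tf_dcgain <- function(tf) {
  n0 <- tf$num[length(tf$num)]
  d0 <- tf$den[length(tf$den)]
  if (d0 == 0) return(sign(n0) * Inf)
  n0 / d0
}

#' Find an equilibrium of a pathway model
#'
#' Damped Newton iteration on `F(x, u0) = 0` with a finite-difference
#' Jacobian. The step is halved (up to 40 times) until the residual norm
#' decreases, giving robust convergence from rough initial guesses.
#'
#' @param model A `pathway_model` (or object coercible via
#'   [as_pathway_model()]).
#' @param u0 Constant input (receptor occupancy) at which to equilibrate.
#' @param guess Initial state guess; defaults to a small positive vector.
#' @param tol Convergence tolerance: `||F|| <= tol * (1 + ||x||)`.
#' @param max_iter Maximum Newton iterations.
#' @return Equilibrium state vector.
#' @export
find_equilibrium <- function(model, u0, guess = NULL, tol = 1e-10,
                             max_iter = 100) {
  model <- as_pathway_model(model)
  x <- if (is.null(guess)) rep(0.1, model$state_dim) else as.numeric(guess)
  if (length(x) != model$state_dim) stop("guess has wrong length")
  fval <- model$deriv(x, u0)
  for (it in seq_len(max_iter)) {
    res <- sqrt(sum(fval^2))
    if (res <= tol * (1 + sqrt(sum(x^2)))) return(x)
    J <- jacobian_fd(function(z) model$deriv(z, u0), x)
    step <- tryCatch(solve(J, -fval), error = function(e)
      stop("singular Jacobian in equilibrium search (residual ", res, ")"))
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      f_new <- model$deriv(x_new, u0)
      if (sqrt(sum(f_new^2)) < res || lambda < 2^-40) break
      lambda <- lambda / 2
    }
    x <- x_new
    fval <- f_new
  }
  res <- sqrt(sum(fval^2))
  if (res <= tol * (1 + sqrt(sum(x^2)))) return(x)
  stop("equilibrium search did not converge in ", max_iter,
       " iterations; last residual ", format(res))
}

# Central-difference Jacobian with step relative to the variable scale.
jacobian_fd <- function(f, x, rel_step = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- rel_step * (1 + abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Linearize a pathway model around its equilibrium
#'
#' First-order Taylor expansion of the state derivative `F` and output map
#' `G` at the equilibrium for constant input `u0`:
#' `A = dF/dx`, `B = dF/du`, `C = dG/dx`, `D = dG/du`, all evaluated by
#' central finite differences with step size relative 1e-6.
#'
#' @inheritParams find_equilibrium
#' @return Object of class `"state_space_model"` with fields `A`, `B`, `C`,
#'   `D`, `x_eq`, `u_eq`.
#' @export
linearize_model <- function(model, u0, guess = NULL) {
  model <- as_pathway_model(model)
  x_eq <- find_equilibrium(model, u0, guess)
  A <- jacobian_fd(function(z) model$deriv(z, u0), x_eq)
  B <- jacobian_fd(function(v) model$deriv(x_eq, v[1]), u0)
  C <- jacobian_fd(function(z) model$output(z, u0), x_eq)
  D <- jacobian_fd(function(v) model$output(x_eq, v[1]), u0)
  state_space_model(A, B, C, D, x_eq = x_eq, u_eq = u0)
}

#' State-space model container
#'
#' @param A,B,C,D System matrices (`A` `n x n`, `B` `n x 1`, `C` `1 x n`,
#'   `D` `1 x 1`).
#' @param x_eq,u_eq Equilibrium state and input the linearization refers to.
#' @return Object of class `"state_space_model"`.
#' @export
state_space_model <- function(A, B, C, D = 0, x_eq = NULL, u_eq = NULL) {
  A <- as.matrix(A); B <- as.matrix(B); C <- matrix(C, nrow = 1)
  D <- as.numeric(D)[1]
  n <- nrow(A)
  if (ncol(A) != n || nrow(B) != n || ncol(B) != 1 || ncol(C) != n)
    stop("inconsistent state-space dimensions")
  structure(list(A = A, B = B, C = C, D = D, x_eq = x_eq, u_eq = u_eq),
            class = "state_space_model")
}

#' Transfer function of a state-space model
#'
#' Expands `H(s) = C (sI - A)^{-1} B + D` into a rational function using the
#' determinant identity `det(sI - A + B C) = det(sI - A) (1 + C (sI-A)^{-1} B)`:
#' the denominator is the characteristic polynomial of `A` and the numerator
#' follows from the characteristic polynomial of `A - B C`.
#'
#' @param ss A [state_space_model()].
#' @return A [transfer_fn()].
#' @export
transfer_function <- function(ss) {
  stopifnot(inherits(ss, "state_space_model"))
  n <- nrow(ss$A)
  if (n == 1) {
    den <- c(1, -ss$A[1, 1])
    num_core <- c(0, ss$C[1, 1] * ss$B[1, 1])
  } else {
    den <- pracma::charpoly(ss$A)
    num_core <- pracma::charpoly(ss$A - ss$B %*% ss$C) - den
  }
  num <- num_core + ss$D * den
  transfer_fn(num, den)
}

#' Frequency response at given angular frequencies
#'
#' Magnitude in decibels (`20 log10 |H(i w)|`) and phase in degrees of the
#' complex response `H(i w)`. A zero response (e.g. `w = 0` for a band-pass
#' filter) yields a `-Inf` magnitude sentinel.
#'
#' @param tf A [transfer_fn()].
#' @param omega Angular frequency vector (1/s), non-negative.
#' @return Data frame with columns `omega_per_s`, `magnitude_db`, `phase_deg`.
#' @export
freq_response <- function(tf, omega) {
  if (any(omega < 0)) stop("omega must be >= 0")
  H <- tf_eval(tf, 1i * omega)
  data.frame(
    omega_per_s = omega,
    magnitude_db = 20 * log10(Mod(H)),
    phase_deg = Arg(H) * 180 / pi
  )
}

#' Bode table over a frequency grid
#'
#' Like [freq_response()] but with the phase unwrapped along the grid so it
#' is continuous (no artificial 360-degree jumps). The default grid is 200
#' log-spaced points over `[1e-4, 1e3]` 1/s, wide enough to span both slow
#' (transcription-scale) and fast (phosphorylation-scale) dynamics.
#'
#' @param tf A [transfer_fn()].
#' @param omega Angular frequency grid (1/s, increasing, positive).
#' @return Data frame of class `"bode_table"` with columns `omega_per_s`,
#'   `magnitude_db`, `phase_deg`.
#' @export
bode_table <- function(tf, omega = pracma::logseq(1e-4, 1e3, 200)) {
  if (any(omega <= 0)) stop("bode_table requires strictly positive omega")
  fr <- freq_response(tf, omega)
  ph <- fr$phase_deg * pi / 180
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  fr$phase_deg <- (ph[1] + c(0, cumsum(d))) * 180 / pi
  class(fr) <- c("bode_table", "data.frame")
  fr
}

#' Peak gain of a stable transfer function
#'
#' Numerically maximises `|H(i w)|` on a wide log grid scaled to the pole
#' magnitudes, refined by golden-section search around the grid argmax.
#'
#' @param tf A [transfer_fn()].
#' @return List with `peak` (absolute gain) and `omega_peak` (1/s).
#' @export
tf_peak_gain <- function(tf) {
  p <- tf_poles(tf)
  scale <- if (length(p) == 0) 1 else exp(mean(log(pmax(Mod(p), 1e-12))))
  grid <- scale * 10^seq(-6, 6, length.out = 600)
  mag <- Mod(tf_eval(tf, 1i * grid))
  k <- which.max(mag)
  lo <- grid[max(k - 1, 1)]; hi <- grid[min(k + 1, length(grid))]
  opt <- stats::optimize(function(w) -Mod(tf_eval(tf, 1i * w)),
                         lower = lo, upper = hi, tol = 1e-12)
  peak <- max(mag[k], -opt$objective, Mod(tf_eval(tf, 0 + 0i)))
  wpk <- if (-opt$objective >= mag[k]) opt$minimum else grid[k]
  list(peak = peak, omega_peak = wpk)
}

#' Classify a transfer function as band-pass, low-pass or other
#'
#' A stable `H(s)` is a band-pass filter when its DC gain vanishes
#' (`|H(0)| <= 1e-9` of the peak gain), its response decays at high
#' frequency, and the peak gain is finite and positive -- the frequency-domain
#' signature of a perfectly adapting pathway. It is a low-pass filter when
#' the peak gain is attained at DC (within relative 1e-6), the magnitude is
#' non-increasing in frequency and the response still decays at high
#' frequency -- a non-adaptive pathway. Everything else is `"other"`.
#'
#' @param tf A [transfer_fn()]; must be stable (all poles in the open left
#'   half plane).
#' @return Character: `"band_pass"`, `"low_pass"` or `"other"`.
#' @export
classify_filter <- function(tf) {
  p <- tf_poles(tf)
  if (any(Re(p) >= 0)) stop("classify_filter requires a stable transfer function")
  rel_degree <- length(tf$den) - length(tf$num)
  pk <- tf_peak_gain(tf)
  if (!is.finite(pk$peak) || pk$peak <= 0) return("other")
  H0 <- abs(tf_dcgain(tf))
  strictly_proper <- rel_degree >= 1
  if (strictly_proper && H0 <= 1e-9 * pk$peak) return("band_pass")
  if (strictly_proper && H0 >= pk$peak * (1 - 1e-6)) {
    scale <- exp(mean(log(pmax(Mod(p), 1e-12))))
    grid <- scale * 10^seq(-6, 6, length.out = 400)
    mag <- Mod(tf_eval(tf, 1i * grid))
    if (all(diff(mag) <= 1e-9 * pk$peak)) return("low_pass")
  }
  "other"
}
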