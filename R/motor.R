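# CheY-P-controlled flagellar motor: Hill-type CW-bias map and the two-state
# (run/tumble) Markov chain at the 0.5 s motor time scale.

#' Flagellar motor model
#'
#' The motor state is held constant over a short time scale (`dt_motor`,
#' default 0.5 s) and switches between clockwise (CW, tumble) and
#' counter-clockwise (CCW, run) rotation. The fraction of time spent CW --
#' the CW rotation bias -- is an ultrasensitive Hill function of CheY-P with
#' half-maximal point `K_half = 3.1` uM and Hill coefficient `10.3`
#' (single-motor calibration), which places the 2.71 uM CheY-P baseline at a
#' 20% CW bias.
#'
#' @param K_half CheY-P concentration at half-maximal CW bias (uM).
#' @param hill Hill coefficient (dimensionless).
#' @param dt_motor Motor time scale (s): the interval over which the state is
#'   approximated constant.
#' @param persistence Optional state persistence in `[0, 1)`: with
#'   probability `persistence` the motor keeps its current state for another
#'   interval, otherwise the state is redrawn from the stationary law. This
#'   rescales both transition probabilities equally, so the stationary CW
#'   occupancy remains exactly the CW bias. Default 0 (memoryless).
#' @return Object of class `"motor_model"`.
#' @export
motor_model <- function(K_half = 3.1, hill = 10.3, dt_motor = 0.5,
                        persistence = 0) {
  stopifnot(K_half > 0, hill > 0, dt_motor > 0,
            persistence >= 0, persistence < 1)
  structure(list(K_half = K_half, hill = hill, dt_motor = dt_motor,
                 persistence = persistence),
            class = "motor_model")
}

#' CW rotation bias as a function of CheY-P
#'
#' `bias = cheYp^h / (cheYp^h + K_half^h)`: the stationary fraction of time
#' the motor rotates clockwise (tumbles). Strictly increasing in CheY-P with
#' `bias(K_half) = 0.5`.
#'
#' @param cheYp CheY-P concentration (uM), scalar or vector, non-negative.
#' @param motor A [motor_model()].
#' @return CW bias fraction(s) in `[0, 1]`.
#' @export
cw_bias <- function(cheYp, motor = motor_model()) {
  if (any(!is.finite(cheYp)) || any(cheYp < 0))
    stop("cheYp must be finite and >= 0")
  # computed on the log scale to avoid overflow at large Hill coefficients
  r <- exp(motor$hill * (log(pmax(cheYp, .Machine$double.xmin)) - log(motor$K_half)))
  ifelse(cheYp == 0, 0, r / (1 + r))
}

#' Draw the next motor state
#'
#' One step of the two-state Markov chain at the motor time scale. With the
#' default memoryless chain the next state is tumble (0) with probability
#' `cw_bias(cheYp)` and run (1) otherwise, so the stationary CW occupancy
#' equals the bias exactly. A nonzero `persistence` in the motor model keeps
#' the current state with that probability before redrawing, preserving the
#' stationary law. Uses R's global random number stream.
#'
#' @param state Current state(s): 1 = run (CCW), 0 = tumble (CW). Scalar or
#'   vector (recycled against `cheYp`).
#' @param cheYp CheY-P concentration(s) (uM).
#' @param motor A [motor_model()].
#' @return Next state(s), 0 or 1.
#' @export
motor_step <- function(state, cheYp, motor = motor_model()) {
  if (!all(state %in% c(0, 1))) stop("motor state must be 0 (tumble) or 1 (run)")
  n <- max(length(state), length(cheYp))
  state <- rep_len(state, n)
  bias <- rep_len(cw_bias(cheYp, motor), n)
  draw <- ifelse(stats::runif(n) < bias, 0, 1)
  if (motor$persistence > 0) {
    keep <- stats::runif(n) < motor$persistence
    draw[keep] <- state[keep]
  }
  draw
}
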