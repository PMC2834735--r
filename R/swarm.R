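# Run-and-tumble agent-based population simulator coupling
# field -> receptor -> controller -> motor -> movement.
#
# Per motor interval: the cell first moves (run) or reorients (tumble)
# according to its current motor state; at the end of the interval the local
# ligand at the new position is read, the controller is advanced to give the
# new CheY-P, and that value sets the motor state for the next interval.

#' Simulation configuration
#'
#' Describes one population experiment: the ligand field, the controller
#' (an LTI [controller_filter()] or a nonlinear [designed_pathway()]), the
#' motor model, population size, duration and kinematics. Time advances in
#' motor intervals `dt` (default 0.5 s); the ligand is sampled once per
#' interval at the current position, so the controller sees a
#' piecewise-constant input.
#'
#' @param controller A [controller_filter()] or [designed_pathway()].
#' @param n_bacteria Number of agents (default 100).
#' @param duration Simulated time (s, default 1000); a multiple of `dt`.
#' @param dt Motor time scale (s, default 0.5).
#' @param speed Run speed (mm/s, default 0.02).
#' @param init_position Common initial position `c(x, y)` in mm
#'   (default `c(1.4, 0)`).
#' @param seed Integer seed; all randomness in [simulate_swarm()] flows from it.
#' @param motor A [motor_model()].
#' @param field A [concentration_field()].
#' @param receptor A [receptor()] used to convert ligand to occupancy for LTI
#'   controllers (designed pathways carry their own receptor).
#' @param record_stride Record every `record_stride`-th step (default 1).
#' @param record_positions If `TRUE`, store per-step agent positions as well
#'   as local ligand concentrations.
#' @param reorientation `"uniform"` (new heading uniform on `[0, 2 pi)`) or
#'   `"deflection"` (heading deflected by a centred Gaussian angle).
#' @param deflection_sd Deflection standard deviation in radians (used for
#'   `reorientation = "deflection"`).
#' @param n_substeps Runge-Kutta substeps per motor interval for nonlinear
#'   pathway controllers (default 10).
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(controller, n_bacteria = 100, duration = 1000,
                              dt = 0.5, speed = 0.02,
                              init_position = c(1.4, 0), seed = 1,
                              motor = motor_model(),
                              field = concentration_field(),
                              receptor = bactaxis::receptor(),
                              record_stride = 1, record_positions = FALSE,
                              reorientation = c("uniform", "deflection"),
                              deflection_sd = pi / 3, n_substeps = 10) {
  reorientation <- match.arg(reorientation)
  if (!inherits(controller, "controller_filter") &&
      !inherits(controller, "designed_pathway"))
    stop("controller must be a controller_filter or a designed_pathway")
  stopifnot(n_bacteria >= 1, dt > 0, duration > 0, speed >= 0,
            length(init_position) == 2, record_stride >= 1, n_substeps >= 1)
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("duration must be a multiple of dt")
  structure(list(controller = controller, n_bacteria = as.integer(n_bacteria),
                 duration = duration, dt = dt, speed = speed,
                 init_position = init_position, seed = seed, motor = motor,
                 field = field, receptor = receptor,
                 record_stride = as.integer(record_stride),
                 record_positions = isTRUE(record_positions),
                 reorientation = reorientation, deflection_sd = deflection_sd,
                 n_substeps = as.integer(n_substeps)),
            class = "simulation_config")
}

# Classical RK4 on the designed-pathway ODEs, vectorised over agents, with a
# safety clamp onto the invariant box (v >= 0, 0 <= y <= Y_T).
rk4_designed <- function(v, y, u, p, dt, nsub) {
  h <- dt / nsub
  for (i in seq_len(nsub)) {
    k1 <- designed_derivs_vec(v, y, u, p)
    k2 <- designed_derivs_vec(v + h / 2 * k1$dv, y + h / 2 * k1$dy, u, p)
    k3 <- designed_derivs_vec(v + h / 2 * k2$dv, y + h / 2 * k2$dy, u, p)
    k4 <- designed_derivs_vec(v + h * k3$dv, y + h * k3$dy, u, p)
    v <- v + h / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
    y <- y + h / 6 * (k1$dy + 2 * k2$dy + 2 * k3$dy + k4$dy)
  }
  list(v = pmax(v, 0), y = pmin(pmax(y, 0), p$Y_T))
}

#' Simulate a run-and-tumble population
#'
#' All agents start at `init_position` with headings drawn uniformly on
#' `[0, 2 pi)` and controller states at equilibrium for the local input.
#' Each motor interval: (1) running agents displace by `speed * dt` along
#' their heading while tumbling agents reorient in place; (2) the local
#' ligand concentration is read at the new position and converted to
#' receptor occupancy; (3) the controller is advanced over `dt`, giving the
#' CheY-P at the end of the interval; (4) the motor state for the next
#' interval is drawn from the CW bias at that CheY-P. Identical seeds give
#' identical records.
#'
#' For LTI controllers the input is the occupancy deviation from the
#' occupancy at the initial position (where the controller is at rest); for
#' band-pass and designed controllers the reference is immaterial since
#' `H(0) = 0`.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Object of class `"population_record"`: list with `times` (s),
#'   `L` (matrix, recorded times x agents, local ligand in uM), optional
#'   `x`/`y` position matrices, `final` data frame (per-agent position,
#'   heading, motor state, CheY-P), and the `config` and `seed` used.
#' @export
simulate_swarm <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$n_bacteria
  K <- round(config$duration / config$dt)
  dt <- config$dt
  ctrl <- config$controller
  is_lti <- inherits(ctrl, "controller_filter")

  x <- rep(config$init_position[1], n)
  y <- rep(config$init_position[2], n)
  heading <- stats::runif(n, 0, 2 * pi)

  L_init <- field_concentration(config$field, x[1], y[1])
  if (is_lti) {
    u_ref <- receptor_occupancy(L_init, config$receptor)
    d <- zoh_discretize(ctrl$ss, dt)
    k_state <- nrow(ctrl$ss$A)
    X <- matrix(0, n, k_state)          # adapted/rest state at the reference input
    Ad_t <- t(d$Ad); Bd <- drop(d$Bd); Cv <- drop(d$C); Dd <- d$D
    sgn <- controller_sign_factor(ctrl)
    cheyp <- rep(ctrl$baseline, n)
  } else {
    u_ref <- receptor_occupancy(L_init, ctrl$receptor)
    eq <- designed_equilibrium(u_ref, ctrl)
    v_state <- rep(eq[["v"]], n)
    y_state <- rep(eq[["y"]], n)
    cheyp <- y_state
  }

  motor_state <- ifelse(stats::runif(n) < cw_bias(cheyp, config$motor), 0, 1)

  rec_steps <- unique(c(seq(0, K, by = config$record_stride), K))
  rec_row <- integer(K + 1)               # step index (0-based) -> record row
  rec_row[rec_steps + 1] <- seq_along(rec_steps)
  is_rec <- logical(K + 1); is_rec[rec_steps + 1] <- TRUE
  L_mat <- matrix(NA_real_, length(rec_steps), n)
  if (config$record_positions) {
    x_mat <- matrix(NA_real_, length(rec_steps), n)
    y_mat <- matrix(NA_real_, length(rec_steps), n)
  }
  record <- function(step, L_loc) {
    r <- rec_row[step + 1]
    L_mat[r, ] <<- L_loc
    if (config$record_positions) {
      x_mat[r, ] <<- x
      y_mat[r, ] <<- y
    }
  }

  uniform_turn <- config$reorientation == "uniform"
  if (is_rec[1]) record(0L, field_concentration(config$field, x, y))

  for (k in seq_len(K)) {
    running <- motor_state == 1
    turn <- if (uniform_turn) stats::runif(n, 0, 2 * pi)
            else heading + stats::rnorm(n, 0, config$deflection_sd)
    heading <- ifelse(running, heading, turn %% (2 * pi))
    x <- x + ifelse(running, config$speed * dt * cos(heading), 0)
    y <- y + ifelse(running, config$speed * dt * sin(heading), 0)

    L_loc <- field_concentration(config$field, x, y)
    u <- if (is_lti) receptor_occupancy(L_loc, config$receptor)
         else receptor_occupancy(L_loc, ctrl$receptor)

    if (is_lti) {
      u_dev <- u - u_ref
      X <- X %*% Ad_t + outer(u_dev, Bd)
      cheyp <- pmax(ctrl$baseline + sgn * (drop(X %*% Cv) + Dd * u_dev), 0)
    } else {
      st <- rk4_designed(v_state, y_state, u, ctrl, dt, config$n_substeps)
      v_state <- st$v
      y_state <- st$y
      cheyp <- y_state
    }

    motor_state <- ifelse(stats::runif(n) < cw_bias(cheyp, config$motor), 0, 1)
    if (config$motor$persistence > 0) {
      keep <- stats::runif(n) < config$motor$persistence
      motor_state <- ifelse(keep & running, 1,
                            ifelse(keep & !running, 0, motor_state))
    }

    if (is_rec[k + 1]) record(k, L_loc)
  }

  out <- list(times = rec_steps * dt, L = L_mat,
              final = data.frame(x_mm = x, y_mm = y, heading_rad = heading,
                                 motor_state = motor_state, cheyp_um = cheyp),
              config = config, seed = seed)
  if (config$record_positions) {
    out$x <- x_mat
    out$y <- y_mat
  }
  structure(out, class = "population_record")
}

#' @export
print.population_record <- function(x, ...) {
  cat(sprintf("population_record: %d agents, %d recorded times over %g s (seed %s)\n",
              ncol(x$L), length(x$times), max(x$times), format(x$seed)))
  cat(sprintf("  mean local [L]: start %.4g uM, end %.4g uM\n",
              mean(x$L[1, ]), mean(x$L[nrow(x$L), ])))
  invisible(x)
}

#' Initialise a single bacterium
#'
#' Single-agent counterpart of the population initialisation in
#' [simulate_swarm()]: position at the configured start point, heading drawn
#' uniformly (or given), controller state at equilibrium for the local input
#' and motor state drawn from the baseline CW bias.
#'
#' @param config A [simulation_config()].
#' @param heading Optional fixed heading (radians); drawn uniformly if `NULL`.
#' @return Object of class `"bacterium"`: list with `position`, `heading`,
#'   `motor_state`, `cheyp_um`, `u_ref` and the controller state.
#' @export
bacterium <- function(config, heading = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  ctrl <- config$controller
  is_lti <- inherits(ctrl, "controller_filter")
  L_init <- field_concentration(config$field, config$init_position[1],
                                config$init_position[2])
  if (is_lti) {
    u_ref <- receptor_occupancy(L_init, config$receptor)
    state <- rep(0, nrow(ctrl$ss$A))
    cheyp <- ctrl$baseline
  } else {
    u_ref <- receptor_occupancy(L_init, ctrl$receptor)
    state <- designed_equilibrium(u_ref, ctrl)
    cheyp <- state[["y"]]
  }
  if (is.null(heading)) heading <- stats::runif(1, 0, 2 * pi)
  motor0 <- ifelse(stats::runif(1) < cw_bias(cheyp, config$motor), 0, 1)
  structure(list(position = config$init_position, heading = heading,
                 motor_state = motor0, cheyp_um = cheyp, u_ref = u_ref,
                 controller_state = state),
            class = "bacterium")
}

#' Advance a single bacterium by one motor interval
#'
#' Same per-step ordering as [simulate_swarm()], applied to one agent: move
#' (run) or reorient (tumble) with the current motor state, read the local
#' ligand at the new position, advance the controller over the interval, then
#' draw the next motor state from the resulting CheY-P. Uses R's global
#' random number stream.
#'
#' @param b A [bacterium()].
#' @param config The [simulation_config()] the bacterium belongs to.
#' @return The updated bacterium.
#' @export
agent_step <- function(b, config) {
  stopifnot(inherits(b, "bacterium"), inherits(config, "simulation_config"))
  ctrl <- config$controller
  is_lti <- inherits(ctrl, "controller_filter")
  dt <- config$dt
  if (b$motor_state == 1) {
    b$position <- b$position + config$speed * dt *
      c(cos(b$heading), sin(b$heading))
  } else {
    b$heading <- if (config$reorientation == "uniform")
      stats::runif(1, 0, 2 * pi)
    else (b$heading + stats::rnorm(1, 0, config$deflection_sd)) %% (2 * pi)
  }
  L_loc <- field_concentration(config$field, b$position[1], b$position[2])
  if (is_lti) {
    u <- receptor_occupancy(L_loc, config$receptor)
    d <- zoh_discretize(ctrl$ss, dt)
    u_dev <- u - b$u_ref
    b$controller_state <- drop(d$Ad %*% b$controller_state) + drop(d$Bd) * u_dev
    out <- controller_sign_factor(ctrl) *
      (drop(d$C %*% b$controller_state) + d$D * u_dev)
    b$cheyp_um <- max(ctrl$baseline + out, 0)
  } else {
    u <- receptor_occupancy(L_loc, ctrl$receptor)
    st <- rk4_designed(b$controller_state[["v"]], b$controller_state[["y"]],
                       u, ctrl, dt, config$n_substeps)
    b$controller_state <- c(v = st$v, y = st$y)
    b$cheyp_um <- st$y
  }
  b$motor_state <- motor_step(b$motor_state, b$cheyp_um, config$motor)
  b
}
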