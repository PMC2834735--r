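# Structured text (YAML) configuration: one file fully specifies an
# experiment (controller, field, motor, simulation). Used by the command-line
# front end and the packaged presets.

#' Read / write experiment configuration files
#'
#' Configurations are YAML files with up to four sections: `controller`,
#' `field`, `motor` and `simulation`. See the packaged presets under
#' `system.file("presets", package = "bactaxis")` for complete examples.
#'
#' @param path File path.
#' @return `read_config()` returns the parsed configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build a controller from a configuration list
#'
#' The `controller` section either describes an LTI filter
#' (`kind: low_pass | band_pass` with `A` and cut-offs) or a designed
#' pathway (`kind: pathway` with `variant` and rate constants).
#'
#' @param cfg Parsed configuration list (or just its `controller` section).
#' @return A [controller_filter()] or [designed_pathway()].
#' @export
config_controller <- function(cfg) {
  cc <- if (!is.null(cfg$controller)) cfg$controller else cfg
  if (is.null(cc$kind)) stop("controller section needs a 'kind'")
  pick <- function(name, default) if (is.null(cc[[name]])) default else cc[[name]]
  if (cc$kind == "pathway") {
    designed_pathway(
      variant = pick("variant", "positive"),
      c_v = pick("c_v", 0.1), d_v = pick("d_v", 0.02),
      k_phos = pick("k_phos", 27.1 / 30), k_dephos = pick("k_dephos", 32.9 / 6),
      Y_T = pick("Y_T", 6), k_auto = pick("k_auto", 1.86),
      receptor = receptor(pick("K_L", 1))
    )
  } else {
    controller_filter(
      kind = cc$kind, A = pick("A", 16),
      omega0 = cc$omega0, omega1 = cc$omega1, omega2 = cc$omega2,
      rank = pick("rank", 2), sign = pick("sign", "attractant"),
      baseline = pick("baseline", 2.71)
    )
  }
}

#' Build a simulation configuration from a configuration list
#'
#' @param cfg Parsed configuration list with `controller`, and optionally
#'   `field`, `motor` and `simulation` sections (missing entries fall back
#'   to the package defaults).
#' @return A [simulation_config()].
#' @export
config_simulation <- function(cfg) {
  ctrl <- config_controller(cfg)
  fld <- cfg$field
  field <- if (is.null(fld)) concentration_field() else
    concentration_field(shape = if (is.null(fld$shape)) "mountain" else fld$shape,
                        L0 = if (is.null(fld$L0)) 2 else fld$L0,
                        r = if (is.null(fld$r)) 2 else fld$r,
                        center = if (is.null(fld$center)) c(0, 0) else unlist(fld$center))
  mm <- cfg$motor
  motor <- if (is.null(mm)) motor_model() else
    motor_model(K_half = if (is.null(mm$K_half)) 3.1 else mm$K_half,
                hill = if (is.null(mm$hill)) 10.3 else mm$hill,
                dt_motor = if (is.null(mm$dt_motor)) 0.5 else mm$dt_motor,
                persistence = if (is.null(mm$persistence)) 0 else mm$persistence)
  sm <- if (is.null(cfg$simulation)) list() else cfg$simulation
  pick <- function(name, default) if (is.null(sm[[name]])) default else sm[[name]]
  simulation_config(
    controller = ctrl,
    n_bacteria = pick("n_bacteria", 100),
    duration = pick("duration", 1000),
    dt = pick("dt", motor$dt_motor),
    speed = pick("speed", 0.02),
    init_position = unlist(pick("init_position", c(1.4, 0))),
    seed = pick("seed", 1),
    motor = motor, field = field,
    receptor = receptor(pick("K_L", 1)),
    record_stride = pick("record_stride", 1),
    record_positions = isTRUE(pick("record_positions", FALSE)),
    reorientation = pick("reorientation", "uniform"),
    deflection_sd = pick("deflection_sd", pi / 3),
    n_substeps = pick("n_substeps", 10)
  )
}
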