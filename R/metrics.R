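# Chemotactic-effect statistic, box-plot summaries and parameter scans.

#' Chemotactic effect of a simulation
#'
#' Population mean of each agent's local ligand concentration, averaged over
#' all recorded steps in the final `window` seconds of the run (default
#' 50 s). Averaging over a window rather than taking the final snapshot
#' suppresses the fluctuation from movement randomness while still
#' reflecting both how quickly the population climbs and the final level it
#' holds.
#'
#' @param record A [simulate_swarm()] result.
#' @param window Averaging window (s), counted back from the final time.
#' @return Mean local ligand concentration (uM).
#' @export
chemotactic_effect <- function(record, window = 50) {
  stopifnot(inherits(record, "population_record"))
  t_end <- max(record$times)
  if (window > t_end) stop("window exceeds the recorded duration")
  keep <- record$times >= t_end - window
  mean(record$L[keep, , drop = FALSE])
}

#' Box-plot summary of a sample
#'
#' Quartiles by linear interpolation of the order statistics
#' ([stats::quantile()] type 7). Whiskers extend from the box to the most
#' extreme data value within 1.5 times the box height (interquartile range);
#' values beyond the whiskers are reported as outliers.
#'
#' @param values Non-empty numeric vector (e.g. local ligand concentrations
#'   of a population at one time point).
#' @return List with `q1`, `median`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `mean`, `n`.
#' @export
boxplot_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("boxplot_summary requires a non-empty sample")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]),
       mean = mean(values), n = length(values))
}

#' Per-time box-plot table of a population record
#'
#' Applies [boxplot_summary()] to every recorded time point of a simulation.
#'
#' @param record A [simulate_swarm()] result.
#' @return Data frame with one row per recorded time: `t_s`, `q1`, `median`,
#'   `q3`, `whisker_low`, `whisker_high`, `n_outliers`, `mean`.
#' @export
boxplot_table <- function(record) {
  stopifnot(inherits(record, "population_record"))
  rows <- lapply(seq_along(record$times), function(i) {
    s <- boxplot_summary(record$L[i, ])
    data.frame(t_s = record$times[i], q1 = s$q1, median = s$median, q3 = s$q3,
               whisker_low = s$whisker_low, whisker_high = s$whisker_high,
               n_outliers = length(s$outliers), mean = s$mean)
  })
  do.call(rbind, rows)
}

#' Scan controller parameters against the chemotactic effect
#'
#' Re-runs [simulate_swarm()] over a grid of controller parameters and
#' tabulates the chemotactic effect. Each grid cell is replicated over the
#' same set of seeds (common random numbers), so differences between cells
#' are not driven by seed noise.
#'
#' @param config Base [simulation_config()]; its controller supplies the
#'   parameters not being scanned.
#' @param grid Named list of parameter vectors to scan. Names must be
#'   controller-constructor arguments: any of `A`, `omega0`, `omega1`,
#'   `omega2`, `rank` for filter controllers. One or two parameters.
#' @param seeds Integer vector of replicate seeds (default `config$seed +
#'   0:2`); the reported effect is the mean over replicates.
#' @param window Averaging window (s) passed to [chemotactic_effect()].
#' @return Object of class `"scan_result"`: list with `grid` (data frame of
#'   parameter combinations with `effect_um` mean and `se_um` standard error
#'   across seeds), `effects` (replicate matrix, cells x seeds), `seeds`,
#'   and, for two-parameter scans, `matrix` (param1 rows x param2 columns).
#' @export
scan_parameters <- function(config, grid, seeds = config$seed + 0:2,
                            window = 50) {
  stopifnot(inherits(config, "simulation_config"), is.list(grid),
            length(grid) %in% c(1, 2), !is.null(names(grid)))
  if (!inherits(config$controller, "controller_filter"))
    stop("scan_parameters currently scans controller_filter parameters")
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  effects <- matrix(NA_real_, nrow(cells), length(seeds))
  for (i in seq_len(nrow(cells))) {
    ctrl <- config$controller
    args <- list(kind = ctrl$kind, A = ctrl$A, omega0 = ctrl$omega0,
                 omega1 = ctrl$omega1, omega2 = ctrl$omega2, rank = ctrl$rank,
                 sign = ctrl$sign, baseline = ctrl$baseline)
    for (nm in names(grid)) args[[nm]] <- cells[i, nm]
    cfg <- config
    cfg$controller <- do.call(controller_filter, args)
    for (j in seq_along(seeds)) {
      rec <- simulate_swarm(cfg, seed = seeds[j])
      effects[i, j] <- chemotactic_effect(rec, window)
    }
  }
  cells$effect_um <- rowMeans(effects)
  cells$se_um <- apply(effects, 1, stats::sd) / sqrt(length(seeds))
  out <- list(grid = cells, effects = effects, seeds = seeds)
  if (length(grid) == 2) {
    out$matrix <- matrix(cells$effect_um, nrow = length(grid[[1]]),
                         dimnames = list(format(grid[[1]], trim = TRUE),
                                         format(grid[[2]], trim = TRUE)))
  }
  structure(out, class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("parameter scan over", nrow(x$grid), "cells x", length(x$seeds),
      "seeds (chemotactic effect, uM):\n")
  print(x$grid, row.names = FALSE)
  invisible(x)
}
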