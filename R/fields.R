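# Static 2-D ligand concentration fields on the simulated plate.

#' Static 2-D ligand concentration field
#'
#' Two built-in shapes on an unbounded plane:
#' \describe{
#'   \item{mountain}{a ridge along the y axis, `L(x, y) = L0 exp(-(x/r)^2)`;}
#'   \item{peak}{a radial Gaussian, `L(x, y) = L0 exp(-(x^2 + y^2)/r^2)`.}
#' }
#' A custom shape can be supplied as a vectorised function `f(x, y)` in uM.
#' Fields are static in time (no diffusion or consumption) and the crest can
#' be shifted with `center`.
#'
#' @param shape `"mountain"`, `"peak"` or `"custom"`.
#' @param L0 Peak concentration (uM, default 2).
#' @param r Length scale (mm, default 2).
#' @param center Crest offset `c(x, y)` in mm (default origin).
#' @param fun Vectorised `function(x, y)` for `shape = "custom"`.
#' @return Object of class `"concentration_field"`.
#' @export
concentration_field <- function(shape = c("mountain", "peak", "custom"),
                                L0 = 2, r = 2, center = c(0, 0), fun = NULL) {
  shape <- match.arg(shape)
  if (shape != "custom") {
    stopifnot(L0 >= 0, r > 0, length(center) == 2)
  } else if (!is.function(fun)) {
    stop("shape = \"custom\" requires a function fun(x, y)")
  }
  structure(list(shape = shape, L0 = L0, r = r, center = center, fun = fun),
            class = "concentration_field")
}

#' Ligand concentration at given positions
#'
#' @param field A [concentration_field()].
#' @param x,y Position coordinates in mm (vectors of equal length).
#' @return Ligand concentration(s) in uM.
#' @export
field_concentration <- function(field, x, y) {
  stopifnot(inherits(field, "concentration_field"))
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("positions must be finite")
  dx <- x - field$center[1]
  dy <- y - field$center[2]
  switch(field$shape,
    mountain = field$L0 * exp(-(dx / field$r)^2),
    peak     = field$L0 * exp(-(dx^2 + dy^2) / field$r^2),
    custom   = field$fun(x, y)
  )
}
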