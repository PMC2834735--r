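# Pathway ODE models: receptor occupancy, the designed three-molecule
# chemotaxis pathways (positive / negative / pseudo wiring), and the universal
# activation/deactivation network model.

#' Ligand receptor
#'
#' A receptor is characterised by a single dissociation scale `K_L` (uM): the
#' ligand concentration at which half of the receptors are occupied.
#'
#' @param K_L Ligand dissociation scale in uM. Must be positive.
#' @return An object of class `"receptor"`.
#' @examples
#' r <- receptor(K_L = 1)
#' receptor_occupancy(1, r)  # 0.5 at the half-saturation point
#' @export
receptor <- function(K_L = 1) {
  stopifnot(is.numeric(K_L), length(K_L) == 1, is.finite(K_L))
  if (K_L <= 0) stop("K_L must be > 0")
  structure(list(K_L = K_L), class = "receptor")
}

#' Receptor occupancy
#'
#' Fraction of receptors bound by ligand, `u = L / (L + K_L)`. This is the
#' input variable of every controller in the package: ligand concentration is
#' translated into occupancy before it reaches the signalling dynamics, so
#' receptor saturation at high ligand is captured even when the downstream
#' controller is linear.
#'
#' @param L Ligand concentration in uM (scalar or vector, non-negative).
#' @param receptor A [receptor()] object.
#' @return Occupancy fraction(s) in `[0, 1]`, same length as `L`.
#' @export
receptor_occupancy <- function(L, receptor = bactaxis::receptor()) {
  if (any(!is.finite(L)) || any(L < 0)) stop("ligand concentration must be finite and >= 0")
  L / (L + receptor$K_L)
}

#' Designed three-molecule chemotaxis pathway
#'
#' The minimal pathway that realises a band-pass controller without feedback:
#' occupied receptor (occupancy `u`) produces an intermediate active molecule
#' `v` and, in the positive wiring, directly dephosphorylates CheY-P while `v`
#' phosphorylates CheY. The fast arm (direct dephosphorylation) and the slow
#' arm (through `v`) cancel at steady state, which makes the equilibrium
#' CheY-P level independent of `u` -- robust perfect adaptation by an
#' "asymmetric clamp" rather than integral feedback.
#'
#' Variants:
#' \describe{
#'   \item{`positive`}{`dv/dt = c_v u - d_v v`;
#'     `dy/dt = k_phos v (Y_T - y) - k_dephos u y`. Attractant-seeking.}
#'   \item{`negative`}{phosphorylation/dephosphorylation roles of `u` and `v`
#'     swapped: `dy/dt = k_dephos u (Y_T - y) - k_phos v y`. Repellent-avoiding.}
#'   \item{`pseudo`}{non-adaptive control: `v` dephosphorylates CheY-P and a
#'     basal autophosphorylation `k_auto (Y_T - y)` supplies CheY-P;
#'     `dy/dt = k_auto (Y_T - y) - k_phos v y`.}
#' }
#'
#' Default rates are calibrated so that the positive pathway has an
#' equilibrium CheY-P of 2.71 uM, a slow (adaptation) rate `d_v = 0.02` 1/s
#' and a fast CheY turnover rate `k_phos v* + k_dephos u* = 5` 1/s at the
#' reference occupancy `u* = 0.5` -- i.e. its linearization is a band-pass
#' filter with cut-offs 0.02 and 5 1/s.
#'
#' @param variant One of `"positive"`, `"negative"`, `"pseudo"`.
#' @param c_v Production rate of active `v` per unit occupancy (uM/s).
#' @param d_v Deactivation rate of `v` (1/s); sets the slow cut-off.
#' @param k_phos CheY phosphorylation rate constant (1/(uM s)).
#' @param k_dephos CheY-P dephosphorylation rate constant per unit occupancy (1/s).
#' @param Y_T Total CheY concentration (uM).
#' @param k_auto Basal CheY autophosphorylation rate (1/s); pseudo variant only.
#' @param receptor A [receptor()] translating ligand to occupancy.
#' @return An object of class `"designed_pathway"`.
#' @seealso [designed_derivs()], [designed_equilibrium()], [as_pathway_model()]
#' @export
designed_pathway <- function(variant = c("positive", "negative", "pseudo"),
                             c_v = 0.1, d_v = 0.02,
                             k_phos = 27.1 / 30, k_dephos = 32.9 / 6,
                             Y_T = 6, k_auto = 1.86,
                             receptor = bactaxis::receptor()) {
  variant <- match.arg(variant)
  rates <- c(c_v = c_v, d_v = d_v, k_phos = k_phos, k_dephos = k_dephos,
             k_auto = k_auto)
  if (any(!is.finite(rates)) || any(rates < 0)) stop("all rates must be finite and >= 0")
  if (!is.finite(Y_T) || Y_T <= 0) stop("Y_T must be > 0")
  stopifnot(inherits(receptor, "receptor"))
  structure(list(variant = variant, c_v = c_v, d_v = d_v, k_phos = k_phos,
                 k_dephos = k_dephos, Y_T = Y_T, k_auto = k_auto,
                 receptor = receptor),
            class = "designed_pathway")
}

# Vectorised right-hand side shared by the scalar API and the swarm stepper.
designed_derivs_vec <- function(v, y, u, p) {
  dv <- p$c_v * u - p$d_v * v
  dy <- switch(p$variant,
    positive = p$k_phos * v * (p$Y_T - y) - p$k_dephos * u * y,
    negative = p$k_dephos * u * (p$Y_T - y) - p$k_phos * v * y,
    pseudo   = p$k_auto * (p$Y_T - y) - p$k_phos * v * y,
    stop("unknown variant: ", p$variant)
  )
  list(dv = dv, dy = dy)
}

#' Time derivatives of a designed pathway
#'
#' @param state Numeric vector `c(v, y)`: active intermediate and CheY-P (uM).
#' @param u Receptor occupancy in `[0, 1]`.
#' @param pathway A [designed_pathway()].
#' @return Numeric vector `c(dv/dt, dy/dt)` in uM/s.
#' @export
designed_derivs <- function(state, u, pathway) {
  stopifnot(inherits(pathway, "designed_pathway"), length(state) == 2)
  d <- designed_derivs_vec(state[[1]], state[[2]], u, pathway)
  c(d$dv, d$dy)
}

#' Equilibrium of a designed pathway
#'
#' Closed-form fixed point at constant occupancy `u`. For the positive and
#' negative wirings the equilibrium CheY-P is independent of `u` (perfect
#' adaptation); for the pseudo wiring it is not.
#'
#' @inheritParams designed_derivs
#' @return Named vector `c(v = v_star, y = y_star)` in uM.
#' @export
designed_equilibrium <- function(u, pathway) {
  stopifnot(inherits(pathway, "designed_pathway"))
  if (pathway$d_v == 0) stop("d_v = 0: the intermediate has no equilibrium")
  if (u < 0 || u > 1) stop("occupancy u must lie in [0, 1]")
  v_star <- pathway$c_v * u / pathway$d_v
  y_star <- switch(pathway$variant,
    positive = {
      if (u == 0) stop("positive variant: equilibrium CheY-P undetermined at u = 0")
      rho <- pathway$c_v / pathway$d_v
      pathway$Y_T * pathway$k_phos * rho / (pathway$k_phos * rho + pathway$k_dephos)
    },
    negative = {
      if (u == 0) stop("negative variant: equilibrium CheY-P undetermined at u = 0")
      rho <- pathway$c_v / pathway$d_v
      pathway$Y_T * pathway$k_dephos / (pathway$k_dephos + pathway$k_phos * rho)
    },
    pseudo = pathway$Y_T * pathway$k_auto /
      (pathway$k_auto + pathway$k_phos * v_star)
  )
  c(v = v_star, y = unname(y_star))
}

#' Universal activation/deactivation pathway model
#'
#' A network of `n` molecules, each switching between inactive and active
#' form. Active molecule `j` activates molecule `i` at rate `C[i, j]` and
#' deactivates it at rate `D[i, j]`; the receptor drives molecule `i` at rates
#' `C_u[i]` / `D_u[i]`; `C_self` / `D_self` are basal self rates. The active
#' concentration of each molecule is confined to `[0, y_t[i]]` by the
#' mass-action structure. The last molecule (by default) is CheY and its
#' active (phosphorylated) concentration is the pathway output.
#'
#' @param y_t Vector of total concentrations (uM), length `n`.
#' @param C,D `n x n` cross-activation / cross-deactivation rate matrices
#'   (1/(uM s)); diagonals are ignored (self rates are separate).
#' @param C_self,D_self Self-activation / self-deactivation rates (1/s).
#' @param C_u,D_u Receptor-driven activation / deactivation rates (1/s per
#'   unit occupancy).
#' @param receptor A [receptor()].
#' @param output_index Index of the CheY molecule (default `n`).
#' @return An object of class `"universal_pathway"`.
#' @export
universal_pathway <- function(y_t, C = NULL, D = NULL,
                              C_self = NULL, D_self = NULL,
                              C_u = NULL, D_u = NULL,
                              receptor = bactaxis::receptor(),
                              output_index = length(y_t)) {
  n <- length(y_t)
  if (n < 1 || any(!is.finite(y_t)) || any(y_t <= 0)) stop("y_t must be positive")
  zm <- function(m) if (is.null(m)) matrix(0, n, n) else m
  zv <- function(v) if (is.null(v)) numeric(n) else v
  C <- zm(C); D <- zm(D)
  C_self <- zv(C_self); D_self <- zv(D_self)
  C_u <- zv(C_u); D_u <- zv(D_u)
  if (!all(dim(C) == c(n, n)) || !all(dim(D) == c(n, n)))
    stop("C and D must be ", n, " x ", n, " matrices")
  if (length(C_self) != n || length(D_self) != n ||
      length(C_u) != n || length(D_u) != n)
    stop("self and receptor rate vectors must have length ", n)
  if (any(c(C, D, C_self, D_self, C_u, D_u) < 0)) stop("all rates must be >= 0")
  if (output_index < 1 || output_index > n) stop("output_index out of range")
  diag(C) <- 0; diag(D) <- 0
  structure(list(n = n, y_t = y_t, C = C, D = D, C_self = C_self,
                 D_self = D_self, C_u = C_u, D_u = D_u, receptor = receptor,
                 output_index = output_index),
            class = "universal_pathway")
}

#' Time derivatives of the universal pathway model
#'
#' `dy_i/dt = (y_t[i] - y_i) (C_self[i] + C_u[i] u + sum_{j != i} C[i,j] y_j)
#'          -  y_i (D_self[i] + D_u[i] u + sum_{j != i} D[i,j] y_j)`
#'
#' @param state Vector of active concentrations (uM), length `n`.
#' @param u Receptor occupancy in `[0, 1]`.
#' @param model A [universal_pathway()].
#' @return Derivative vector in uM/s.
#' @export
universal_derivs <- function(state, u, model) {
  stopifnot(inherits(model, "universal_pathway"))
  if (length(state) != model$n) stop("state must have length ", model$n)
  act <- model$C_self + model$C_u * u + drop(model$C %*% state)
  dea <- model$D_self + model$D_u * u + drop(model$D %*% state)
  (model$y_t - state) * act - state * dea
}

#' Wrap a pathway as a generic input-driven ODE model
#'
#' A `pathway_model` is the common currency of the linearization machinery:
#' a smooth state derivative `deriv(state, u)`, a scalar output map
#' `output(state, u)` (CheY-P here) and the state dimension. The input `u` is
#' receptor occupancy.
#'
#' @param x A [designed_pathway()] or [universal_pathway()], or (for
#'   `pathway_model()`) a derivative function.
#' @param ... Passed to methods (unused).
#' @return An object of class `"pathway_model"` with fields `deriv`, `output`,
#'   `state_dim`.
#' @export
as_pathway_model <- function(x, ...) UseMethod("as_pathway_model")

#' @rdname as_pathway_model
#' @param deriv Function `(state, u) -> dstate/dt`.
#' @param output Function `(state, u) -> scalar`.
#' @param state_dim Integer state dimension.
#' @export
pathway_model <- function(deriv, output, state_dim) {
  stopifnot(is.function(deriv), is.function(output),
            is.numeric(state_dim), state_dim >= 1)
  structure(list(deriv = deriv, output = output, state_dim = as.integer(state_dim)),
            class = "pathway_model")
}

#' @rdname as_pathway_model
#' @export
as_pathway_model.designed_pathway <- function(x, ...) {
  force(x)
  pathway_model(
    deriv = function(state, u) designed_derivs(state, u, x),
    output = function(state, u) state[[2]],
    state_dim = 2L
  )
}

#' @rdname as_pathway_model
#' @export
as_pathway_model.universal_pathway <- function(x, ...) {
  force(x)
  pathway_model(
    deriv = function(state, u) universal_derivs(state, u, x),
    output = function(state, u) state[[x$output_index]],
    state_dim = x$n
  )
}

#' @rdname as_pathway_model
#' @export
as_pathway_model.pathway_model <- function(x, ...) x
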