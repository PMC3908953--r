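# Wall composition, geometry, constitutive stress laws, Laplace equilibrium
# and Poiseuille shear. Pure functions; everything in SI.

.degenerate_geometry <- function(msg) {
  stop(errorCondition(msg, class = c("vesseladapt_degenerate_geometry",
                                     "error", "condition")))
}

# geometry without validation; used inside the ODE right-hand side where
# transient trial states may be degenerate (guards terminate those runs)
.geometry <- function(eps, span, r_mslack, wcsa) {
  r_m <- r_mslack * (1 + eps)
  h <- wcsa / (2 * pi * r_m)
  list(r_m = r_m, h = h, r_i = r_m - h / 2, l = span * 2 * pi * r_m)
}

#' Derive vessel geometry from the state
#'
#' The midwall radius follows from the slack radius and the matrix strain,
#' `r_m = r_mslack * (1 + eps)`. The wall is a circular annulus about the
#' mid-surface, so `wcsa = 2*pi*r_m*h` exactly and `r_i = r_m - h/2`. SMC
#' length is span times circumference, `l = span * 2*pi*r_m`.
#'
#' @param state a [vessel_state()] (or named vector with the five components).
#' @return list with `r_m`, `h`, `r_i` (m) and SMC length `l` (m).
#' @examples
#' g <- derive_geometry(vessel_state(0.5, 0, 0.2, 80e-6, 1.508e-8))
#' c(r_m = g$r_m, h = g$h, r_i = g$r_i)  # 120, 20, 110 um
#' @export
derive_geometry <- function(state) {
  g <- .geometry(state[["eps"]], state[["span"]], state[["r_mslack"]],
                 state[["wcsa"]])
  if (!is.finite(g$r_i) || g$r_i <= 0)
    .degenerate_geometry("degenerate geometry: internal radius <= 0 (wall thicker than the lumen permits)")
  g
}

#' Passive matrix stress
#'
#' Bi-exponential stress-strain law of the vascular matrix,
#' `c_p1*(exp(c_p3*eps)-1) + c_p2*(exp(c_p4*eps)-1)` for positive strain.
#' The first term dominates at moderate strain; the second, very steep term
#' represents recruitment of stiff fibers at high distension. A slack matrix
#' (eps <= 0) bears no load: the stress is floored at 0.
#'
#' @param eps matrix strain (vectorized).
#' @param params a [vessel_params()] object.
#' @return stress in Pa, non-negative, strictly increasing and convex for
#'   eps > 0.
#' @export
matrix_stress <- function(eps, params = vessel_params()) {
  s <- params$c_p1 * (exp(params$c_p3 * eps) - 1) +
    params$c_p2 * (exp(params$c_p4 * eps) - 1)
  ifelse(eps <= 0, 0, s)
}

#' Active stress capacity of the smooth muscle
#'
#' Bell-shaped dependence of the maximal (fully activated) active stress on
#' SMC length: `sigma_amax * exp(-((l - l_opt)/l_w)^2)`. The capacity peaks
#' at `l_opt` and is symmetric about it with width `l_w`. The actual active
#' stress is tone times this capacity.
#'
#' @param l SMC length in m (vectorized).
#' @inheritParams matrix_stress
#' @return stress capacity in Pa.
#' @examples
#' active_stress_capacity(106.18e-6)  # 250000 Pa at the optimum
#' @export
active_stress_capacity <- function(l, params = vessel_params()) {
  params$sigma_amax * exp(-((l - params$l_opt) / params$l_w)^2)
}

#' Cytoskeletal stress (stretch brake)
#'
#' Very steep exponential dependence of cytoskeletal stress on SMC length,
#' `c_c1 * exp(c_c2 * (l - c_c3)/c_c3)`, anchored so the stress equals
#' `c_c1` at `l = c_c3`. Negligible at the reference length, it acts as a
#' brake preventing stretch of the cell much beyond `c_c3`.
#'
#' @inheritParams active_stress_capacity
#' @return stress in Pa, strictly increasing in `l`.
#' @export
cytoskeletal_stress <- function(l, params = vessel_params()) {
  params$c_c1 * exp(params$c_c2 * (l - params$c_c3) / params$c_c3)
}

#' Element and mean wall stresses of a state
#'
#' The three stress-bearing elements are arranged in parallel, each covering
#' an area fraction of the wall, so the mean wall stress is
#' `sigma = af_p*sigma_p + af_a*tone*sigma_acap + af_c*sigma_c` with the SMC
#' length taken from [derive_geometry()]. When pressure and/or flow are
#' supplied, the Laplace equilibrium stress and the Poiseuille wall shear are
#' included.
#'
#' @inheritParams derive_geometry
#' @param params a [vessel_params()] object.
#' @param P transmural pressure in Pa (optional).
#' @param Q volume flow in m^3/s (optional).
#' @return list with `sigma_p`, `sigma_acap`, `sigma_a`, `sigma_c`, `sigma`
#'   (Pa), and `sigma_eq`, `tau` when P, Q are given.
#' @export
wall_stresses <- function(state, params = vessel_params(), P = NULL, Q = NULL) {
  g <- derive_geometry(state)
  eps <- max(state[["eps"]], .EPS_FLOOR)
  tone <- min(max(state[["tone"]], 0), 1)
  sigma_p <- matrix_stress(eps, params)
  sigma_acap <- active_stress_capacity(g$l, params)
  sigma_c <- cytoskeletal_stress(g$l, params)
  sigma_a <- tone * sigma_acap
  out <- list(
    sigma_p = sigma_p, sigma_acap = sigma_acap, sigma_a = sigma_a,
    sigma_c = sigma_c,
    sigma = params$af_p * sigma_p + params$af_a * sigma_a +
      params$af_c * sigma_c
  )
  if (!is.null(P)) out$sigma_eq <- laplace_stress(P, g)
  if (!is.null(Q)) out$tau <- wall_shear_stress(Q, g$r_i, params)
  out
}

#' @rdname wall_stresses
#' @return `mean_wall_stress()` returns the scalar mean wall stress (Pa).
#' @export
mean_wall_stress <- function(state, params = vessel_params()) {
  wall_stresses(state, params)$sigma
}

#' Laplace equilibrium wall stress
#'
#' The wall stress that balances the transmural pressure for the current
#' geometry: `sigma_eq = P * r_i / h`.
#'
#' @param P pressure in Pa.
#' @param geom geometry list from [derive_geometry()] (needs `r_i`, `h`).
#' @return stress in Pa.
#' @export
laplace_stress <- function(P, geom) {
  if (any(geom$h == 0))
    stop("laplace_stress: wall thickness is zero", call. = FALSE)
  P * geom$r_i / geom$h
}

#' Poiseuille wall shear stress
#'
#' `tau = 4 * eta * Q / (pi * r_i^3)` for fully developed laminar flow at
#' constant viscosity.
#'
#' @param Q volume flow in m^3/s (>= 0).
#' @param r_i internal radius in m (> 0).
#' @inheritParams matrix_stress
#' @return shear stress in Pa.
#' @examples
#' wall_shear_stress(0.25e-9, 100e-6)  # about 1.11 Pa
#' @export
wall_shear_stress <- function(Q, r_i, params = vessel_params()) {
  if (any(r_i <= 0))
    .degenerate_geometry("wall_shear_stress: internal radius <= 0")
  4 * params$eta * Q / (pi * r_i^3)
}
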