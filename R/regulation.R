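# Tone set-point (Hill curves), model variants, and the 5-D state derivative.

# Hill activation; stimuli are clamped at zero from below so that negative
# equipotent agents (allowed behind a flag in protocols) saturate the curve
# at zero rather than producing poles.
.hill <- function(x, K, n) {
  x <- pmax(x, 0)
  x^n / (x^n + K^n)
}

#' Tone-reducing factor of shear stress and dilators
#'
#' Shear stress and endothelium-dependent dilators reduce tone by a common
#' fractional factor, `TRF = 1 - ecf * Hill(tau + DIL; tau_50, hd)`.
#' Endothelial cell function `ecf` scales the maximal achievable reduction;
#' `ecf = 0` abolishes shear/dilator-mediated dilation (TRF = 1 always).
#'
#' @param tau wall shear stress in Pa (>= 0).
#' @param DIL extrinsic dilator as equipotent shear stress in Pa.
#' @param params a [vessel_params()] object.
#' @return TRF in [1 - ecf, 1], monotone decreasing in `tau + DIL`.
#' @examples
#' tone_reducing_factor(5, 0)  # 0.5 at the half-maximal shear stimulus
#' @export
tone_reducing_factor <- function(tau, DIL = 0, params = vessel_params()) {
  1 - params$ecf * .hill(tau + DIL, params$tau_50, params$hd)
}

#' Equilibrium tone
#'
#' The tone towards which activation adapts once all acute kinetics have
#' settled: the myogenic Hill response to wall stress plus equipotent
#' constrictors, scaled by the tone-reducing factor,
#' `A_eq = Hill(sigma + CON; sigma_50, hc) * TRF`.
#'
#' @param sigma mean wall stress in Pa.
#' @param CON extrinsic constrictor as equipotent wall stress in Pa.
#' @param trf tone-reducing factor from [tone_reducing_factor()].
#' @inheritParams tone_reducing_factor
#' @return equilibrium tone in [0, 1].
#' @examples
#' equilibrium_tone(30000, 0, trf = 1)  # 0.5 at the half-activation stress
#' @export
equilibrium_tone <- function(sigma, CON = 0, trf = 1, params = vessel_params()) {
  pmin(pmax(.hill(sigma + CON, params$sigma_50, params$hc) * trf, 0), 1)
}

.VARIANTS <- list(
  MECH    = c(mech = TRUE, tone = FALSE, plasticity = FALSE, remodeling = FALSE, growth = FALSE),
  FUNCT   = c(mech = TRUE, tone = TRUE,  plasticity = FALSE, remodeling = FALSE, growth = FALSE),
  PLAST   = c(mech = TRUE, tone = TRUE,  plasticity = TRUE,  remodeling = FALSE, growth = FALSE),
  REMOD   = c(mech = TRUE, tone = TRUE,  plasticity = TRUE,  remodeling = TRUE,  growth = FALSE),
  GROWTH  = c(mech = TRUE, tone = TRUE,  plasticity = TRUE,  remodeling = TRUE,  growth = TRUE),
  FUNCTKO = c(mech = TRUE, tone = FALSE, plasticity = TRUE,  remodeling = TRUE,  growth = TRUE),
  PLASTKO = c(mech = TRUE, tone = TRUE,  plasticity = FALSE, remodeling = TRUE,  growth = TRUE),
  REMODKO = c(mech = TRUE, tone = TRUE,  plasticity = TRUE,  remodeling = FALSE, growth = TRUE)
)

#' Model variants and software knockouts
#'
#' A variant mask switches individual adaptation processes on or off by
#' zeroing their rate constants. The hierarchy MECH, FUNCT, PLAST, REMOD,
#' GROWTH adds processes one by one (mechanical strain relaxation is active
#' in every variant); FUNCTKO, PLASTKO and REMODKO are the full model with
#' exactly one process knocked out. A disabled process contributes a zero
#' rate, so its state component stays frozen at its initial value.
#'
#' @param name one of `"MECH"`, `"FUNCT"`, `"PLAST"`, `"REMOD"`, `"GROWTH"`,
#'   `"FUNCTKO"`, `"PLASTKO"`, `"REMODKO"`, or an existing mask.
#' @return a named logical vector of class `vessel_variant` with flags
#'   `mech`, `tone`, `plasticity`, `remodeling`, `growth`.
#' @examples
#' vessel_variant("FUNCTKO")
#' @export
vessel_variant <- function(name = "GROWTH") {
  if (inherits(name, "vessel_variant")) return(name)
  if (is.logical(name) && length(name) == 5L &&
      setequal(names(name), names(.VARIANTS$GROWTH))) {
    return(structure(name[names(.VARIANTS$GROWTH)], class = "vessel_variant",
                     variant = "custom"))
  }
  if (!is.character(name) || length(name) != 1L || !name %in% names(.VARIANTS))
    stop("unknown model variant; use one of ",
         paste(names(.VARIANTS), collapse = ", "), call. = FALSE)
  structure(.VARIANTS[[name]], class = "vessel_variant", variant = name)
}

#' @export
print.vessel_variant <- function(x, ...) {
  cat("Model variant:", attr(x, "variant"), "\n")
  cat("  active processes:",
      paste(names(x)[as.logical(x)], collapse = ", "), "\n")
  invisible(x)
}

#' Time derivative of the five-state vessel system
#'
#' Assembles the five first-order rate laws, each gated by the variant mask:
#' \itemize{
#'   \item strain relaxes towards mechanical equilibrium,
#'     `deps/dt = k_mech * (sigma_eq - sigma)`;
#'   \item tone follows its set point, `dA/dt = k_tone * (A_eq - A)`;
#'   \item SMC plasticity restores cell length to the reference,
#'     `dspan/dt = k_span * span * (l/l_ref) * (l_ref - l)`, so the relative
#'     rate of length change is proportional to the ratio of actual and
#'     reference cell length and vanishes at `l = l_ref`;
#'   \item eutrophic remodeling balances strain-driven outward against
#'     tone-driven inward rearrangement,
#'     `dr_mslack/dt = k_slack * r_mslack * (beta_strain*eps - alpha_tone*A)`;
#'   \item growth follows wall stress,
#'     `dwcsa/dt = k_growth * wcsa * (sigma - sigma_ref)`.
#' }
#' The strain entering the stress laws is floored at -0.5; at the floor,
#' further compressive rates are clamped to zero.
#'
#' @param t time in s (unused; the laws are autonomous given the inputs).
#' @param state named state vector (see [vessel_state()]).
#' @param inputs named vector or list with `P` (Pa), `Q` (m^3/s), `CON`,
#'   `DIL` (equipotent Pa).
#' @param params a [vessel_params()] object.
#' @param mask a [vessel_variant()] mask.
#' @return named numeric vector of the five rates (per second).
#' @export
state_derivative <- function(t, state, inputs, params = vessel_params(),
                             mask = vessel_variant("GROWTH")) {
  g <- .geometry(max(state[["eps"]], .EPS_FLOOR), state[["span"]],
                 state[["r_mslack"]], state[["wcsa"]])
  if (!is.finite(g$r_i) || g$r_i <= 0 || g$h < 0)
    .degenerate_geometry("state_derivative: degenerate geometry")
  .state_rates(state, inputs, params, mask)
}

# total (never-failing on transiently degenerate trial states) rate
# evaluation used inside the stiff solver; the internal radius is floored at
# 10 nm, three orders of magnitude below any collapse guard, so the clamp is
# only ever visible on trajectories already being terminated
.state_rates <- function(state, inputs, params, mask) {
  eps <- max(state[["eps"]], .EPS_FLOOR)
  tone <- min(max(state[["tone"]], 0), 1)
  g <- .geometry(eps, state[["span"]], state[["r_mslack"]], state[["wcsa"]])
  g$r_i <- max(g$r_i, 1e-8)
  sigma_p <- matrix_stress(eps, params)
  sigma_acap <- active_stress_capacity(g$l, params)
  sigma_c <- cytoskeletal_stress(g$l, params)
  sigma <- params$af_p * sigma_p + params$af_a * tone * sigma_acap +
    params$af_c * sigma_c
  sigma_eq <- if (g$h > 0) inputs[["P"]] * g$r_i / g$h else Inf
  tau <- 4 * params$eta * inputs[["Q"]] / (pi * g$r_i^3)
  trf <- tone_reducing_factor(tau, inputs[["DIL"]], params)
  a_eq <- equilibrium_tone(sigma, inputs[["CON"]], trf, params)

  d_eps <- params$k_mech * (sigma_eq - sigma)
  if (d_eps < 0) {
    # smooth approach to the strain floor: compressive rates ramp to zero
    # over the last 0.01 strain units, so the clamped state is an ordinary
    # equilibrium instead of a discontinuity the stiff solver chatters on
    ramp <- min(max((state[["eps"]] - .EPS_FLOOR) / 0.01, 0), 1)
    d_eps <- d_eps * ramp
  }
  d_tone <- params$k_tone * (a_eq - tone)
  d_span <- params$k_span * state[["span"]] * (g$l / params$l_ref) *
    (params$l_ref - g$l)
  d_slack <- params$k_slack * state[["r_mslack"]] *
    (params$beta_strain * eps - params$alpha_tone * tone)
  d_wcsa <- params$k_growth * state[["wcsa"]] * (sigma - params$sigma_ref)

  d <- c(eps = d_eps, tone = d_tone, span = d_span,
         r_mslack = d_slack, wcsa = d_wcsa) * as.numeric(mask)
  if (any(!is.finite(d)))
    stop("state_derivative: non-finite derivative", call. = FALSE)
  d
}

# deSolve-facing wrapper
.deriv_desolve <- function(t, y, parms) {
  list(.state_rates(y, parms$inputs, parms$params, parms$mask))
}
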