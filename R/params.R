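#' Model parameters of the vessel wall model
#'
#' Constructs the full parameter set of the single-segment resistance artery
#' model, in SI units. Defaults are the reference parameterization of a small
#' artery working at 80 mmHg and 0.25 µL/s. Any subset can be overridden by
#' name; the set is validated (composition closure, positivity, ranges)
#' before use.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Parameters (SI units):
#' \describe{
#'   \item{af_p, af_a, af_c}{area fractions of the wall covered by passive
#'     matrix, active contractile elements, and cytoskeleton; must sum to 1
#'     (defaults 1/3 each).}
#'   \item{c_p1, c_p2, c_p3, c_p4}{constants of the bi-exponential passive
#'     stress-strain curve (Pa, Pa, -, -; defaults 55000, 0.0186, 1.5, 24).}
#'   \item{l_opt, sigma_amax, l_w}{optimal SMC length (m), maximal active
#'     stress at that length (Pa), and width of the bell-shaped active curve
#'     (m); defaults 106.18 µm, 250000 Pa, 45.868 µm.}
#'   \item{c_c1, c_c2, c_c3}{cytoskeletal stretch brake: stress at length
#'     c_c3 (Pa), steepness, and anchor length (m); defaults 250000, 30,
#'     118.92 µm.}
#'   \item{hc, sigma_50}{Hill coefficient and half-activation wall stress of
#'     the myogenic activation curve (-, Pa); defaults 3 and 30000.}
#'   \item{hd, tau_50}{Hill coefficient and half-maximal shear stimulus of
#'     the dilation curve (-, Pa); defaults 3 and 5.}
#'   \item{ecf}{endothelial cell function; 1 = intact, 0 = full impairment
#'     of shear/dilator-mediated dilation. The physiological range is
#'     [0, 1]; values slightly above 1 (supra-normal dilatory gain) are
#'     admitted for sensitivity analysis around the default.}
#'   \item{l_ref}{reference SMC length for plasticity (m; default 80 µm).}
#'   \item{alpha_tone, beta_strain}{weights of tone-driven inward and
#'     strain-driven outward eutrophic remodeling (defaults 0.65 and 1).}
#'   \item{sigma_ref}{reference wall stress for the trophic response (Pa;
#'     default 30000).}
#'   \item{eta}{blood viscosity (Pa s; default 0.0035).}
#'   \item{k_mech, k_tone, k_span, k_slack, k_growth}{rate constants of the
#'     five first-order processes: mechanical strain relaxation
#'     (m2 N-1 s-1, 1e-6), tone (s-1, 0.005), SMC span plasticity
#'     (m-1 s-1, 3.75), slack-radius remodeling (s-1, 2e-5), wall growth
#'     (m2 N-1 s-1, 1e-10).}
#' }
#'
#' @return an object of class `vessel_params` (named list).
#' @examples
#' p <- vessel_params(ecf = 0.8)
#' p$ecf
#' @export
vessel_params <- function(...) {
  p <- list(
    af_p = 1 / 3, af_a = 1 / 3, af_c = 1 / 3,
    c_p1 = 55000, c_p2 = 0.0186, c_p3 = 1.5, c_p4 = 24,
    l_opt = 106.18e-6, sigma_amax = 250000, l_w = 45.868e-6,
    c_c1 = 250000, c_c2 = 30, c_c3 = 118.92e-6,
    hc = 3, sigma_50 = 30000,
    hd = 3, tau_50 = 5,
    ecf = 1,
    l_ref = 80e-6,
    alpha_tone = 0.65, beta_strain = 1,
    sigma_ref = 30000,
    eta = 0.0035,
    k_mech = 1e-6, k_tone = 0.005, k_span = 3.75,
    k_slack = 2e-5, k_growth = 1e-10
  )
  ov <- list(...)
  if (length(ov) == 1L && is.list(ov[[1L]]) && is.null(names(ov))) ov <- ov[[1L]]
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) {
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(ov)] <- ov
  }
  p <- structure(p, class = "vessel_params")
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks the invariants of the model parameters: area fractions in (0, 1)
#' summing to 1; strictly positive rate constants, Hill constants, lengths,
#' stresses and viscosity; `ecf` in [0, 1].
#'
#' @param p a `vessel_params` object.
#' @return `p`, invisibly; errors describe the offending parameter.
#' @export
validate_params <- function(p) {
  num1 <- function(nm) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    v
  }
  for (nm in c("af_p", "af_a", "af_c")) {
    v <- num1(nm)
    if (v <= 0 || v >= 1)
      stop("area fraction '", nm, "' must lie in (0, 1)", call. = FALSE)
  }
  if (abs(p$af_p + p$af_a + p$af_c - 1) > 1e-9)
    stop("area fractions af_p + af_a + af_c must sum to 1", call. = FALSE)
  pos <- c("c_p1", "c_p2", "c_p3", "c_p4", "l_opt", "sigma_amax", "l_w",
           "c_c1", "c_c2", "c_c3", "hc", "sigma_50", "hd", "tau_50",
           "l_ref", "alpha_tone", "beta_strain", "sigma_ref", "eta",
           "k_mech", "k_tone", "k_span", "k_slack", "k_growth")
  for (nm in pos) {
    if (num1(nm) <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  }
  ecf <- num1("ecf")
  if (ecf < 0)
    stop("parameter 'ecf' must be non-negative", call. = FALSE)
  invisible(p)
}

# numerical floor on matrix strain (slack matrix buckles; keeps geometry sane)
.EPS_FLOOR <- -0.5

#' Vessel state vector
#'
#' The model state: matrix strain `eps` (relative extension of the midwall
#' radius over its slack value), tone `tone` in [0, 1], SMC span `span`
#' (fraction of the circumference covered by one cell), slack midwall radius
#' `r_mslack` (m) and wall cross-sectional area `wcsa` (m^2).
#'
#' @param eps matrix strain (dimensionless, >= -0.5).
#' @param tone activation in [0, 1].
#' @param span SMC span, fraction of circumference (> 0).
#' @param r_mslack slack midwall radius (m, > 0).
#' @param wcsa wall cross-sectional area (m^2, >= 0).
#' @return named numeric vector of class `vessel_state`.
#' @examples
#' vessel_state(eps = 0.24, tone = 0.37, span = 0.16,
#'              r_mslack = 64.5e-6, wcsa = 1.21e-8)
#' @export
vessel_state <- function(eps, tone, span, r_mslack, wcsa) {
  s <- c(eps = eps, tone = tone, span = span, r_mslack = r_mslack, wcsa = wcsa)
  validate_state(s)
  structure(s, class = c("vessel_state", "numeric"))
}

#' @rdname vessel_state
#' @param s named numeric vector with the five state components.
#' @export
validate_state <- function(s) {
  need <- c("eps", "tone", "span", "r_mslack", "wcsa")
  if (!all(need %in% names(s)))
    stop("state must contain ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(is.finite(s[need]))) stop("non-finite state component", call. = FALSE)
  if (s[["eps"]] < .EPS_FLOOR)
    stop("eps below the numerical floor of ", .EPS_FLOOR, call. = FALSE)
  if (s[["tone"]] < 0 || s[["tone"]] > 1)
    stop("tone must lie in [0, 1]", call. = FALSE)
  if (s[["span"]] <= 0) stop("span must be strictly positive", call. = FALSE)
  if (s[["r_mslack"]] <= 0)
    stop("r_mslack must be strictly positive", call. = FALSE)
  if (s[["wcsa"]] < 0) stop("wcsa must be non-negative", call. = FALSE)
  invisible(s)
}

# generic physiological starting point for steady-state searches
.default_state0 <- function(params) {
  c(eps = 0.3, tone = 0.5, span = 1 / (2 * pi),
    r_mslack = 70e-6, wcsa = 1.5e-8)
}

#' @export
print.vessel_params <- function(x, ...) {
  cat("Resistance artery wall model parameters (SI units)\n")
  v <- unlist(x)
  def <- unlist(unclass(vessel_params()))
  tag <- ifelse(abs(v - def[names(v)]) > 0, " *", "")
  cat(sprintf("  %-11s %-12.6g%s\n", names(v), v, tag), sep = "")
  if (any(tag != "")) cat("  (* differs from default)\n")
  invisible(x)
}
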