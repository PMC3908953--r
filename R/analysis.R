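# Computational experiments: pressure-radius curves, step responses,
# steady-state maps, sensitivity matrix, dilator instability scan.

#' Quasi-static pressure-radius relation
#'
#' Traces the mechanical (no further adaptation) equilibrium radius against
#' pressure at the structure of a converged working point. `mode = "frozen"`
#' pins tone at the working-point value; `"passive"` and `"active"` pin it at
#' 0 and 1. Points are quasi-static equilibria obtained by root continuation
#' from the working point outward, so the physical branch is followed.
#'
#' @param P_grid pressures in Pa.
#' @param mode `"frozen"`, `"passive"` or `"active"`.
#' @param baseline a stable `vessel_steady`; by default the full model at
#'   default inputs.
#' @param params a [vessel_params()] object.
#' @param control a [sim_control()].
#' @return data.frame of class `vessel_prcurve` with `P` (Pa), `P_mmHg`,
#'   `eps`, `r_i` (m), `r_i_um`, plus NA rows flagged `degenerate` where no
#'   equilibrium was found.
#' @export
pressure_radius_curve <- function(P_grid = mmHg(seq(10, 140, by = 2.5)),
                                  mode = c("frozen", "passive", "active"),
                                  baseline = NULL,
                                  params = vessel_params(),
                                  control = sim_control()) {
  mode <- match.arg(mode)
  if (is.null(baseline))
    baseline <- vessel_steady_state(params = params, control = control,
                                    derived = FALSE)
  if (baseline$verdict != "stable")
    stop("baseline steady state is not stable", call. = FALSE)
  s <- baseline$state
  tone <- switch(mode, frozen = s[["tone"]], passive = 0, active = 1)
  P0 <- baseline$inputs[["P"]]
  ord <- order(abs(P_grid - P0))  # continuation outward from working point
  eps <- rep(NA_real_, length(P_grid))
  eps_seed <- s[["eps"]]
  # march towards low and high pressures separately, seeding each root with
  # the neighbouring solution
  for (dir in list(which(P_grid[ord] <= P0), which(P_grid[ord] > P0))) {
    seed <- eps_seed
    for (i in ord[dir]) {
      e <- tryCatch(
        mechanical_equilibrium(s[["span"]], s[["r_mslack"]], s[["wcsa"]],
                               tone, P_grid[i], params, eps_init = seed),
        error = function(e) NA_real_)
      eps[i] <- e
      if (is.finite(e)) seed <- e
    }
  }
  g <- .geometry(eps, s[["span"]], s[["r_mslack"]], s[["wcsa"]])
  out <- data.frame(P = P_grid, P_mmHg = to_mmHg(P_grid), eps = eps,
                    r_i = g$r_i, r_i_um = to_um(g$r_i),
                    degenerate = !is.finite(eps) | g$r_i <= 0)
  structure(out[order(out$P), ],
            class = c("vessel_prcurve", "data.frame"),
            mode = mode, tone = tone, baseline = baseline)
}

#' @export
plot.vessel_prcurve <- function(x, ...) {
  plot(x$P_mmHg, x$r_i_um, type = "l", xlab = "pressure (mmHg)",
       ylab = "internal radius (um)",
       main = paste0("pressure-radius (", attr(x, "mode"), ")"))
  invisible(x)
}

#' Step response of a model variant
#'
#' Starts the chosen variant at the default working point (the full-model
#' steady state under default inputs; components the variant freezes stay
#' pinned there) and applies a step change of one or more inputs at t = 0.
#' Output times are log-spaced, covering the full range of time scales from
#' acute mechanics to trophic adaptation.
#'
#' @param variant variant name or mask.
#' @param P,Q,CON,DIL post-step inputs (SI); defaults keep the pre-step
#'   value.
#' @param t_end horizon in s.
#' @param params a [vessel_params()] object.
#' @param control a [sim_control()].
#' @return a `vessel_sim` trajectory; the pre-step working point is in
#'   attribute `baseline`.
#' @examples
#' \donttest{
#' sr <- step_response("GROWTH", P = mmHg(100), t_end = 1e7)
#' }
#' @export
step_response <- function(variant = "GROWTH", P = NULL, Q = NULL,
                          CON = NULL, DIL = NULL, t_end = 1e8,
                          params = vessel_params(),
                          control = sim_control()) {
  base <- .default_baseline(params, control)
  if (base$verdict != "stable")
    stop("default working point did not converge", call. = FALSE)
  prot <- stimulus_protocol(
    P = if (is.null(P)) base$inputs[["P"]] else P,
    Q = if (is.null(Q)) base$inputs[["Q"]] else Q,
    CON = if (is.null(CON)) base$inputs[["CON"]] else CON,
    DIL = if (is.null(DIL)) base$inputs[["DIL"]] else DIL)
  sim <- simulate_vessel(prot, variant = variant, params = params,
                         state0 = base$state, t_end = t_end,
                         control = control)
  attr(sim, "baseline") <- base
  sim
}

#' Steady-state response map over input grids
#'
#' Recomputes the steady state of each variant while one input at a time is
#' varied over a grid, the others held at their defaults; the paper-style
#' homeostasis map. Instabilities are recorded as verdicts, not errors.
#'
#' @param variants character vector of variant names.
#' @param P_grid,Q_grid,CON_grid,DIL_grid grids in SI units; each is varied
#'   one-at-a-time around the default inputs.
#' @param params a [vessel_params()] object.
#' @param control a [sim_control()].
#' @return data.frame of class `vessel_map`: one row per (variant, input,
#'   value) with the verdict, the nine steady-state outputs and their ratios
#'   to that variant's default steady state.
#' @export
steady_state_map <- function(variants = c("MECH", "FUNCT", "PLAST", "REMOD",
                                          "GROWTH", "PLASTKO", "REMODKO"),
                             P_grid = mmHg(seq(40, 160, by = 20)),
                             Q_grid = uL_per_s(0.0625 * 2^(0:4)),
                             CON_grid = 1000 * seq(0, 30, by = 7.5),
                             DIL_grid = seq(0, 3, by = 0.75),
                             params = vessel_params(),
                             control = sim_control()) {
  defaults <- c(P = mmHg(80), Q = uL_per_s(0.25), CON = 0, DIL = 0)
  grids <- list(P = P_grid, Q = Q_grid, CON = CON_grid, DIL = DIL_grid)
  rows <- list()
  for (v in variants) {
    base <- vessel_steady_state(variant = v, params = params,
                                control = control)
    for (input in names(grids)) {
      for (val in grids[[input]]) {
        inp <- defaults
        inp[input] <- val
        ss <- vessel_steady_state(P = inp[["P"]], Q = inp[["Q"]],
                                  CON = inp[["CON"]], DIL = inp[["DIL"]],
                                  variant = v, params = params,
                                  control = control)
        rel <- if (base$verdict == "stable") ss$derived / base$derived
               else rep(NA_real_, length(ss$derived))
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, input = input, value = val,
          verdict = ss$verdict, t(ss$derived),
          t(setNames(rel, paste0(names(ss$derived), "_rel"))))
      }
    }
  }
  structure(do.call(rbind, rows), class = c("vessel_map", "data.frame"),
            defaults = defaults)
}

#' Steady-state parameter sensitivity matrix
#'
#' Central-difference relative sensitivities of the steady-state outputs to
#' model parameters around their defaults: entry (i, j) is the relative
#' change of output i divided by the relative change of parameter j, with
#' each parameter perturbed by `+-rel_step` (default 5%; 50% mirrors a
#' half-to-double variation study). Entries are NA when a perturbed model
#' has no stable steady state.
#'
#' @param param_names parameters to perturb.
#' @param output_names steady-state outputs (rows).
#' @param rel_step relative perturbation (0.05 = +-5%).
#' @param variant variant name (the full model by default).
#' @param params a [vessel_params()] object.
#' @param control a [sim_control()].
#' @return matrix of class `vessel_sensitivity` (outputs x parameters), with
#'   the baseline `vessel_steady` in attribute `baseline`.
#' @examples
#' \donttest{
#' S <- sensitivity_matrix()
#' S["l", "l_ref"]       # 1: cell length tracks its reference one-for-one
#' }
#' @export
sensitivity_matrix <- function(param_names = c("ecf", "l_ref", "beta_strain",
                                               "sigma_ref"),
                               output_names = c("r_i", "tone", "l",
                                                "r_islack", "wcsa", "sigma",
                                                "tau", "tension_match",
                                                "radius_reserve"),
                               rel_step = 0.05, variant = "GROWTH",
                               params = vessel_params(),
                               control = sim_control()) {
  base <- vessel_steady_state(variant = variant, params = params,
                              control = control)
  if (base$verdict != "stable")
    stop("no stable baseline steady state", call. = FALSE)
  S <- matrix(NA_real_, length(output_names), length(param_names),
              dimnames = list(output_names, param_names))
  for (pn in param_names) {
    out <- lapply(c(1 + rel_step, 1 - rel_step), function(f) {
      pf <- unclass(params)
      pf[[pn]] <- pf[[pn]] * f
      vessel_steady_state(variant = variant, params = vessel_params(pf),
                          control = control)
    })
    if (all(vapply(out, function(s) s$verdict == "stable", logical(1)))) {
      S[, pn] <- (out[[1]]$derived[output_names] -
                    out[[2]]$derived[output_names]) /
        base$derived[output_names] / (2 * rel_step)
    }
  }
  structure(S, class = c("vessel_sensitivity", "matrix"),
            rel_step = rel_step, baseline = base)
}

#' @export
print.vessel_sensitivity <- function(x, digits = 3, ...) {
  cat("Steady-state sensitivity matrix (relative change in output per ",
      "relative change in parameter;\n step +-",
      100 * attr(x, "rel_step"), "%):\n", sep = "")
  m <- x
  attributes(m) <- list(dim = dim(x), dimnames = dimnames(x))
  print(round(m, digits))
  invisible(x)
}

#' Dilator instability scan
#'
#' Computes the full-model steady state over a grid of extrinsic dilator
#' levels. Over the stable range the steady-state shear stress falls exactly
#' as the dilator rises, keeping the total dilatory stimulus `tau + DIL`
#' constant; above that level no steady state exists and the radius runs
#' away. Reported in dyn/cm2, the conventional unit for shear.
#'
#' @param DIL_grid dilator levels in Pa.
#' @param P,Q pressure and flow (SI), default working conditions.
#' @param params a [vessel_params()] object.
#' @param control a [sim_control()].
#' @return data.frame of class `vessel_dilator_scan` with columns `DIL`
#'   (Pa), `DIL_dyn_cm2`, `tau_dyn_cm2`, `sum_dyn_cm2`, `verdict`; the
#'   largest stable dilator level (Pa) is in attribute `threshold`.
#' @export
dilator_scan <- function(DIL_grid = seq(0, 5, by = 0.25), P = mmHg(80),
                         Q = uL_per_s(0.25), params = vessel_params(),
                         control = sim_control()) {
  rows <- lapply(DIL_grid, function(d) {
    ss <- vessel_steady_state(P = P, Q = Q, DIL = d, params = params,
                              control = control, derived = FALSE)
    tau <- if (ss$verdict == "stable") ss$derived[["tau"]] else NA_real_
    data.frame(DIL = d, DIL_dyn_cm2 = to_dyn_cm2(d),
               tau_dyn_cm2 = to_dyn_cm2(tau),
               sum_dyn_cm2 = to_dyn_cm2(tau + d), verdict = ss$verdict)
  })
  out <- do.call(rbind, rows)
  stable <- out$DIL[out$verdict == "stable"]
  structure(out, class = c("vessel_dilator_scan", "data.frame"),
            threshold = if (length(stable)) max(stable) else NA_real_)
}

#' @export
print.vessel_dilator_scan <- function(x, ...) {
  cat("Dilator scan:", nrow(x), "levels;",
      sum(x$verdict == "stable"), "stable\n")
  s <- x$sum_dyn_cm2[x$verdict == "stable"]
  if (length(s))
    cat("  tau + DIL over stable range:", signif(mean(s), 4),
        "dyn/cm2 (range", signif(min(s), 4), "-", signif(max(s), 4), ")\n")
  cat("  largest stable DIL:", signif(to_dyn_cm2(attr(x, "threshold")), 4),
      "dyn/cm2\n")
  invisible(x)
}
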