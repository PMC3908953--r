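# Configuration loading, built-in scenarios, and result writers.

# tiny deterministic polynomial hash for provenance stamps
.cfg_hash <- function(x) {
  b <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 0
  for (v in b) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Load a run configuration
#'
#' Reads a YAML configuration and resolves it against the model defaults.
#' Recognized sections: `params` (overrides by parameter name), `variant`,
#' `units` (`SI` or `clinical`, applying to the protocol entries), `protocol`
#' (list of segments with `t_start`, `P`, `Q`, `CON`, `DIL`), `solver`
#' (`rtol`, `atol`, `t_end`), `guards` (`lo`, `hi`). Unknown parameter names
#' are rejected; overrides are validated against the parameter invariants;
#' clinically implausible magnitudes trigger unit-heuristic warnings.
#'
#' @param path path to a YAML file, or a list with the same structure.
#' @return list of class `run_config` with elements `params`
#'   ([vessel_params()]), `variant`, `protocol` ([stimulus_protocol()]),
#'   `control` ([sim_control()]), `units` and a provenance `hash`.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg)) cfg <- list()
  known <- c("params", "variant", "units", "protocol", "solver", "guards")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  units <- cfg$units %||% "SI"
  if (!units %in% c("SI", "clinical"))
    stop("units must be 'SI' or 'clinical'", call. = FALSE)
  params <- do.call(vessel_params, as.list(cfg$params %||% list()))
  variant <- vessel_variant(cfg$variant %||% "GROWTH")
  prot <- if (is.null(cfg$protocol)) {
    stimulus_protocol()
  } else {
    def_P <- if (units == "clinical") 80 else mmHg(80)
    def_Q <- if (units == "clinical") 0.25 else uL_per_s(0.25)
    seg <- do.call(rbind, lapply(cfg$protocol, function(s) {
      data.frame(t_start = s$t_start %||% 0, P = s$P %||% def_P,
                 Q = s$Q %||% def_Q, CON = s$CON %||% 0, DIL = s$DIL %||% 0)
    }))
    if (units == "clinical") {
      if (any(seg$P > 400))
        warning("clinical pressures above 400 mmHg; value given in Pa?",
                call. = FALSE)
    } else if (any(seg$P > 0 & seg$P < 300)) {
      warning("SI pressures below 300 Pa; value given in mmHg?",
              call. = FALSE)
    }
    stimulus_protocol(P = seg$P, Q = seg$Q, CON = seg$CON, DIL = seg$DIL,
                      t_start = seg$t_start, units = units)
  }
  ctl_args <- list()
  if (!is.null(cfg$solver)) {
    if (!is.null(cfg$solver$rtol)) ctl_args$rtol <- cfg$solver$rtol
    if (!is.null(cfg$solver$t_end)) ctl_args$t_end <- cfg$solver$t_end
    if (!is.null(cfg$solver$atol))
      ctl_args$atol <- unlist(cfg$solver$atol)[c("eps", "tone", "span",
                                                 "r_mslack", "wcsa")]
  }
  if (!is.null(cfg$guards)) {
    if (!is.null(cfg$guards$lo)) ctl_args$guard_lo <- cfg$guards$lo
    if (!is.null(cfg$guards$hi)) ctl_args$guard_hi <- cfg$guards$hi
  }
  control <- do.call(sim_control, ctl_args)
  out <- list(params = params, variant = variant, protocol = prot,
              control = control, units = units)
  out$hash <- .cfg_hash(out[c("params", "variant", "protocol", "control")])
  structure(out, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat("run_config (hash", x$hash, ")\n")
  cat("  variant:", attr(x$variant, "variant"), " units:", x$units, "\n")
  print(x$protocol)
  invisible(x)
}

#' Built-in scenario fixtures
#'
#' Named, self-contained configurations reproducing the package's standard
#' computational experiments: `fig3_curves` (quasi-static pressure-radius
#' relations at the working point), `fig4_pressure_step` (pressure step 80 to
#' 100 mmHg across the variant hierarchy), `fig4_flow_step` (flow doubling
#' 0.25 to 0.5 µL/s), `fig5_map` (steady-state response maps),
#' `table3_sensitivity` (parameter sensitivity matrix) and `dilator_scan`
#' (instability threshold scan). Run one with [run_scenario()].
#'
#' @return named list of scenario descriptions.
#' @export
builtin_scenarios <- function() {
  list(
    fig3_curves = list(task = "pr_curves",
                       P_grid_mmHg = seq(10, 140, by = 2.5)),
    fig4_pressure_step = list(task = "step",
                              variants = c("MECH", "FUNCT", "PLAST",
                                           "REMOD", "GROWTH"),
                              P_mmHg = 100, t_end = 1e8),
    fig4_flow_step = list(task = "step",
                          variants = c("MECH", "FUNCT", "PLAST",
                                       "REMOD", "GROWTH"),
                          Q_uL_s = 0.5, t_end = 1e8),
    fig5_map = list(task = "map"),
    table3_sensitivity = list(task = "sensitivity", rel_step = 0.05),
    dilator_scan = list(task = "dilator_scan",
                        DIL_dyn_cm2 = seq(0, 50, by = 2.5))
  )
}

#' Run a built-in scenario
#'
#' @param name a scenario name from [builtin_scenarios()].
#' @param params a [vessel_params()] object.
#' @param control a [sim_control()].
#' @return the scenario's result object (curves, trajectories, map,
#'   sensitivity matrix or scan table).
#' @export
run_scenario <- function(name, params = vessel_params(),
                         control = sim_control()) {
  sc <- builtin_scenarios()[[name]]
  if (is.null(sc)) stop("unknown scenario '", name, "'", call. = FALSE)
  switch(
    sc$task,
    pr_curves = {
      base <- vessel_steady_state(params = params, control = control)
      lapply(setNames(nm = c("frozen", "passive", "active")), function(m)
        pressure_radius_curve(mmHg(sc$P_grid_mmHg), mode = m,
                              baseline = base, params = params,
                              control = control))
    },
    step = lapply(setNames(nm = sc$variants), function(v)
      step_response(v,
                    P = if (!is.null(sc$P_mmHg)) mmHg(sc$P_mmHg),
                    Q = if (!is.null(sc$Q_uL_s)) uL_per_s(sc$Q_uL_s),
                    t_end = sc$t_end, params = params, control = control)),
    map = steady_state_map(params = params, control = control),
    sensitivity = sensitivity_matrix(rel_step = sc$rel_step, params = params,
                                     control = control),
    dilator_scan = dilator_scan(dyn_cm2(sc$DIL_dyn_cm2), params = params,
                                control = control),
    stop("unknown task '", sc$task, "'", call. = FALSE)
  )
}

#' Write a time series as annotated CSV
#'
#' One row per time point with SI columns for the state, derived geometry
#' and stresses and the active inputs, plus clinical-unit convenience
#' columns (µm, mmHg, µL/s, dyn/cm2). Run metadata (package version,
#' variant, verdict, solver tolerances, resolved parameters, each with its
#' unit) is written as `#`-prefixed header lines.
#'
#' @param ts a `vessel_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  params <- attr(ts, "params")
  control <- attr(ts, "control")
  hdr <- c(
    paste0("# vesseladapt ", as.character(packageVersion("vesseladapt")),
           " time series"),
    paste0("# variant: ", attr(attr(ts, "variant"), "variant")),
    paste0("# verdict: ", attr(ts, "verdict")),
    paste0("# solver: rtol=", control$rtol, " atol=",
           paste(names(control$atol), control$atol, sep = "=",
                 collapse = " ")),
    "# deterministic: yes (no stochastic terms in the model)",
    paste0("# params_SI: ",
           paste(names(params), vapply(params, format, ""), sep = "=",
                 collapse = " ")),
    paste0("# units: time=s lengths=m stresses=Pa flow=m3/s; _um=um",
           " _mmHg=mmHg _uL_s=uL/s _dyn_cm2=dyn/cm2")
  )
  df <- as.data.frame(ts)
  df$r_i_um <- to_um(df$r_i)
  df$l_um <- to_um(df$l)
  df$r_islack_um <- to_um(df$r_islack)
  df$P_mmHg <- to_mmHg(df$P)
  df$Q_uL_s <- to_uL_per_s(df$Q)
  df$tau_dyn_cm2 <- to_dyn_cm2(df$tau)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(df, digits = 15, trim = TRUE), con, sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @return `read_timeseries()` returns the data.frame (header comments
#'   skipped).
#' @export
read_timeseries <- function(path) {
  read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Write a structured result report as JSON
#'
#' Serializes steady states, maps, sensitivity matrices or dilator scans
#' with full provenance: package version, solver tolerances, resolved SI
#' parameters, a configuration hash and a determinism note. Runaway or
#' collapsed runs keep their verdict and last valid state.
#'
#' @param x a `vessel_steady`, `vessel_map`, `vessel_sensitivity` or
#'   `vessel_dilator_scan`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  meta <- list(
    package = paste0("vesseladapt ",
                     as.character(packageVersion("vesseladapt"))),
    deterministic = "yes (no stochastic terms in the model)")
  body <- if (inherits(x, "vessel_steady")) {
    meta$solver <- x$control[c("rtol", "atol", "t_end", "root_tol")]
    meta$params_SI <- unclass(x$params)
    meta$config_hash <- .cfg_hash(list(x$params, x$inputs,
                                    attr(x$variant, "variant")))
    list(kind = "steady_state", variant = attr(x$variant, "variant"),
         inputs_SI = as.list(x$inputs), verdict = x$verdict,
         residual_scaled = x$residual, state = as.list(x$state),
         derived_SI = as.list(x$derived))
  } else if (inherits(x, "vessel_sensitivity")) {
    b <- attr(x, "baseline")
    meta$params_SI <- unclass(b$params)
    meta$config_hash <- .cfg_hash(list(b$params, attr(x, "rel_step")))
    m <- x; attributes(m) <- list(dim = dim(x), dimnames = dimnames(x))
    list(kind = "sensitivity", rel_step = attr(x, "rel_step"), matrix = m)
  } else if (inherits(x, "vessel_dilator_scan")) {
    meta$config_hash <- .cfg_hash(as.data.frame(x)$DIL)
    list(kind = "dilator_scan", threshold_Pa = attr(x, "threshold"),
         table = as.data.frame(x))
  } else if (inherits(x, "vessel_map")) {
    meta$config_hash <- .cfg_hash(attr(x, "defaults"))
    list(kind = "steady_state_map", defaults_SI = as.list(attr(x, "defaults")),
         table = as.data.frame(x))
  } else stop("write_report: unsupported object", call. = FALSE)
  jsonlite::write_json(c(list(meta = meta), body), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
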