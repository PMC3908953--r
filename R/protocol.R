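#' Piecewise-constant stimulus protocol
#'
#' A protocol is an ordered set of segments, each holding pressure, flow and
#' the two equipotent vasoactive inputs constant from its start time until
#' the next segment. Vectors are recycled to the longest length. The first
#' segment must start at t = 0.
#'
#' @param P pressure per segment; Pa in SI mode, mmHg in clinical mode.
#' @param Q flow per segment; m^3/s in SI mode, µL/s in clinical mode.
#' @param CON extrinsic constrictor, equipotent wall stress; Pa in SI mode,
#'   kPa in clinical mode.
#' @param DIL extrinsic dilator, equipotent shear stress; Pa in SI mode,
#'   dyn/cm2 in clinical mode.
#' @param t_start segment start times in s, strictly increasing from 0.
#' @param units `"SI"` (default) or `"clinical"`.
#' @param allow_negative allow negative CON/DIL (endothelium-independent
#'   dilation / endothelium-dependent constriction as negative equipotent
#'   stimuli). Off by default.
#' @return data.frame of class `stimulus_protocol` with SI columns
#'   `t_start`, `P`, `Q`, `CON`, `DIL`.
#' @examples
#' # step in pressure from 80 to 100 mmHg at t = 0 (single post-step segment)
#' stimulus_protocol(P = 100, Q = 0.25, units = "clinical")
#' @export
stimulus_protocol <- function(P = mmHg(80), Q = uL_per_s(0.25), CON = 0,
                              DIL = 0, t_start = 0,
                              units = c("SI", "clinical"),
                              allow_negative = FALSE) {
  units <- match.arg(units)
  n <- max(length(P), length(Q), length(CON), length(DIL), length(t_start))
  seg <- data.frame(t_start = rep_len(t_start, n), P = rep_len(P, n),
                    Q = rep_len(Q, n), CON = rep_len(CON, n),
                    DIL = rep_len(DIL, n))
  if (units == "clinical") {
    seg$P <- mmHg(seg$P)
    seg$Q <- uL_per_s(seg$Q)
    seg$CON <- seg$CON * 1000     # kPa -> Pa
    seg$DIL <- dyn_cm2(seg$DIL)
  }
  if (seg$t_start[1] != 0)
    stop("the first protocol segment must start at t = 0", call. = FALSE)
  if (n > 1 && any(diff(seg$t_start) <= 0))
    stop("segment start times must be strictly increasing", call. = FALSE)
  if (any(seg$P < 0) || any(seg$Q < 0))
    stop("P and Q must be non-negative", call. = FALSE)
  if (!allow_negative && (any(seg$CON < 0) || any(seg$DIL < 0)))
    stop("negative CON/DIL require allow_negative = TRUE", call. = FALSE)
  structure(seg, class = c("stimulus_protocol", "data.frame"), units = units)
}

#' @rdname stimulus_protocol
#' @param protocol a `stimulus_protocol`.
#' @param t time in s.
#' @return `protocol_inputs()` returns the named input vector
#'   `c(P, Q, CON, DIL)` (SI) active at time `t`.
#' @export
protocol_inputs <- function(protocol, t) {
  i <- findInterval(t, protocol$t_start)
  i <- max(i, 1L)
  c(P = protocol$P[i], Q = protocol$Q[i], CON = protocol$CON[i],
    DIL = protocol$DIL[i])
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("Stimulus protocol (", nrow(x), " segment",
      if (nrow(x) > 1) "s", "):\n", sep = "")
  show <- data.frame(t_start_s = x$t_start, P_mmHg = to_mmHg(x$P),
                     Q_uL_s = to_uL_per_s(x$Q), CON_kPa = x$CON / 1000,
                     DIL_dyn_cm2 = to_dyn_cm2(x$DIL))
  print(show, row.names = FALSE, digits = 4)
  invisible(x)
}
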