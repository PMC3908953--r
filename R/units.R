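# All internal computation is strict SI; clinical units exist only at the
# I/O boundary. Conversions are exact constants.

#' Unit conversions between SI and clinical units
#'
#' The model runs in SI units (Pa, m, m^3/s). Inputs and results are often
#' quoted in clinical units: pressure in mmHg, flow in µL/s, shear stress in
#' dyn/cm2, lengths in µm. These helpers convert to SI (`mmHg()`,
#' `dyn_cm2()`, `uL_per_s()`, `um()`) and back (`to_mmHg()`, `to_dyn_cm2()`,
#' `to_uL_per_s()`, `to_um()`). 1 mmHg = 133.322 Pa; 1 dyn/cm2 = 0.1 Pa;
#' 1 µL/s = 1e-9 m^3/s.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' mmHg(80)          # 10665.76 Pa
#' to_dyn_cm2(3.5)   # 35 dyn/cm2
#' @name units
NULL

.MMHG_PA <- 133.322
.DYNCM2_PA <- 0.1
.ULS_M3S <- 1e-9

#' @rdname units
#' @export
mmHg <- function(x) x * .MMHG_PA

#' @rdname units
#' @export
to_mmHg <- function(x) x / .MMHG_PA

#' @rdname units
#' @export
dyn_cm2 <- function(x) x * .DYNCM2_PA

#' @rdname units
#' @export
to_dyn_cm2 <- function(x) x / .DYNCM2_PA

#' @rdname units
#' @export
uL_per_s <- function(x) x * .ULS_M3S

#' @rdname units
#' @export
to_uL_per_s <- function(x) x / .ULS_M3S

#' @rdname units
#' @export
um <- function(x) x * 1e-6

#' @rdname units
#' @export
to_um <- function(x) x * 1e6
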