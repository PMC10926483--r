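# Dose and concentration arithmetic for chronic feeding exposures.
# ppb is interpreted as ng of active ingredient per mL of feeding solution.

#' Convert a feeding concentration from ppb to nanomolar
#'
#' `conc * 1000 / mw` (ng/mL to nmol/L). For example 50 ppb imidacloprid
#' (MW 255.66 g/mol) is 195 nM and 50 ppb sulfoxaflor (MW 277.27 g/mol) is
#' 180 nM, taking the integer part as is conventional when reporting feeding
#' concentrations.
#'
#' @param conc concentration in ppb (ng active ingredient per mL solution).
#' @param mw molecular weight in g/mol.
#' @return concentration in nM.
#' @export
ppb_to_nanomolar <- function(conc, mw) {
  if (any(conc <= 0) || any(mw <= 0))
    stop_invalid("conc and mw must be > 0")
  conc * 1000 / mw
}

#' @rdname ppb_to_nanomolar
#' @param nm concentration in nM.
#' @export
nanomolar_to_ppb <- function(nm, mw) {
  if (any(nm <= 0) || any(mw <= 0)) stop_invalid("nm and mw must be > 0")
  nm * mw / 1000
}

#' Daily active-ingredient dose from consumption
#'
#' `volume * conc / 1000`: microliters consumed per day times ng/mL gives
#' ng of active ingredient per day. A bee consuming 46.1 ul/day of a 50 ppb
#' solution receives 2.3 ng/day.
#'
#' @param volume consumption in ul per animal per day (>= 0).
#' @param conc solution concentration in ppb.
#' @return dose in ng active ingredient per day.
#' @export
daily_dose <- function(volume, conc) {
  if (any(volume < 0) || any(conc < 0)) stop_invalid("inputs must be >= 0")
  volume * conc / 1000
}
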