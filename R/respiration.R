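## Reactor respiration mass balances: CO2 evolution rate (CER), O2 uptake
## rate (OUR), and numerical integration over the incubation.

#' Carbon dioxide evolution rate from a gas mass balance
#'
#' CER = F * (CO2_out - CO2_in), in mg CO2 day^-1 gdw^-1, where F is the
#' air flow rate (mg air day^-1 gdw^-1) and the concentrations are mass
#' fractions (mg CO2 per mg air) in the effluent and influent air.
#'
#' @param F air flow rate(s), mg air day^-1 gdw^-1; must be > 0
#' @param co2Out,co2In CO2 mass fractions in effluent / influent air
#' @return CER, mg CO2 day^-1 gdw^-1
#' @export
cer <- function(F, co2Out, co2In) {
  if (any(F <= 0)) stop("air flow rate F must be > 0")
  F * (co2Out - co2In)
}

#' Oxygen uptake rate from a gas mass balance
#'
#' OUR = F * (O2_in - O2_out), in mg O2 day^-1 gdw^-1; uptake is positive
#' when the effluent carries less oxygen than the influent.
#'
#' @param F air flow rate(s), mg air day^-1 gdw^-1; must be > 0
#' @param o2In,o2Out O2 mass fractions in influent / effluent air
#' @return OUR, mg O2 day^-1 gdw^-1
#' @export
our <- function(F, o2In, o2Out) {
  if (any(F <= 0)) stop("air flow rate F must be > 0")
  F * (o2In - o2Out)
}

#' Respiration rates for a gas time series
#'
#' @param gas data.frame with columns \code{t_day}, \code{F},
#'   \code{co2_in}, \code{co2_out}, \code{o2_in}, \code{o2_out} and
#'   optionally \code{event}
#' @return the input with added \code{cer} and \code{our} columns
#' @export
respirationRates <- function(gas) {
  need <- c("t_day", "F", "co2_in", "co2_out", "o2_in", "o2_out")
  if (!all(need %in% names(gas)))
    stop("gas series needs columns: ", paste(need, collapse = ", "))
  if (is.unsorted(gas$t_day, strictly = TRUE))
    stop("sample times must be strictly increasing")
  if (any(c(gas$co2_in, gas$co2_out, gas$o2_in, gas$o2_out) < 0))
    stop("gas concentrations must be non-negative")
  gas$cer <- cer(gas$F, gas$co2_out, gas$co2_in)
  gas$our <- our(gas$F, gas$o2_in, gas$o2_out)
  gas
}

#' Integrate a respiration rate series over a time window
#'
#' Composite trapezoid over the sample times. Event-flagged points
#' (mixing, water addition) are real data and are included; gaps are
#' simply spanned by the trapezoid, not interpolated.
#'
#' @param t sample times (days), strictly increasing
#' @param value rate values aligned to \code{t}
#' @param window length-2 numeric, integration window in days; defaults to
#'   the full series. Window ends falling between samples are included by
#'   linear interpolation at the window boundary.
#' @return cumulative gas, mg gdw^-1
#' @export
integrateRates <- function(t, value, window = range(t)) {
  if (is.unsorted(t, strictly = TRUE))
    stop("sample times must be strictly increasing")
  keep <- t >= window[1] & t <= window[2]
  tt <- t[keep]; vv <- value[keep]
  if (window[1] < min(t) || window[2] > max(t))
    stop("window extends beyond the sampled times")
  if (!length(tt) || tt[1] > window[1]) {
    tt <- c(window[1], tt)
    vv <- c(approx(t, value, xout = window[1])$y, vv)
  }
  if (tt[length(tt)] < window[2]) {
    tt <- c(tt, window[2])
    vv <- c(vv, approx(t, value, xout = window[2])$y)
  }
  if (length(tt) < 2L) stop("need at least two points in the window")
  pracma::trapz(tt, vv)
}

#' Read a gas time-series CSV
#'
#' @param path CSV with header \code{t_day, F, co2_in, co2_out, o2_in,
#'   o2_out, event}
#' @return data.frame
#' @export
readGasSeries <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Summarise respiration over the incubation
#'
#' @param gas data.frame as for [respirationRates()]
#' @return list with peak rates, their times, and cumulative totals
#' @export
respirationSummary <- function(gas) {
  r <- respirationRates(gas)
  list(peakCER = max(r$cer), peakCERDay = r$t_day[which.max(r$cer)],
       peakOUR = max(r$our), peakOURDay = r$t_day[which.max(r$our)],
       totalCO2 = integrateRates(r$t_day, r$cer),
       totalO2 = integrateRates(r$t_day, r$our))
}
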