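#' Standard-atmosphere constants
#'
#' Constants of the hypsometric conversion between barometric pressure and
#' altitude under the ISO standard atmosphere with a linear temperature
#' lapse: sea-level temperature `T0` (K), lapse rate `L` (K/m), sea-level
#' pressure `P0` (hPa), gravitational acceleration `g` (m/s^2) and the
#' specific gas constant of air `R0` (J/kg/K).
#'
#' @param T0,L,P0,g,R0 override individual constants; all must be positive.
#' @return A named list of class `"atmosphere_constants"`.
#' @export
atmosphere_constants <- function(T0 = 288.15, L = 0.0065, P0 = 1013.25,
                                 g = 9.8, R0 = 287.058) {
  vals <- list(T0 = T0, L = L, P0 = P0, g = g, R0 = R0)
  if (any(vapply(vals, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1))))
    stopf("all atmosphere constants must be single positive numbers")
  structure(vals, class = "atmosphere_constants")
}

#' Convert barometric pressure to altitude
#'
#' Hypsometric formula: `h = (T0/L) * (1 - (P/P0)^(R0*L/g))`, giving metres
#' above sea level for pressure in hPa. Strictly decreasing in `P`; the
#' algebraic inverse is [altitude_to_pressure()].
#'
#' @param pressure_hpa pressure in hPa; must be strictly positive.
#' @param constants an [atmosphere_constants()] object.
#' @return Altitude in metres above sea level, same length as `pressure_hpa`.
#' @examples
#' pressure_to_altitude(1013.25)  # 0 masl
#' pressure_to_altitude(540)      # just above 5000 masl
#' @export
pressure_to_altitude <- function(pressure_hpa,
                                 constants = atmosphere_constants()) {
  if (any(!is.finite(pressure_hpa) | pressure_hpa <= 0))
    stopf("pressure must be finite and strictly positive (hPa)")
  with(constants, (T0 / L) * (1 - (pressure_hpa / P0)^(R0 * L / g)))
}

#' Convert altitude to barometric pressure
#'
#' Exact algebraic inverse of [pressure_to_altitude()]:
#' `P = P0 * (1 - h*L/T0)^(g/(R0*L))`. Defined for altitudes below the
#' singular height `T0/L` (about 44.3 km), where the linear-lapse
#' atmosphere runs out of temperature.
#'
#' @param altitude_masl altitude in metres above sea level.
#' @param constants an [atmosphere_constants()] object.
#' @return Pressure in hPa.
#' @export
altitude_to_pressure <- function(altitude_masl,
                                 constants = atmosphere_constants()) {
  ceiling_m <- constants$T0 / constants$L
  if (any(!is.finite(altitude_masl) | altitude_masl >= ceiling_m))
    stopf("altitude must be finite and below T0/L = %.0f m", ceiling_m)
  with(constants, P0 * (1 - altitude_masl * L / T0)^(g / (R0 * L)))
}

#' Altitude time series
#'
#' @param timestamp `POSIXct` UTC instants on the 5-min grid.
#' @param altitude altitude in metres above sea level, finite.
#' @param provenance `"raw"` (direct hypsometric conversion) or
#'   `"smoothed"` (after [rolling_mean3()]).
#' @return data frame of class `"altitude_series"` with a `provenance`
#'   attribute.
#' @export
altitude_series <- function(timestamp, altitude,
                            provenance = c("raw", "smoothed")) {
  provenance <- match.arg(provenance)
  if (length(timestamp) != length(altitude))
    stopf("timestamp and altitude must have the same length")
  if (any(!is.finite(altitude))) stopf("altitude values must be finite")
  if (length(timestamp) && is.unsorted(as.numeric(timestamp), strictly = TRUE))
    stopf("timestamps must be strictly increasing")
  structure(data.frame(timestamp = timestamp, altitude = altitude),
            provenance = provenance, class = c("altitude_series", "data.frame"))
}

#' Three-point rolling mean of an altitude series
#'
#' Centred window of width 3; at the two endpoints the mean of the two
#' available values is used, so the series keeps its length and sample
#' counts stay comparable with the raw series. Descent extraction and the
#' vertical-displacement metrics operate on this smoothed series.
#'
#' @param series an [altitude_series()] (or a bare numeric vector).
#' @return Object of the same kind with provenance `"smoothed"`.
#' @export
rolling_mean3 <- function(series) {
  if (is.numeric(series)) return(roll3(series))
  stopifnot(inherits(series, "altitude_series"))
  altitude_series(series$timestamp, roll3(series$altitude),
                  provenance = "smoothed")
}

roll3 <- function(z) {
  n <- length(z)
  if (n <= 2) {
    if (n == 2) return(rep(mean(z), 2)) else return(z)
  }
  mid <- (z[1:(n - 2)] + z[2:(n - 1)] + z[3:n]) / 3
  c(mean(z[1:2]), mid, mean(z[(n - 1):n]))
}

#' Per-interval vertical displacement and rate
#'
#' @param series an [altitude_series()] with at least two samples.
#' @return data frame with one row per interval: `t0`, `t1`, `dz` (m,
#'   signed), `dt` (s) and `rate` (m/s). The displacements telescope:
#'   `sum(dz)` equals last minus first altitude.
#' @export
vertical_displacement <- function(series) {
  stopifnot(inherits(series, "altitude_series"))
  n <- nrow(series)
  if (n < 2) stopf("need at least 2 samples to form displacements")
  dt <- diff(as.numeric(series$timestamp))
  if (any(dt <= 0)) stopf("duplicate or non-increasing timestamps")
  dz <- diff(series$altitude)
  data.frame(t0 = series$timestamp[-n], t1 = series$timestamp[-1],
             dz = dz, dt = dt, rate = dz / dt)
}
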