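#' @keywords internal
"_PACKAGE"

## Physical constants used throughout.
R_GAS <- 8.31446         # J mol-1 K-1
C_MOLAR_MASS <- 12.011   # g mol-1
LAMBDA_14C <- 1 / 8267   # yr-1, true mean-life decay constant of 14C

#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the package flows from one user seed; each generator
#' draws from its own stream so that, e.g., regenerating the flux campaign
#' does not perturb the soil-climate draw.
#'
#' @param seed integer master seed.
#' @param stream character stream label.
#' @return An integer seed in `[0, 2^31)`, a deterministic function of both
#'   arguments.
#' @export
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

## Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

days_in_year <- function(year) ifelse(is_leap_year(year), 366L, 365L)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Saturation vapor pressure and vapor pressure deficit
#'
#' Magnus-form approximation of saturation vapor pressure over water;
#' VPD is derived from air temperature and relative humidity.
#'
#' @param air_temp_c air temperature, degrees C.
#' @param rel_humidity relative humidity, percent (0-100).
#' @return `vapor_pressure_deficit()` returns VPD in hPa.
#' @export
vapor_pressure_deficit <- function(air_temp_c, rel_humidity) {
  stopifnot(all(rel_humidity >= 0 & rel_humidity <= 100, na.rm = TRUE))
  es <- 6.1094 * exp(17.625 * air_temp_c / (air_temp_c + 243.04)) # hPa
  es * (1 - rel_humidity / 100)
}
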