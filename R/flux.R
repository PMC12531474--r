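#' Concentration slope of a chamber closure
#'
#' Ordinary-least-squares slope of CO2 concentration against time over the
#' closure window (default 120 s), the quantity entering the chamber flux
#' equation.
#'
#' @param seconds time since closure, seconds, strictly increasing.
#' @param ppm CO2 mixing ratio, ppm.
#' @param window length-2 window `c(from, to)` in seconds; points outside are
#'   dropped.
#' @return Slope in ppm s-1.
#' @export
estimate_concentration_slope <- function(seconds, ppm, window = c(0, 120)) {
  stopifnot(length(seconds) == length(ppm))
  if (is.unsorted(seconds, strictly = TRUE))
    stop("times must be strictly increasing")
  keep <- seconds >= window[1] & seconds <= window[2]
  s <- seconds[keep]; p <- ppm[keep]
  if (length(s) < 3L) stop("need at least 3 points inside the window")
  if (diff(range(s)) <= 0) stop("zero time span")
  unname(stats::coef(stats::lm(p ~ s))[2L])
}

#' Static-chamber CO2 flux
#'
#' Converts a headspace concentration slope to an areal CO2 flux. The default
#' (`mode = "ideal_gas"`) multiplies the slope (ppm s-1 = umol mol-1 s-1) by
#' the molar density of air `p / (R * T_K)` (mol m-3) and the chamber
#' height `V/A` (m), giving umol CO2 m-2 s-1. `mode = "literal"` evaluates
#' the arithmetic of the classic printed chamber formula
#' `slope * 273.15/(T_air+273.15) * p/1000 * 22.41/1000 * V/A` verbatim, for
#' auditing legacy spreadsheets; only the ideal-gas form is dimensionally
#' consistent with the stated output unit.
#'
#' @param conc_slope_ppm_s concentration slope, ppm s-1.
#' @param air_temp_c air temperature, degrees C.
#' @param pressure_pa air pressure, Pa (sanity-checked to 50-110 kPa).
#' @param volume_m3 chamber volume, m^3.
#' @param area_m2 chamber footprint, m^2.
#' @param mode `"ideal_gas"` (default) or `"literal"`.
#' @return Flux in umol CO2 m-2 s-1 (ideal-gas mode).
#' @export
compute_chamber_flux <- function(conc_slope_ppm_s, air_temp_c, pressure_pa,
                                 volume_m3, area_m2,
                                 mode = c("ideal_gas", "literal")) {
  mode <- match.arg(mode)
  if (any(volume_m3 <= 0) || any(area_m2 <= 0))
    stop("chamber volume and area must be positive")
  t_k <- air_temp_c + 273.15
  if (any(t_k <= 0)) stop("air temperature below absolute zero")
  if (any(pressure_pa < 50e3 | pressure_pa > 110e3))
    stop("pressure outside plausible range 50-110 kPa")
  if (mode == "ideal_gas") {
    conc_slope_ppm_s * pressure_pa / (R_GAS * t_k) * volume_m3 / area_m2
  } else {
    conc_slope_ppm_s * 273.15 / t_k * pressure_pa / 1000 *
      22.41 / 1000 * volume_m3 / area_m2
  }
}

#' Root incubation respiration flux
#'
#' Flux per gram of dry fine root from a closed incubation chamber: linear
#' slope of the CO2 rise over a fixed window (default minutes 5-15),
#' converted to mol s-1 through chamber volume and the ideal gas law and
#' normalized by root dry mass. The linear fit must pass a minimum R^2
#' quality floor.
#'
#' @param seconds,ppm concentration time series of the incubation.
#' @param chamber_volume_m3 incubation chamber volume, m^3.
#' @param root_dry_mass_g dry mass of the incubated roots, g.
#' @param air_temp_c incubation temperature, degrees C.
#' @param pressure_pa pressure, Pa.
#' @param fit_window window in seconds (default minutes 5-15).
#' @param min_r_squared QC floor on the linear fit R^2.
#' @return List: `flux_umol_g_s`, `slope_ppm_s`, `r_squared`.
#' @export
root_incubation_flux <- function(seconds, ppm, chamber_volume_m3,
                                 root_dry_mass_g, air_temp_c = 17,
                                 pressure_pa = 101325,
                                 fit_window = c(300, 900),
                                 min_r_squared = 0.99) {
  stopifnot(root_dry_mass_g > 0, chamber_volume_m3 > 0)
  if (min(seconds) > fit_window[1] || max(seconds) < fit_window[2])
    stop("concentration series does not cover the fit window")
  keep <- seconds >= fit_window[1] & seconds <= fit_window[2]
  fit <- stats::lm(ppm[keep] ~ seconds[keep])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.finite(r2) && r2 < min_r_squared)
    stop(sprintf("linear fit R^2 = %.4f below QC floor %.3f", r2, min_r_squared))
  slope <- unname(stats::coef(fit)[2L])
  molar_density <- pressure_pa / (R_GAS * (air_temp_c + 273.15)) # mol m-3
  flux <- slope * molar_density * chamber_volume_m3 / root_dry_mass_g
  list(flux_umol_g_s = flux, slope_ppm_s = slope, r_squared = r2)
}

#' Fit the Gaussian temperature-response model
#'
#' Nonlinear least squares of `flux = R0 * exp(a*T + b*T^2)` against soil
#' temperature, the Gaussian respiration model used to upscale chamber
#' measurements to daily fluxes. Starting values come from a quadratic
#' regression of log flux on temperature; fitting uses Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). If the full model fails to converge the model is
#' refit with `b = 0` (pure exponential) and flagged. The fit is intended to
#' pool a three-calendar-year window per plot (the year under consideration
#' plus its neighbours; truncated at the study edges).
#'
#' @param temp_c soil temperatures (degrees C) of the measurements.
#' @param flux measured fluxes, umol m-2 s-1 (positive).
#' @param plot_id,window_years bookkeeping labels stored with the result.
#' @return List of class `temp_response_params`: `plot_id`, `window_years`,
#'   `R0`, `a`, `b`, `r_squared` (on the flux scale), `n_obs`, `fallback`
#'   (TRUE when b was fixed to zero).
#' @export
fit_temperature_response <- function(temp_c, flux, plot_id = NA_character_,
                                     window_years = NULL) {
  stopifnot(length(temp_c) == length(flux))
  ok <- is.finite(temp_c) & is.finite(flux) & flux > 0
  temp_c <- temp_c[ok]; flux <- flux[ok]
  if (length(flux) < 6L) stop("need at least 6 positive flux-temperature pairs")
  if (diff(range(temp_c)) < 5)
    stop("temperature span below 5 degrees C: response not identifiable")
  start_fit <- stats::lm(log(flux) ~ temp_c + I(temp_c^2))
  st <- stats::coef(start_fit)
  start <- list(lR0 = st[[1L]], a = st[[2L]], b = st[[3L]])
  fallback <- FALSE
  fit <- tryCatch(
    minpack.lm::nlsLM(flux ~ exp(lR0 + a * temp_c + b * temp_c^2),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fallback <- TRUE
    fit <- minpack.lm::nlsLM(flux ~ exp(lR0 + a * temp_c),
                             start = start[c("lR0", "a")],
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  pred <- stats::fitted(fit)
  r2 <- 1 - sum((flux - pred)^2) / sum((flux - mean(flux))^2)
  structure(
    list(plot_id = plot_id, window_years = window_years,
         R0 = unname(exp(cf["lR0"])), a = unname(cf["a"]),
         b = if ("b" %in% names(cf)) unname(cf["b"]) else 0,
         r_squared = r2, n_obs = length(flux), fallback = fallback),
    class = "temp_response_params"
  )
}

#' @export
print.temp_response_params <- function(x, ...) {
  cat(sprintf(
    "<temp_response: plot %s  R0=%.4g  a=%.4g  b=%.4g  R2=%.3f  n=%d%s>\n",
    x$plot_id, x$R0, x$a, x$b, x$r_squared, x$n_obs,
    if (x$fallback) "  [b fixed to 0]" else ""))
  invisible(x)
}

#' Fill gaps in a soil-temperature series
#'
#' Imputes missing soil temperatures the way long chamber-campaign records
#' are gap-filled: (i) when a neighbouring plot's series covers the gap, by
#' the neighbour plus a constant offset estimated from the pre-gap overlap;
#' (ii) otherwise by a lagged linear regression of soil on air temperature
#' fitted to the pre-gap overlap. Every imputed point is flagged with its
#' fill source.
#'
#' @param series data frame `timestamp` (Date or POSIXct), `soil_temp_5cm_c`
#'   (NA where missing), timestamps strictly increasing.
#' @param air_temp optional data frame `timestamp, air_temp_c`.
#' @param neighbor optional data frame `timestamp, soil_temp_5cm_c` from an
#'   adjacent plot.
#' @param overlap_days minimum pre-gap overlap used to calibrate either
#'   method (days).
#' @param lag_days lag applied to air temperature in the regression method.
#' @return `series` with gaps filled and a `source` column in
#'   `{"measured", "neighbor fill", "air-regression fill"}`.
#' @export
fill_temperature_gaps <- function(series, air_temp = NULL, neighbor = NULL,
                                  overlap_days = 7, lag_days = 1) {
  stopifnot(all(c("timestamp", "soil_temp_5cm_c") %in% names(series)))
  if (is.unsorted(as.numeric(series$timestamp), strictly = TRUE))
    stop("timestamps must be strictly increasing")
  out <- series
  out$source <- ifelse(is.na(out$soil_temp_5cm_c), NA_character_, "measured")
  gaps <- which(is.na(out$soil_temp_5cm_c))
  if (length(gaps) == 0L) return(out)

  day_s <- 86400
  ts_num <- as.numeric(as.POSIXct(out$timestamp))
  ## contiguous gap runs; each run is calibrated on the window preceding it
  runs <- split(gaps, cumsum(c(1L, diff(gaps) != 1L)))
  nb <- if (!is.null(neighbor))
    stats::approx(as.numeric(as.POSIXct(neighbor$timestamp)),
                  neighbor$soil_temp_5cm_c, xout = ts_num, rule = 1)$y
  air <- if (!is.null(air_temp))
    stats::approx(as.numeric(as.POSIXct(air_temp$timestamp)),
                  air_temp$air_temp_c,
                  xout = ts_num - lag_days * day_s, rule = 1)$y
  for (run in runs) {
    start <- run[1L]
    pre <- ts_num >= ts_num[start] - overlap_days * day_s &
      ts_num < ts_num[start] & !is.na(series$soil_temp_5cm_c)
    filled <- FALSE
    if (!is.null(neighbor) &&
        sum(pre & !is.na(nb)) >= 3L && !anyNA(nb[run])) {
      offset <- mean(series$soil_temp_5cm_c[pre] - nb[pre], na.rm = TRUE)
      out$soil_temp_5cm_c[run] <- nb[run] + offset
      out$source[run] <- "neighbor fill"
      filled <- TRUE
    }
    if (!filled && !is.null(air_temp)) {
      use <- pre & !is.na(air)
      if (sum(use) >= 3L && !anyNA(air[run])) {
        fit <- stats::lm(series$soil_temp_5cm_c[use] ~ air[use])
        out$soil_temp_5cm_c[run] <- unname(stats::coef(fit)[1L] +
                                             stats::coef(fit)[2L] * air[run])
        out$source[run] <- "air-regression fill"
        filled <- TRUE
      }
    }
    if (!filled)
      stop("no predictor overlaps the pre-gap window at position ", start)
  }
  out
}

#' Predict daily fluxes from a fitted temperature response
#'
#' @param params a `temp_response_params` (or any list with `R0`, `a`, `b`).
#' @param daily_mean_temp_c vector of daily mean soil temperatures.
#' @return Daily fluxes, umol m-2 s-1.
#' @export
predict_daily_flux <- function(params, daily_mean_temp_c) {
  stopifnot(is.finite(params$R0), is.finite(params$a), is.finite(params$b))
  params$R0 * exp(params$a * daily_mean_temp_c +
                    params$b * daily_mean_temp_c^2)
}

## seconds-per-day x g C per umol CO2
.daily_umol_to_gc <- 86400 * C_MOLAR_MASS * 1e-6

#' Annual cumulative efflux from modeled daily fluxes
#'
#' Sums a complete daily flux series for one calendar year and converts to
#' g C m-2 yr-1 (`flux x 86400 s x 12.011 g mol-1 x 1e-6`).
#'
#' @param daily_flux daily mean fluxes, umol m-2 s-1, one value per day of
#'   `year` (365 or 366 values).
#' @param year calendar year.
#' @param plot_id label stored in the result.
#' @return Data frame row: `plot_id, year, cumulative_c_g_m2, method`.
#' @export
annual_sum_modeled <- function(daily_flux, year, plot_id = NA_character_) {
  nd <- days_in_year(year)
  if (length(daily_flux) != nd)
    stop(sprintf("expected %d daily values for %d, got %d",
                 nd, year, length(daily_flux)))
  if (anyNA(daily_flux)) stop("missing days in daily flux series")
  data.frame(plot_id = plot_id, year = as.integer(year),
             cumulative_c_g_m2 = sum(daily_flux) * .daily_umol_to_gc,
             method = "model", stringsAsFactors = FALSE)
}

#' Annual cumulative efflux by linear interpolation between measurements
#'
#' Averages chamber replicates per plot and date, linearly interpolates the
#' plot-mean flux between consecutive measurement dates, integrates over the
#' calendar year (trapezoid), and converts to g C m-2 yr-1. Measurements
#' outside the year bracket the integration where available; otherwise the
#' first/last within-year value is extended to the year boundaries.
#'
#' @param dates measurement dates (Date).
#' @param flux measured fluxes, umol m-2 s-1 (chamber level or plot means).
#' @param year calendar year to integrate.
#' @param plot_id label stored in the result.
#' @return Data frame row: `plot_id, year, cumulative_c_g_m2, method`.
#' @export
annual_sum_interpolated <- function(dates, flux, year,
                                    plot_id = NA_character_) {
  stopifnot(length(dates) == length(flux))
  ## chamber replicates -> plot-date means
  agg <- stats::aggregate(list(flux = flux), by = list(date = dates), FUN = mean)
  agg <- agg[order(agg$date), ]
  start <- as.Date(sprintf("%d-01-01", year))
  end <- as.Date(sprintf("%d-01-01", year + 1L))
  in_or_near <- agg$date >= start - 40 & agg$date <= end + 40
  agg <- agg[in_or_near, ]
  if (sum(agg$date >= start & agg$date < end) < 2L)
    stop("need at least 2 measurement dates inside the year")
  t_num <- as.numeric(agg$date)
  grid <- c(as.numeric(start), t_num[t_num > as.numeric(start) &
                                       t_num < as.numeric(end)],
            as.numeric(end))
  vals <- stats::approx(t_num, agg$flux, xout = grid, rule = 2)$y
  total_days <- trapz(grid, vals)      # umol m-2 s-1 x days
  data.frame(plot_id = plot_id, year = as.integer(year),
             cumulative_c_g_m2 = total_days * .daily_umol_to_gc,
             method = "interpolation", stringsAsFactors = FALSE)
}

#' Daily mean soil temperature from sub-daily records
#'
#' Arithmetic mean per calendar day and plot.
#'
#' @param temperature_log data frame `plot_id, timestamp, soil_temp_5cm_c`.
#' @return Data frame `plot_id, date, soil_temp_5cm_c`.
#' @export
daily_mean_temperature <- function(temperature_log) {
  d <- as.Date(temperature_log$timestamp)
  agg <- stats::aggregate(
    list(soil_temp_5cm_c = temperature_log$soil_temp_5cm_c),
    by = list(plot_id = temperature_log$plot_id, date = d), FUN = mean)
  agg[order(agg$plot_id, agg$date), ]
}

#' Annual budgets for every plot of a flux campaign
#'
#' Convenience driver used by the pipeline: per plot and year it fits the
#' Gaussian temperature response on the three-year window (truncated at the
#' study edges), predicts daily fluxes from daily mean soil temperatures, and
#' returns both the modeled and the interpolation annual sums.
#'
#' @param campaign flux measurement table (see [synth_flux_campaign()] or the
#'   `flux_campaign` schema); fluxes are taken from `flux_umol_m2_s` if
#'   present, else computed via [compute_chamber_flux()].
#' @param climate daily temperature table `plot_id, date, soil_temp_5cm_c`
#'   (e.g. [synth_soil_climate()] output).
#' @param years years to summarize (default: all complete years in `climate`).
#' @return List: `budgets` (data frame of annual sums, both methods) and
#'   `fits` (data frame of per-plot-year response parameters).
#' @export
annual_budgets <- function(campaign, climate, years = NULL) {
  if (!"flux_umol_m2_s" %in% names(campaign)) {
    campaign$flux_umol_m2_s <- compute_chamber_flux(
      campaign$conc_slope_ppm_s, campaign$air_temp_c, campaign$pressure_pa,
      campaign$volume_m3, campaign$area_m2)
  }
  campaign$year <- as.integer(strftime(campaign$date, "%Y"))
  climate$year <- as.integer(strftime(climate$date, "%Y"))
  if (is.null(years)) years <- sort(unique(campaign$year))
  plots <- unique(campaign$plot_id)
  budgets <- list(); fits <- list(); k <- 0L
  for (p in plots) {
    cam_p <- campaign[campaign$plot_id == p, ]
    cli_p <- climate[climate$plot_id == p, ]
    for (y in years) {
      win <- intersect((y - 1L):(y + 1L), range(years)[1]:range(years)[2])
      sub <- cam_p[cam_p$year %in% win, ]
      fit <- tryCatch(
        fit_temperature_response(sub$soil_temp_5cm_c, sub$flux_umol_m2_s,
                                 plot_id = p, window_years = win),
        error = function(e) NULL)
      if (is.null(fit)) next
      k <- k + 1L
      fits[[k]] <- data.frame(plot_id = p, year = y, R0 = fit$R0, a = fit$a,
                              b = fit$b, r_squared = fit$r_squared,
                              n_obs = fit$n_obs, fallback = fit$fallback,
                              stringsAsFactors = FALSE)
      tday <- cli_p[cli_p$year == y, ]
      tday <- tday[order(tday$date), ]
      mod <- annual_sum_modeled(
        predict_daily_flux(fit, tday$soil_temp_5cm_c), y, plot_id = p)
      itp <- annual_sum_interpolated(cam_p$date[cam_p$year == y],
                                     cam_p$flux_umol_m2_s[cam_p$year == y],
                                     y, plot_id = p)
      budgets[[length(budgets) + 1L]] <- rbind(mod, itp)
    }
  }
  list(budgets = do.call(rbind, budgets), fits = do.call(rbind, fits))
}
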