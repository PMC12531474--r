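#' Configuration of the synthetic paired-plot warming experiment
#'
#' Bundles every knob of the synthetic-data generators. Defaults reproduce
#' the design of the emulated field experiment: six blocks of paired
#' control/warmed plots (two establishment cohorts, warming from 2005 and
#' 2008), +4 degrees C soil warming throughout the snow-free season
#' (day-of-year 105-335, i.e. mid-April to early December), one suspension
#' year (2014, the 10th warming year) with the heating off, multiplicative
#' lognormal flux noise, lognormal between-plot SOC heterogeneity and ~20%
#' higher bulk density under warming.
#'
#' @param seed integer master seed; every generator stream derives from it.
#' @param n_blocks number of control/warmed plot pairs.
#' @param warming_offset soil warming offset, degrees C.
#' @param snow_free_window integer day-of-year interval `c(first, last)`
#'   during which the heating runs.
#' @param years calendar years simulated.
#' @param flux_noise_sigma sd of the lognormal multiplicative flux noise
#'   (log scale, dimensionless).
#' @param c14_noise_sigma Gaussian measurement noise on Delta-14C (per mil).
#' @param soc_lognormal_cv coefficient of variation of the between-plot
#'   lognormal SOC and bulk-density heterogeneity.
#' @param bd_warming_ratio multiplicative bulk-density increase in warmed
#'   plots.
#' @param suspension_year calendar year with the heating switched off.
#' @param cohort_start_years first warming year of the two plot cohorts;
#'   blocks are split as evenly as possible between them.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_blocks = 6L,
                             warming_offset = 4,
                             snow_free_window = c(105L, 335L),
                             years = 2005:2022,
                             flux_noise_sigma = 0.2,
                             c14_noise_sigma = 5,
                             soc_lognormal_cv = 0.2,
                             bd_warming_ratio = 1.2,
                             suspension_year = 2014L,
                             cohort_start_years = c(2005L, 2008L)) {
  stopifnot(n_blocks >= 1, warming_offset >= 0,
            length(snow_free_window) == 2L,
            snow_free_window[1] < snow_free_window[2],
            flux_noise_sigma >= 0, c14_noise_sigma >= 0,
            soc_lognormal_cv >= 0, bd_warming_ratio > 0)
  structure(
    list(seed = as.integer(seed), n_blocks = as.integer(n_blocks),
         warming_offset = warming_offset,
         snow_free_window = as.integer(snow_free_window),
         years = as.integer(years),
         flux_noise_sigma = flux_noise_sigma,
         c14_noise_sigma = c14_noise_sigma,
         soc_lognormal_cv = soc_lognormal_cv,
         bd_warming_ratio = bd_warming_ratio,
         suspension_year = as.integer(suspension_year),
         cohort_start_years = as.integer(cohort_start_years)),
    class = "synthetic_config"
  )
}

## Run expr with the RNG seeded from (seed, stream), restoring the caller's
## RNG state afterwards: generators are independently reproducible and leave
## no hidden global state behind.
with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(sub_seed(seed, stream))
  expr
}

## Table of plots implied by a config: block, cohort, treatment, plot ids.
plot_layout <- function(config) {
  blocks <- seq_len(config$n_blocks)
  cohort <- config$cohort_start_years[
    1L + (blocks > ceiling(config$n_blocks / 2))]
  data.frame(
    block_id = rep(blocks, each = 2L),
    plot_id = as.vector(rbind(sprintf("B%d-C", blocks), sprintf("B%d-W", blocks))),
    treatment = rep(c("control", "warmed"), config$n_blocks),
    first_warming_year = rep(cohort, each = 2L),
    stringsAsFactors = FALSE
  )
}

#' Synthetic analytic bomb-spike atmospheric curve
#'
#' An analytic stand-in for observational atmospheric Delta-14C records:
#' constant pre-bomb baseline until 1950, linear rise to the bomb peak, then
#' exponential relaxation back toward the baseline. Real spliced records are
#' accepted everywhere this synthetic curve is, via [atmospheric_curve()] /
#' [read_atmospheric_curve()].
#'
#' @param params list with `baseline` (per mil), `peak_year` (> 1950),
#'   `peak_value` (per mil), `decline_timescale` (years); see
#'   [bomb_curve_params()].
#' @param year_range numeric `c(first, last)`; must cover at least 1900-2022.
#' @param step grid step in years.
#' @return An [atmospheric_curve()] with provenance `"synthetic"`.
#' @export
synth_atmospheric_curve <- function(params = bomb_curve_params(),
                                    year_range = c(1850, 2025),
                                    step = 0.1) {
  stopifnot(length(year_range) == 2L, year_range[1] < year_range[2])
  if (year_range[1] > 1900 || year_range[2] < 2022)
    stop("year_range must cover at least 1900-2022")
  yrs <- seq(year_range[1], year_range[2], by = step)
  v <- numeric(length(yrs)) + params$baseline
  ramp <- yrs > 1950 & yrs <= params$peak_year
  v[ramp] <- params$baseline + (params$peak_value - params$baseline) *
    (yrs[ramp] - 1950) / (params$peak_year - 1950)
  post <- yrs > params$peak_year
  v[post] <- params$baseline + (params$peak_value - params$baseline) *
    exp(-(yrs[post] - params$peak_year) / params$decline_timescale)
  atmospheric_curve(yrs, v, provenance = "synthetic")
}

#' @rdname synth_atmospheric_curve
#' @param baseline pre-bomb Delta-14C level (per mil).
#' @param peak_year calendar year of the bomb peak (> 1950).
#' @param peak_value Delta-14C at the peak (per mil).
#' @param decline_timescale e-folding time of the post-peak decline (years).
#' @export
bomb_curve_params <- function(baseline = 0, peak_year = 1964,
                              peak_value = 900, decline_timescale = 16) {
  stopifnot(peak_year > 1950, decline_timescale > 0)
  list(baseline = baseline, peak_year = peak_year,
       peak_value = peak_value, decline_timescale = decline_timescale)
}

#' Synthetic daily soil-temperature series for every plot
#'
#' Control plots follow a sinusoidal annual cycle (cool-humid montane
#' climate: annual mean ~6.5 C at 5 cm, amplitude ~7.5 C) plus AR(1) noise
#' shared within a block. Warmed plots equal their paired control plus the
#' warming offset on snow-free days of active warming years; the offset is
#' zero outside the snow-free window, before a cohort's first warming year,
#' and throughout the suspension year.
#'
#' @param config a [synthetic_config()].
#' @return Data frame: `plot_id, block_id, treatment, date, year, doy,
#'   soil_temp_5cm_c, warming_on`.
#' @export
synth_soil_climate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  layout <- plot_layout(config)
  dates <- seq(as.Date(sprintf("%d-01-01", min(config$years))),
               as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  year <- as.integer(strftime(dates, "%Y"))
  seasonal <- 6.5 + 7.5 * cos(2 * pi * (doy - 205) / 365.25)
  nd <- length(dates)
  with_stream_seed(config$seed, "soil_climate", {
    out <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      block_offset <- stats::rnorm(1, 0, 0.3)
      noise <- as.numeric(stats::filter(stats::rnorm(nd, 0, 0.7),
                                        0.8, method = "recursive"))
      t_control <- seasonal + block_offset + noise
      lay <- layout[layout$block_id == b, ]
      fwy <- lay$first_warming_year[1]
      on <- doy >= config$snow_free_window[1] &
        doy <= config$snow_free_window[2] &
        year >= fwy & year != config$suspension_year
      t_warmed <- t_control + ifelse(on, config$warming_offset, 0)
      out[[b]] <- data.frame(
        plot_id = rep(lay$plot_id, each = nd),
        block_id = b,
        treatment = rep(c("control", "warmed"), each = nd),
        date = rep(dates, 2L), year = rep(year, 2L), doy = rep(doy, 2L),
        soil_temp_5cm_c = c(t_control, t_warmed),
        warming_on = c(rep(FALSE, nd), on),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Synthetic chamber flux campaign
#'
#' Draws chamber CO2 flux measurements from a Gaussian temperature response
#' `R0 * exp(a*T + b*T^2)` evaluated at each plot's soil temperature, with
#' multiplicative lognormal noise per chamber. Sampling is biweekly during
#' the snow-free season and monthly otherwise, three chambers per plot and
#' date. The table carries full chamber metadata (concentration slope
#' back-calculated through the ideal-gas chamber equation, air temperature,
#' pressure, geometry) so it feeds [compute_chamber_flux()] directly.
#'
#' @param config a [synthetic_config()].
#' @param climate output of [synth_soil_climate()].
#' @param true_params list with elements `R0` (umol m-2 s-1), `a` (1/C),
#'   `b` (1/C^2): the generating temperature response, shared by all plots.
#' @param response_gain optional warming-response gain `g` (fraction per
#'   degree C). When given, a warmed plot's mean flux is
#'   `R(T_control) * (1 + g * (T_w - T_c))` instead of `R(T_w)`: the
#'   multiplicative treatment effect the per-degree response statistic is
#'   designed to recover.
#' @return Data frame of flux measurements, one row per chamber reading,
#'   with columns `plot_id, block_id, treatment, date, datetime, chamber_id,
#'   conc_slope_ppm_s, air_temp_c, pressure_pa, volume_m3, area_m2,
#'   soil_temp_5cm_c, flux_umol_m2_s`.
#' @export
synth_flux_campaign <- function(config, climate, true_params,
                                response_gain = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            all(c("R0", "a", "b") %in% names(true_params)),
            all(is.finite(unlist(true_params[c("R0", "a", "b")]))))
  gaussian_flux <- function(t) {
    true_params$R0 * exp(true_params$a * t + true_params$b * t^2)
  }
  ## Measurement dates: biweekly inside the snow-free window, monthly outside.
  all_dates <- sort(unique(climate$date))
  doy <- as.integer(strftime(all_dates, "%j"))
  snow_free <- doy >= config$snow_free_window[1] &
    doy <= config$snow_free_window[2]
  keep <- logical(length(all_dates))
  since <- 999L
  for (i in seq_along(all_dates)) {
    since <- since + 1L
    need <- if (snow_free[i]) 14L else 30L
    if (since >= need) { keep[i] <- TRUE; since <- 0L }
  }
  meas_dates <- all_dates[keep]
  cl <- climate[climate$date %in% meas_dates, ]
  geom <- list(volume_m3 = pi * 0.1^2 * 0.1, area_m2 = pi * 0.1^2,
               pressure_pa = 91000)

  with_stream_seed(config$seed, "flux_campaign", {
    ## plot-level mean flux
    cl <- cl[order(cl$date, cl$block_id, cl$treatment), ]
    mean_flux <- gaussian_flux(cl$soil_temp_5cm_c)
    if (!is.null(response_gain)) {
      ## index paired control rows (same block and date)
      key <- paste(cl$block_id, cl$date)
      ctrl_idx <- match(key, key[cl$treatment == "control"])
      ctrl <- cl[cl$treatment == "control", ]
      w <- cl$treatment == "warmed"
      dt <- cl$soil_temp_5cm_c[w] - ctrl$soil_temp_5cm_c[ctrl_idx[w]]
      mean_flux[w] <- gaussian_flux(ctrl$soil_temp_5cm_c[ctrl_idx[w]]) *
        (1 + response_gain * dt)
    }
    n <- nrow(cl)
    chambers <- 3L
    idx <- rep(seq_len(n), each = chambers)
    flux <- mean_flux[idx] *
      exp(stats::rnorm(n * chambers, 0, config$flux_noise_sigma))
    air_t <- cl$soil_temp_5cm_c[idx] + 2 + stats::rnorm(n * chambers, 0, 1)
    molar_density <- geom$pressure_pa / (R_GAS * (air_t + 273.15))
    slope <- flux / (molar_density * geom$volume_m3 / geom$area_m2)
    data.frame(
      plot_id = cl$plot_id[idx], block_id = cl$block_id[idx],
      treatment = cl$treatment[idx], date = cl$date[idx],
      datetime = as.POSIXct(paste(cl$date[idx], "09:30:00"), tz = "UTC"),
      chamber_id = rep(seq_len(chambers), n),
      conc_slope_ppm_s = slope, air_temp_c = air_t,
      pressure_pa = geom$pressure_pa, volume_m3 = geom$volume_m3,
      area_m2 = geom$area_m2,
      soil_temp_5cm_c = cl$soil_temp_5cm_c[idx],
      flux_umol_m2_s = flux,
      stringsAsFactors = FALSE
    )
  })
}

#' Synthetic soil inventory (SOC concentrations and bulk-density cores)
#'
#' Per plot and layer (0-10 and 10-20 cm): SOC concentration lognormal around
#' layer-specific treatment means, fine-soil bulk density lognormal around
#' layer means with warmed plots at `bd_warming_ratio` times their paired
#' control (plus plot noise), rock volume fraction zero in the topsoil and
#' uniform on 0-0.24 in the subsoil. Core geometry is a 100 cm^3 cylinder;
#' rock mass follows a 2.65 g cm^-3 rock density.
#'
#' @param config a [synthetic_config()].
#' @param layer_means list with per-layer means: `soc_pct` (named list
#'   control/warmed, each length 2) and `bd_control` (length 2, g cm-3).
#' @return Data frame: `plot_id, block_id, treatment, layer, soc_pct,
#'   core_total_mass_g, core_rock_mass_g, core_total_vol_cm3,
#'   core_rock_vol_cm3, nominal_thickness_cm`.
#' @export
synth_soc_inventory <- function(config,
                                layer_means = list(
                                  soc_pct = list(control = c(12.3, 7.1),
                                                 warmed = c(11.5, 5.7)),
                                  bd_control = c(0.53, 0.59))) {
  stopifnot(inherits(config, "synthetic_config"))
  layout <- plot_layout(config)
  layers <- c("0-10", "10-20")
  cv <- config$soc_lognormal_cv
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm_mean <- function(n, mean, s) {
    stats::rlnorm(n, meanlog = log(mean) - s^2 / 2, sdlog = s)
  }
  with_stream_seed(config$seed, "soc_inventory", {
    rows <- vector("list", config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      bd_c <- rlnorm_mean(2L, layer_means$bd_control, sdlog / 2)
      bd_w <- bd_c * config$bd_warming_ratio *
        exp(stats::rnorm(2L, 0, sdlog / 4))
      soc_c <- rlnorm_mean(2L, layer_means$soc_pct$control, sdlog)
      soc_w <- rlnorm_mean(2L, layer_means$soc_pct$warmed, sdlog)
      rock_frac <- c(0, stats::runif(1, 0, 0.24),    # control 0-10, 10-20
                     0, stats::runif(1, 0, 0.24))    # warmed 0-10, 10-20
      vol <- 100
      rock_vol <- rock_frac * vol
      rock_mass <- 2.65 * rock_vol
      bd <- c(bd_c, bd_w)
      fine_mass <- bd * (vol - rock_vol)
      lay <- layout[layout$block_id == b, ]
      rows[[b]] <- data.frame(
        plot_id = rep(lay$plot_id, each = 2L),
        block_id = b,
        treatment = rep(lay$treatment, each = 2L),
        layer = rep(layers, 2L),
        soc_pct = c(soc_c, soc_w),
        core_total_mass_g = fine_mass + rock_mass,
        core_rock_mass_g = rock_mass,
        core_total_vol_cm3 = vol,
        core_rock_vol_cm3 = rock_vol,
        nominal_thickness_cm = 10,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
}

#' Forward-simulated Delta-14C observations
#'
#' Runs the compartmental radiocarbon forward model and adds Gaussian
#' measurement noise, yielding an observation table in the same shape the
#' fitting routine consumes (one row per pool and sampling year).
#'
#' @param model a [compartment_model()].
#' @param curve an [atmospheric_curve()] covering the observation years.
#' @param obs_years sampling years (default 2012 and 2019).
#' @param noise_sigma Gaussian noise sd (per mil); 0 gives exact
#'   forward-model values.
#' @param seed integer seed for the noise stream.
#' @return Data frame: `year, pool, depth, treatment, delta14c_permil,
#'   sd_permil`.
#' @export
synth_radiocarbon_obs <- function(model, curve, obs_years = c(2012, 2019),
                                  noise_sigma = 5, seed = 1L) {
  stopifnot(inherits(model, "compartment_model"))
  if (any(obs_years < min(curve$years)) || any(obs_years > max(curve$years)))
    stop("observation year outside atmospheric curve support")
  fwd <- forward_delta14c(model, curve,
                          t_span = c(1900, max(obs_years)))
  pools <- model$pool_names
  grid <- expand.grid(pool = pools, year = obs_years,
                      stringsAsFactors = FALSE)
  truth <- mapply(function(p, y) {
    stats::approx(fwd$year, fwd[[p]], xout = y)$y
  }, grid$pool, grid$year)
  with_stream_seed(seed, "radiocarbon_obs", {
    data.frame(
      year = grid$year, pool = grid$pool,
      depth = model$depth, treatment = model$treatment,
      delta14c_permil = truth + stats::rnorm(nrow(grid), 0, noise_sigma),
      sd_permil = rep(max(noise_sigma, 1), nrow(grid)),
      stringsAsFactors = FALSE
    )
  })
}
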