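test_that("concentration slope matches OLS on exact and noisy series", {
  s <- seq(0, 120, by = 10)
  expect_equal(estimate_concentration_slope(s, 400 + 2 * s), 2)
  expect_equal(estimate_concentration_slope(s, rep(400, length(s))), 0)
  set.seed(11)
  s2 <- sort(runif(25, 0, 120))
  p2 <- 400 + 0.8 * s2 + rnorm(25, 0, 1)
  expect_equal(estimate_concentration_slope(s2, p2),
               ols_slope_oracle(s2, p2), tolerance = 1e-12)
  expect_error(estimate_concentration_slope(c(0, 60), c(400, 410)),
               "at least 3")
  expect_error(estimate_concentration_slope(c(0, 60, 30), c(1, 2, 3)),
               "strictly increasing")
})

test_that("chamber flux equals the ideal-gas dimensional oracle", {
  ## 1 ppm/s at 20 C, 101325 Pa, V/A = 0.1 m: molar density 41.6 mol m-3
  expect_equal(compute_chamber_flux(1, 20, 101325, 0.01, 0.1),
               chamber_flux_oracle(1, 20, 101325, 0.01, 0.1))
  expect_equal(round(compute_chamber_flux(1, 20, 101325, 0.01, 0.1), 2), 4.16)
  expect_equal(compute_chamber_flux(0, 20, 101325, 0.01, 0.1), 0)
  expect_equal(round(compute_chamber_flux(1, 0, 101325, 0.01, 0.1), 2), 4.46)
  ## randomized inputs: 1e-10 relative agreement with the oracle
  set.seed(42)
  for (i in 1:50) {
    sl <- runif(1, -1, 3); t <- runif(1, -15, 35)
    p <- runif(1, 60e3, 105e3); v <- runif(1, 1e-3, 1e-2)
    a <- runif(1, 1e-2, 1e-1)
    expect_equal(compute_chamber_flux(sl, t, p, v, a),
                 chamber_flux_oracle(sl, t, p, v, a), tolerance = 1e-10)
  }
  expect_error(compute_chamber_flux(1, 20, 101325, -1, 0.1), "positive")
  expect_error(compute_chamber_flux(1, 20, 20e3, 0.01, 0.1), "plausible")
})

test_that("literal audit mode reproduces the legacy printed arithmetic", {
  got <- compute_chamber_flux(1, 20, 101325, 0.01, 0.1, mode = "literal")
  expect_equal(got, 1 * 273.15 / 293.15 * 101325 / 1000 * 22.41 / 1000 *
                 0.01 / 0.1)
  ## the literal form differs from the dimensionally consistent one
  expect_false(isTRUE(all.equal(got, compute_chamber_flux(1, 20, 101325,
                                                          0.01, 0.1))))
})

test_that("root incubation flux inverts a forward-constructed series", {
  v <- 325e-6; mass <- 2.5; t <- 17; p <- 101325
  true_flux <- 0.012  # umol g-1 s-1
  molar_density <- p / (8.31446 * (t + 273.15))
  slope <- true_flux * mass / (molar_density * v)
  sec <- seq(0, 1800, by = 30)
  res <- root_incubation_flux(sec, 400 + slope * sec, v, mass,
                              air_temp_c = t, pressure_pa = p)
  expect_equal(res$flux_umol_g_s, true_flux, tolerance = 1e-10)
  ## doubling root mass halves the per-gram flux
  res2 <- root_incubation_flux(sec, 400 + slope * sec, v, 2 * mass,
                               air_temp_c = t, pressure_pa = p)
  expect_equal(res2$flux_umol_g_s, true_flux / 2, tolerance = 1e-10)
  ## QC floor on the linear fit
  set.seed(1)
  expect_error(root_incubation_flux(sec, 400 + rnorm(length(sec), 0, 20),
                                    v, mass), "QC floor")
  expect_error(root_incubation_flux(sec[sec < 600], 400 + slope * sec[sec < 600],
                                    v, mass), "cover")
})

test_that("Gaussian temperature response is recovered from noiseless data", {
  t <- seq(0, 20, length.out = 30)
  flux <- 0.8 * exp(0.12 * t - 0.002 * t^2)
  fit <- fit_temperature_response(t, flux)
  expect_equal(fit$R0, 0.8, tolerance = 1e-4)
  expect_equal(fit$a, 0.12, tolerance = 1e-4)
  expect_equal(fit$b, -0.002, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999999)
  expect_false(fit$fallback)
})

test_that("pure-exponential fit implies the closed-form Q10", {
  t <- seq(2, 22, length.out = 25)
  flux <- 1.5 * exp(0.0693147 * t)
  fit <- fit_temperature_response(t, flux)
  expect_equal(exp(10 * fit$a), 2, tolerance = 1e-3)
})

test_that("Gaussian fit is scale-equivariant", {
  set.seed(3)
  t <- runif(40, 0, 18)
  flux <- 0.9 * exp(0.1 * t - 0.0015 * t^2) * exp(rnorm(40, 0, 0.15))
  f1 <- fit_temperature_response(t, flux)
  f2 <- fit_temperature_response(t, 3.7 * flux)
  expect_equal(f2$R0, 3.7 * f1$R0, tolerance = 1e-4)
  expect_equal(f2$a, f1$a, tolerance = 1e-4)
  expect_equal(f2$b, f1$b, tolerance = 1e-3)
})

test_that("degenerate fits are refused", {
  expect_error(fit_temperature_response(c(10, 10.1, 10.2, 10.3, 10.4, 10.5),
                                        rep(1, 6)), "span")
  expect_error(fit_temperature_response(1:5, rep(1, 5)), "at least 6")
})

test_that("temperature gaps fill by neighbor offset and air regression", {
  days <- seq(as.Date("2010-01-01"), by = "day", length.out = 60)
  truth <- 8 + 6 * sin(seq(0, 2, length.out = 60))
  neighbor <- data.frame(timestamp = days, soil_temp_5cm_c = truth - 0.5)
  series <- data.frame(timestamp = days, soil_temp_5cm_c = truth)
  series$soil_temp_5cm_c[30:35] <- NA
  filled <- fill_temperature_gaps(series, neighbor = neighbor)
  expect_equal(filled$soil_temp_5cm_c[30:35], truth[30:35], tolerance = 1e-9)
  expect_true(all(filled$source[30:35] == "neighbor fill"))
  expect_true(all(filled$source[-(30:35)] == "measured"))
  ## identity on gap-free input
  ok <- data.frame(timestamp = days, soil_temp_5cm_c = truth)
  expect_equal(fill_temperature_gaps(ok, neighbor = neighbor)$soil_temp_5cm_c,
               truth)
  ## air-regression fill: soil = 0.8 * air(t - 1 day) + 2 plus noise
  set.seed(8)
  air <- data.frame(timestamp = days, air_temp_c = 10 + 8 * sin(seq(0, 3,
                    length.out = 60)))
  soil <- 0.8 * c(air$air_temp_c[1], air$air_temp_c[-60]) + 2 +
    rnorm(60, 0, 0.3)
  s2 <- data.frame(timestamp = days, soil_temp_5cm_c = soil)
  s2$soil_temp_5cm_c[40:45] <- NA
  f2 <- fill_temperature_gaps(s2, air_temp = air)
  rmse <- sqrt(mean((f2$soil_temp_5cm_c[40:45] -
                       (0.8 * air$air_temp_c[39:44] + 2))^2))
  expect_lt(rmse, 0.3)
  expect_true(all(f2$source[40:45] == "air-regression fill"))
  ## no predictor at all
  s3 <- s2
  expect_error(fill_temperature_gaps(s3), "no predictor")
})

test_that("daily flux prediction follows the Gaussian form", {
  p <- list(R0 = 1.4, a = 0.1, b = -0.002)
  expect_equal(predict_daily_flux(p, 0), 1.4)
  ## aT + bT^2 = 0 at T = -a/b
  expect_equal(predict_daily_flux(p, -p$a / p$b), p$R0)
  t <- seq(0, 40, by = 0.1)
  f <- predict_daily_flux(p, t)
  expect_equal(t[which.max(f)], -p$a / (2 * p$b), tolerance = 0.1)
  ## monotone when b = 0, a > 0
  f0 <- predict_daily_flux(list(R0 = 1, a = 0.05, b = 0), t)
  expect_true(all(diff(f0) > 0))
})

test_that("modeled annual sums convert units exactly", {
  conv <- 86400 * 12.011 * 1e-6
  expect_equal(annual_sum_modeled(rep(1, 365), 2010)$cumulative_c_g_m2,
               365 * conv)  # 378.8 g C m-2 for a constant 1 umol m-2 s-1
  expect_equal(round(annual_sum_modeled(rep(1, 365), 2010)$cumulative_c_g_m2, 1),
               378.8)
  expect_equal(round(annual_sum_modeled(rep(1, 366), 2012)$cumulative_c_g_m2, 1),
               379.8)
  expect_equal(annual_sum_modeled(rep(0, 365), 2010)$cumulative_c_g_m2, 0)
  expect_error(annual_sum_modeled(rep(1, 100), 2010), "expected 365")
  expect_error(annual_sum_modeled(c(rep(1, 364), NA), 2010), "missing")
})

test_that("interpolated annual sums integrate the trapezoid correctly", {
  conv <- 86400 * 12.011 * 1e-6
  d <- as.Date(c("2010-01-01", "2010-12-31"))
  expect_equal(annual_sum_interpolated(d, c(1, 1), 2010)$cumulative_c_g_m2,
               365 * conv, tolerance = 1e-6)
  ## 0 then 2: trapezoid mean 1 over the spanned interval
  expect_equal(annual_sum_interpolated(d, c(0, 2), 2010)$cumulative_c_g_m2,
               365 * conv, tolerance = 0.01)
  expect_error(annual_sum_interpolated(as.Date("2010-06-01"), 1, 2010),
               "at least 2")
  ## Riemann convergence against a smooth known flux
  truth_fun <- function(x) 1.5 + sin(2 * pi * x / 365)
  exact <- integrate(truth_fun, 0, 365)$value * conv
  for (n in c(30, 120, 365)) {
    dd <- as.Date("2010-01-01") + unique(round(seq(0, 364, length.out = n)))
    est <- annual_sum_interpolated(dd, truth_fun(as.numeric(dd -
              as.Date("2010-01-01"))), 2010)$cumulative_c_g_m2
    err <- abs(est - exact) / exact
    expect_lt(err, 0.01)
  }
  expect_lt(err, 0.001)  # daily sampling nails the integral
})

test_that("chamber replicates are averaged before interpolation", {
  d <- rep(as.Date(c("2010-01-01", "2010-12-31")), each = 3)
  f <- c(0.5, 1.0, 1.5, 0.5, 1.0, 1.5)  # plot-date means both 1.0
  conv <- 86400 * 12.011 * 1e-6
  expect_equal(annual_sum_interpolated(d, f, 2010)$cumulative_c_g_m2,
               365 * conv, tolerance = 1e-6)
})
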