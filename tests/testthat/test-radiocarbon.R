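test_that("compartmental validity is enforced on construction", {
  expect_error(compartment_model(1, matrix(0.1), pool_names = "p"),
               "negative")
  nm <- c("a", "b")
  B <- matrix(c(-1, 0, -0.2, -0.5), 2, 2)
  expect_error(compartment_model(c(1, 0), B, pool_names = nm),
               "non-negative")
  B2 <- matrix(c(-1, 1.5, 0, -0.5), 2, 2)
  expect_error(compartment_model(c(1, 0), B2, pool_names = nm),
               "column sums")
  expect_error(compartment_model(c(0, 0), matrix(c(-1, 0, 0, -1), 2),
                                 pool_names = nm), "input")
  expect_error(three_pool_model(1, 1, 1, 1.2, 0.1), "a31")
})

test_that("steady-state stocks solve the balance", {
  m1 <- compartment_model(1, matrix(-0.1), pool_names = "p")
  expect_equal(unname(steady_state_stocks(m1)), 10)
  ## chain: litter 190 g at k1 = 1, 30 % transferred to SOC at k3 = 0.01
  m <- three_pool_model(1, 1, 0.01, 0.3, 0, input = c(190, 0, 0))
  x <- steady_state_stocks(m)
  expect_equal(unname(x["bulk_soc"]), 0.3 * 190 / 0.01)  # 5700 g C m-2
  ## conservation: total release equals total input
  release <- -colSums(m$B) * x
  expect_equal(sum(release), sum(m$u), tolerance = 1e-12)
})

test_that("curve splicing prefers later sources and checks gaps", {
  pre <- data.frame(year = seq(1900, 1990, 1), delta14c_permil = 0)
  single <- splice_atmospheric_curve(list(pre))
  expect_equal(curve_at(single, 1950), 0)
  post <- data.frame(year = seq(1986, 2022, 1), delta14c_permil = 100)
  both <- splice_atmospheric_curve(list(pre, post))
  expect_equal(curve_at(both, 1950), 0)
  expect_equal(curve_at(both, 2000), 100)
  ## identical overlap values: splice equals either source
  post2 <- data.frame(year = seq(1986, 2022, 1), delta14c_permil = 0)
  same <- splice_atmospheric_curve(list(pre, post2))
  expect_equal(curve_at(same, seq(1920, 2020, 7)), rep(0, 15))
  ## hand interpolation at the join: last pre knot 1985 (0), first post 1986
  expect_equal(curve_at(both, 1985.5), 50, tolerance = 1e-9)
  gap <- data.frame(year = seq(2000, 2022, 1), delta14c_permil = 50)
  expect_error(splice_atmospheric_curve(list(pre, gap)), "gap")
})

test_that("one-pool 14C equilibrium matches k/(k+lambda)", {
  lambda <- 1 / 8267
  for (k in c(0.01, 0.1, 1)) {
    m <- compartment_model(1, matrix(-k), pool_names = "p")
    fw <- forward_delta14c(m, flat_curve(0))
    closed <- 1000 * (k / (k + lambda) - 1)
    expect_equal(tail(fw$p, 1), closed, tolerance = 1e-4)
    ## constant forcing: trajectory stays at equilibrium throughout
    expect_lt(max(abs(fw$p - closed)), 1e-8)
  }
})

test_that("a fast pool lags a synthetic bomb spike by about a year", {
  cur <- bomb_curve()
  m <- compartment_model(1, matrix(-1), pool_names = "p")
  fw <- forward_delta14c(m, cur, t_span = c(1900, 1990), step = 0.05)
  peak_year <- fw$year[which.max(fw$p)]
  expect_gt(peak_year, 1964.3)
  expect_lt(peak_year, 1966.5)
})

test_that("forward solver matches its matrix-exponential fallback", {
  cur <- bomb_curve()
  m <- true_three_pool()
  fw1 <- forward_delta14c(m, cur, t_span = c(1900, 2020), step = 0.2)
  ## force the step-loop branch by duplicating decay rates (degenerate eigen)
  m2 <- three_pool_model(0.5, 0.5, 0.0075, 0.1, 0.15, input = 190)
  fw2 <- forward_delta14c(m2, cur, t_span = c(1900, 2020), step = 0.2)
  expect_true(all(is.finite(fw2$bulk_soc)))
  ## same model through both code paths agrees
  Bl <- m$B - diag(1 / 8267, 3)
  f <- 1 + curve_at(cur, fw1$year, rule = "clamp") / 1000
  m0 <- solve(-Bl, m$u * f[1])
  E <- as.matrix(Matrix::expm(Matrix::Matrix(Bl * 0.2)))
  x <- m0; out <- matrix(0, length(f), 3); out[1, ] <- m0
  Ainv <- solve(Bl)
  v0 <- Ainv %*% (E - diag(3)) %*% m$u
  v1 <- (-0.2 * Ainv + Ainv %*% Ainv %*% (E - diag(3))) %*% m$u / 0.2
  for (j in 2:length(f)) {
    x <- E %*% x + v0 * f[j - 1] + v1 * (f[j] - f[j - 1])
    out[j, ] <- x
  }
  x_star <- steady_state_stocks(m)
  expect_equal(fw1$bulk_soc, 1000 * (out[, 3] / x_star[3] - 1),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("one-pool age and transit distributions are exponential", {
  k <- 0.1
  m <- compartment_model(1, matrix(-k), pool_names = "p")
  ad <- age_distribution(m, scope = "system", age_step = 0.5)
  expect_equal(ad$mean, 1 / k, tolerance = 1e-10)
  expect_equal(ad$median, log(2) / k, tolerance = 1e-4)
  ## density matches k e^{-ka}
  expect_equal(ad$density[1:50], k * exp(-k * ad$age[1:50]), tolerance = 1e-3)
  tt <- transit_time_distribution(m, age_step = 0.5)
  expect_equal(tt$mean, 1 / k, tolerance = 1e-10)
  expect_equal(tt$median, log(2) / k, tolerance = 1e-4)
  expect_equal(tt$density, ad$density, tolerance = 1e-9)
})

test_that("age densities integrate to one and mean agrees with closed form", {
  m <- true_three_pool()
  ## fast pools need a finer quadrature step than slow ones
  for (spec in list(list(scope = "system", pool = NULL, step = 0.5),
                    list(scope = "pool", pool = "bulk_soc", step = 0.5),
                    list(scope = "pool", pool = "fine_roots", step = 0.05))) {
    ad <- age_distribution(m, scope = spec$scope, pool = spec$pool,
                           age_step = spec$step, max_age = 1500)
    step <- ad$age[2] - ad$age[1]
    mass <- sum((ad$density[-1] + ad$density[-length(ad$density)]) / 2) * step
    expect_equal(mass, 1, tolerance = 1e-6)
    expect_gte(ad$mass_captured, 0.999)
    num_mean <- sum((ad$age[-1] * ad$density[-1] +
                       ad$age[-length(ad$age)] *
                         ad$density[-length(ad$density)]) / 2) * step
    expect_equal(num_mean, ad$mean, tolerance = 1e-3)
  }
})

test_that("mean transit time equals stock over input", {
  m <- true_three_pool()
  tt <- transit_time_distribution(m, age_step = 0.1)
  expect_equal(tt$mean, sum(steady_state_stocks(m)) / sum(m$u),
               tolerance = 1e-12)
  num_mean <- warmsoil:::trapz(tt$age, tt$age * tt$density)
  expect_equal(num_mean, tt$mean, tolerance = 1e-3)
  ## a slow pool holding mass but receiving tiny input keeps the identity
  B <- rbind(c(-1, 0), c(0, -0.001))
  m2 <- compartment_model(c(10, 0.01), B, pool_names = c("fast", "slow"))
  tt2 <- transit_time_distribution(m2)
  expect_equal(tt2$mean, sum(steady_state_stocks(m2)) / sum(m2$u),
               tolerance = 1e-12)
})

test_that("faster SOC decay rejuvenates the SOC pool", {
  base <- true_three_pool()
  warm <- three_pool_model(0.9, 0.35, 0.0095, 0.10, 0.15, input = 190)
  a0 <- age_distribution(base, scope = "pool", pool = "bulk_soc")
  a1 <- age_distribution(warm, scope = "pool", pool = "bulk_soc")
  expect_lt(a1$mean, a0$mean)
  expect_lt(a1$median, a0$median)
})

test_that("stock-weighted mixture combines depth distributions", {
  top <- age_distribution(true_three_pool(), scope = "pool", pool = "bulk_soc")
  deep <- age_distribution(
    three_pool_model(0.9, 0.35, 0.0015, 0.10, 0.15, input = c(20, 60, 0)),
    scope = "pool", pool = "bulk_soc")
  mix <- mix_age_distributions(list(top, deep), weights = c(6.3, 4.5))
  expect_equal(mix$mean, (6.3 * top$mean + 4.5 * deep$mean) / 10.8,
               tolerance = 1e-9)
  expect_gt(mix$median, top$median)
  expect_equal(warmsoil:::trapz(mix$age, mix$density), 1, tolerance = 1e-9)
})

test_that("Delta-14C mass distribution is consistent with the forward model", {
  cur <- bomb_curve()
  m <- true_three_pool()
  ad <- age_distribution(m, scope = "pool", pool = "bulk_soc", age_step = 1)
  dd <- delta14c_mass_distribution(ad, cur, 2019)
  expect_equal(sum(dd$mass_fraction), 1, tolerance = 1e-9)
  expect_true(all(dd$mass_fraction >= 0))
  fw <- forward_delta14c(m, cur, t_span = c(1900, 2019))
  expect_equal(dd$mean_delta14c, tail(fw$bulk_soc, 1), tolerance = 2,
               ignore_attr = TRUE)  # within 2 permil at 1-yr resolution
  ## near-zero-age pool concentrates in the bin holding the current atmosphere
  fast <- compartment_model(1, matrix(-50), pool_names = "p")
  af <- age_distribution(fast, scope = "system", age_step = 0.01,
                         max_age = 2)
  df <- delta14c_mass_distribution(af, cur, 2019,
                                   bins = seq(-1000, 1000, by = 20))
  atm <- curve_at(cur, 2019)
  hot <- which(df$bin_edges[-1] > atm & df$bin_edges[-length(df$bin_edges)] <= atm)
  expect_gt(df$mass_fraction[hot], 0.9)
  expect_error(delta14c_mass_distribution(af, cur, 2019, bins = 5), "2 bin")
})

test_that("noiseless fit recovers all five parameters within 1 percent", {
  cur <- bomb_curve()
  true <- true_three_pool()
  obs <- synth_radiocarbon_obs(true, cur, noise_sigma = 0, seed = 2)
  fit <- fit_radiocarbon_model(obs, cur, input = 190,
                               stocks = steady_state_stocks(true))
  truth <- c(k1 = 0.9, k2 = 0.35, k3 = 0.0075, a31 = 0.10, a32 = 0.15)
  expect_true(fit$converged)
  expect_true(all(abs(fit$params - truth) / truth < 0.01))
})

test_that("under-determined radiocarbon fits are refused", {
  cur <- bomb_curve()
  true <- true_three_pool()
  obs <- synth_radiocarbon_obs(true, cur, noise_sigma = 0, seed = 2)
  one_pool <- obs[obs$pool == "bulk_soc", ]
  expect_error(fit_radiocarbon_model(one_pool, cur), "under-determined")
  expect_error(fit_radiocarbon_model(obs[1:4, ], cur), "under-determined")
  bad_sd <- obs; bad_sd$sd_permil <- 0
  expect_error(fit_radiocarbon_model(bad_sd, cur), "positive")
})
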