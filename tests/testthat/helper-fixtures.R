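## Shared fixtures, all built in code.

## flat 0-permil atmosphere over a long support
flat_curve <- function(level = 0, from = 1700, to = 2030) {
  atmospheric_curve(c(from, to), c(level, level), provenance = "synthetic")
}

## default synthetic bomb curve
bomb_curve <- function() synth_atmospheric_curve()

## the generating three-pool system used across radiocarbon tests
true_three_pool <- function(depth = "0-10", treatment = "control") {
  three_pool_model(k1 = 0.9, k2 = 0.35, k3 = 0.0075, a31 = 0.10, a32 = 0.15,
                   input = 190, depth = depth, treatment = treatment)
}

## small, fast synthetic experiment
small_config <- function(seed = 7, years = 2005:2010, ...) {
  synthetic_config(seed = seed, n_blocks = 2L, years = years, ...)
}

## independent OLS oracle: normal equations, no lm()
ols_slope_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

## independent ideal-gas chamber flux oracle by dimensional analysis
chamber_flux_oracle <- function(slope, t_c, p, v, a) {
  molar_density <- p / (8.31446 * (t_c + 273.15))  # mol m-3
  slope * molar_density * v / a                    # umol m-2 s-1
}
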