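---
title: "Soil warming, CO2 efflux and the fate of soil carbon: methods"
author: "warmsoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil warming, CO2 efflux and the fate of soil carbon: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warmsoil)
```

`warmsoil` implements the computational chain of a long-term paired-plot
soil-warming experiment: chamber CO2 fluxes, temperature-response modelling
and annual upscaling, a per-degree warming-response statistic, SOC stock
accounting with an equivalent-soil-mass compaction correction, a
heterotrophic carbon-budget closure, and a three-pool steady-state
radiocarbon model with carbon age, transit-time and Delta-14C
distributions. This vignette explains the models, the parameters that
matter, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## Chamber fluxes and the Gaussian temperature response

A static-chamber flux is the headspace concentration slope (ppm s^-1 over a
120 s closure, ordinary least squares) converted to an areal flux with the
ideal gas law:

$$ R_{CO_2} = \frac{\Delta C}{\Delta t} \cdot \frac{p}{R\,T_K} \cdot \frac{V}{A} \quad [\mu\mathrm{mol\ m^{-2}\ s^{-1}}], $$

i.e. slope times molar air density (mol m^-3) times chamber height (m).
Legacy spreadsheets often multiply by the 22.41 L mol^-1 molar volume
instead of dividing by it; `compute_chamber_flux(mode = "literal")`
reproduces that printed arithmetic for auditing old data, but only the
ideal-gas form is dimensionally consistent with the stated unit, and it is
the default.

Plot-level upscaling uses the Gaussian respiration model

$$ R(T) = R_0\, e^{aT + bT^2}, $$

fit per plot by Levenberg-Marquardt nonlinear least squares
(`fit_temperature_response()`), with starting values from a quadratic
regression of log flux on temperature. The fit pools a three-calendar-year
window (the year under consideration plus both neighbours; truncated to two
years at the study edges, where the full window is undefined). If
the full model does not converge, the quadratic term is dropped (`b = 0`,
pure exponential, implied Q10 of `exp(10a)`) and the result flagged. Two
annual budgets are computed per plot and year and both are reported:

* **model**: daily fluxes predicted from daily mean soil temperature
  (arithmetic mean of sub-daily records per calendar day), summed with the
  conversion `86400 s x 12.011 g mol^-1 x 1e-6` to g C m^-2 yr^-1;
* **interpolation**: chamber replicates averaged per plot-date (arithmetic
  mean, three chambers), linear interpolation between measurement dates,
  trapezoidal integration over the calendar year. Where measurements do not
  reach the year boundaries the nearest value is extended.

On noiseless biweekly campaigns the two routes agree within 5% (they use
the same information in different ways); the field analogue of this check
is the close agreement of the two published cumulative estimates.

Gaps in logged soil temperature are filled (`fill_temperature_gaps()`)
preferentially from an adjacent plot plus a constant offset estimated over
the seven days preceding the gap, otherwise by a lagged (1 day) linear
regression on air temperature; all filled points carry a source flag.

## The warming-response statistic

For each block and measurement date with both treatments,

$$ \mathrm{response} = 100 \cdot \frac{R_w - R_c}{(T_w - T_c)\,R_c} \quad [\%\ ^\circ\mathrm{C}^{-1}]. $$

This is the printed ratio form re-expressed so that equal fluxes give 0%.
Records with a realized temperature difference of 2 degrees C or less are
dropped (heating off or failing), as are suspension years; calendar years
are relabeled to a warming-year index per establishment cohort. Date-level
responses are averaged within block, then mean and SD are taken across
blocks per warming year. Under multiplicative flux noise the ratio
statistic carries a small positive bias (`E[exp(e)]E[exp(-e)] =
exp(sigma^2)`), visible in synthetic runs as a few tenths of a percent at
`sigma = 0.1`; this is a property of the statistic itself, not of the
implementation.

Cumulative surplus efflux sums warmed-minus-control annual budgets per
block from each cohort's first warming year and reports mean and standard
error across the six blocks, separately for the two upscaling methods.
Driver correlations (soil temperature, air temperature, VPD via the Magnus
saturation-vapor-pressure approximation) are plain Pearson correlations on
annual means.

## SOC stocks and the equivalent-soil-mass correction

Fine-soil bulk density removes rock fragments from both numerator and
denominator: `(mass_total - mass_rock) / (vol_total - vol_rock)`. A layer
stock is `SOC% / 100 x BD x thickness`, converted to kg C m^-2. Seasonal
SOC samples are pooled by arithmetic mean per plot and layer before stock
computation.

Because warming compacted the topsoil (~20% higher bulk density), stocks
are compared over equal mineral-soil masses rather than equal depths: the
corrected thickness of a warmed layer is `nominal x BD_control/BD_warmed`
(for sub-layers minus any surplus thickness of the layers above), and the
corrected stock scales the uncorrected one by corrected/nominal thickness.
This conserves fine-soil mass per area exactly (a property test asserts it
to 1e-9). The correction is computed **per plot pair and then averaged**,
not from treatment-mean densities: with paired blocks the per-pair
calculation is the faithful one, and it is why a per-plot mean corrected
depth (8.9 cm in the reference inventory) differs from the ratio of mean
densities (8.41 cm).

```{r stocks}
corrected_thickness(bd_control = 0.53, bd_warmed = 0.63,
                    nominal_thickness_cm = 10)
```

The budget closure partitions the cumulative surplus efflux at the stock
assessment year into autotrophic and heterotrophic shares (the autotrophic
fraction, 0.40 by default, comes from a trenching experiment and is treated
as constant across years — the source gives no year-resolved values) and
annualizes what heterotrophic losses do not explain:

```{r budget}
closed_budget(surplus_cum = 3.0, autotrophic_fraction = 0.40,
              delta_soc = -0.9, years = 14)
```

The stock change enters with a sign convention of negative = loss; the
closure uses its magnitude.

## The three-pool radiocarbon model

Each depth increment (0-10 and 10-20 cm) is modelled as an independent
steady-state linear system `dC/dt = u + BC` with pools aboveground litter,
fine roots and bulk SOC: inputs `(C_in, C_in, 0)`, decay rates `k1, k2,
k3` on the diagonal of `B`, and transfer fractions `a31, a32` routing
decayed litter and root carbon into SOC. Treating the depths as uncoupled
follows the assumption that no relevant carbon transfer occurs between
them; DOC input is excluded as rapidly mineralized. Construction enforces
compartmental validity (negative diagonal, non-negative transfers, column
sums at most zero).

The 14C balance adds atmospheric forcing and radioactive decay
(`lambda = 1/8267` yr^-1, the true mean-life constant; `Delta14C =
(F - 1) x 1000` in the delta13C-corrected convention):

$$ \frac{dm}{dt} = u\,F_{atm}(t) + (B - \lambda I)\,m, $$

with `m` the fraction-modern-weighted stocks, initialized in 1900 at
equilibrium with the pre-bomb level and run to 2022. The solver is an
exact exponential integrator for piecewise-linear forcing: `B - lambda I`
is eigen-decomposed (the matrix is lower triangular, so eigenvalues are the
decay rates) and each mode advances through a recursive linear filter; a
matrix-exponential step loop covers near-degenerate eigenvalue sets. For
constant forcing the solution is exact, which is what makes the one-pool
equilibrium check (`F = k/(k + lambda)`) hold to more than four decimals.

Fitting (`fit_radiocarbon_model()`) estimates `(k1, k2, k3, a31, a32)` by
Levenberg-Marquardt from Delta-14C observations of all three pools at the
two sampling years, fitted jointly as a time series, with residuals
weighted by measurement sd. Observed pool stocks enter as **soft
constraints** (additional residuals with a 10% relative sd) rather than
hard equalities — the weighting is configurable because the original
analysis does not state how stocks constrained its fit. Inputs are fixed
(litterfall-derived, 190 g C m^-2 yr^-1 to each of litter and fine roots by
default — the displayed model equation shows equal entries, likely
notational, so they are independently configurable) rather than fitted; the
fine-root input magnitude is genuinely unconstrained by the source and is
the main structural uncertainty of the module. The optimizer restarts from
five jittered initializations and keeps the best fit; parameters pinned at
bounds are flagged. With 5 per-mil Gaussian noise the five parameters fall
inside their 95% confidence intervals in well over 90% of simulation
replicates, although the split between `a31` and `a32` is only weakly
identified (the data constrain mainly their flux-weighted sum, so those
intervals are wide and individual estimates often sit at a bound).

### Age, transit-time and Delta-14C distributions

At steady state the age density of carbon in the system is proportional to
`1' e^{aB} u`, per pool to `(e^{aB} u)_i`, and the transit-time (exit-age)
density to `z e^{aB} u` with release rates `z = -1'B`. Densities are
evaluated on a uniform grid (default 1 yr step to 3000 yr) by iterating the
per-step matrix exponential; the grid doubles until at least 99.9% of the
analytic mass is captured, then the density is normalized on the returned
grid. Means use closed forms (`-B^{-1}` applied to the steady-state
composition; total stock over total input for transit time) and medians are
root-found on the analytic cumulative distribution, so neither depends on
the display grid. The 1-yr default step is a display resolution: numerical
means recomputed from the grid agree with the closed forms to 0.1% only
when the step is matched to the pool's rate (0.5 yr for slow pools, 0.05-
0.1 yr for fast pools and transit times), which is how the tests check
them. A faster SOC decay with fixed inputs rejuvenates the pool — the mean
age drops — mirroring the direction of the warming effect in the field
data. Whole-profile (0-20 cm) aggregates are computed as stock-weighted
mixtures of the two depth systems (`mix_age_distributions()`); this is an
interpretation, since the aggregation rule behind published whole-profile
ages is not stated.

The Delta-14C mass distribution maps each age class `a` at sampling year
`t` to the atmospheric signature of year `t - a` decayed by
`e^{-lambda a}`, and accumulates class masses into Delta-14C bins (ages
older than the curve start use the pre-bomb baseline; out-of-range values
are clamped into the end bins so mass is conserved). Its unbinned mean
reproduces the forward-model pool Delta-14C within 2 per mil at 1-yr age
resolution — a useful cross-check, since the two computations share no
code path.

## The synthetic experiment

The generator reproduces the statistical structure the analysis assumes,
with defaults fixed at the study conditions: six paired blocks in two
cohorts (first warming in 2005 and 2008), +4 C warming during the snow-free
season (day-of-year 105-335, matching an April/May to November/December
window), warming suspended in 2014 (the tenth warming year of the first
cohort), biweekly-to-monthly campaigns with three chambers per plot,
lognormal between-plot SOC heterogeneity and a 1.2 bulk-density ratio under
warming. Where the sources state no value, one realistic choice was made
and fixed: a sinusoidal 6.5 +/- 7.5 C soil-temperature climatology with
AR(1) noise (giving annual mean warming of `4 x 231/365 ~ 2.5` C, inside
the reported 1.5-2.8 C span), 91 kPa ambient pressure (montane elevation),
20 cm diameter x 10 cm chambers, lognormal flux noise `sigma = 0.2`, 5 per
mil Delta-14C measurement noise, and an analytic bomb curve (0 per mil
plateau to 1950, linear ramp to 900 per mil in 1964, exponential decline
with a 16-yr timescale) standing in for observational splices, which the
same `atmospheric_curve` container accepts from file. The flux-noise
default is a free parameter: at `sigma = 0.2` synthetic temperature-
response fits reach mean R^2 near 0.8, while reproducing the published
R^2 of 0.90 +/- 0.03 would require `sigma ~ 0.12`.

A `response_gain` option generates warmed fluxes as
`R(T_c) (1 + g (T_w - T_c))` — the exact multiplicative effect the
response statistic is designed to recover — rather than via the
temperature response itself; the pipeline default `g = 0.13` mirrors the
reported ~13% per degree. All randomness flows from one seed through named
sub-streams (`sub_seed()`), so each generator is independently
reproducible and identical seeds give byte-identical tables.

What the generator does **not** emulate: snow-pack gradient fluxes (winter
campaigns simply sample the same Gaussian response), the 2008/2009 drought
roofing, drifting climate, spatially correlated SOC, or DOC chemistry
beyond constant-mean noise. Passing tests therefore demonstrate that the
estimators recover what they are designed to recover under the assumed
error structure — not that the field values themselves are reproduced,
which requires the deposited dataset.

## Problem sizes and tolerances

The test suite and the acceptance script run the full chain at the study's
scale (6 blocks, 18 years) for the pipeline checks, and scale simulation
studies to 100-200 replicates: 100 noisy radiocarbon refits for the
confidence-interval coverage check and 200 synthetic plot-years for the
temperature-response recovery check, sizes at which the binomial error on
a 90% coverage criterion is about 3%. Matrix exponentials use
scaling-and-squaring (`Matrix::expm`); the forward solver step is 0.2 yr
against a 0.1-yr atmospheric grid; fits restart from 5 (default) jittered
starts. Chamber replicates are averaged arithmetically; how the original
analysis averaged its three chambers is not stated, and the arithmetic
mean is the natural default.
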