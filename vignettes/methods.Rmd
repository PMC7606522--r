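---
title: "Models and methods: temperature exposure and child anthropometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: temperature exposure and child anthropometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

heatgrowth estimates how ambient temperature affects child nutrition
outcomes in georeferenced household surveys, and projects what fitted
responses imply for future wasting prevalence under warming. This vignette
describes the statistical model, the synthetic data that the package uses
to validate the whole pipeline, the numerical choices, and the design
decisions that were genuinely open.

## The outcome and its standardization

Child anthropometry is analysed as WHO-style Z-scores: weight-for-height
(WHZ, the acute "wasting" dimension), weight-for-age (WAZ) and
height-for-age (HAZ, the chronic "stunting" dimension). Raw measurements
are standardized with the LMS method,

$$ z = \frac{(x/M)^L - 1}{L\,S}, \qquad z = \frac{\log(x/M)}{S}
   \ \text{ when } |L| < 10^{-8}, $$

where the reference parameters $L$ (skewness power), $M$ (median) and $S$
(coefficient of variation) are indexed by height for WHZ and by age in
months for WAZ and HAZ, sex-specifically, with linear interpolation
between reference rows. Records where any index exceeds $6\sigma$ in
absolute value are removed as biologically implausible
(`apply_who_flags()`); comparisons at thresholds are strict
(`|z| > 6`, wasting `z < -2`, severe `z < -3`), with boundary values
assigned to the milder class, a convention fixed for determinism.

Two deliberate choices here: (i) the package ships a *synthetic* LMS
reference with realistic shapes, not WHO tables — real tables in the same
CSV layout drop in via `read_lms_reference()`; (ii) WHO Anthro's restricted
tail adjustment for weight-based indices beyond $|z|=3$ is **not**
implemented. Plain LMS is used both in the scorer and in the generator's
inverse, which makes the measurement round trip exact and testable to
machine precision. Whether the tail adjustment belongs in a given analysis
is a substantive choice we leave to the user supplying real references.

## Exposure construction

Children are matched to grid cells of a regular monthly climate grid by
half-open cell intervals (an edge point belongs to the more
northern/eastern cell). Exposure windows are resolved in calendar months:

* **survey month** — the interview month;
* **prior year** — the 12 months strictly before the interview month (the
  interview month itself enters separately as a control);
* **lifetime** — birth month through interview month inclusive;
* **trimesters** — months $-9..-7$, $-6..-4$, $-3..-1$ relative to the
  birth month; they partition the nine pre-birth months;
* **growing season** — the prior-year window restricted to the crop's
  growing-season calendar months in the child's cell. This makes the
  window "the previous year's growing season" and guarantees it always
  sits inside the 12 pre-interview months, at the cost of occasionally
  splitting a season that straddles the interview anniversary. The
  alternative convention (most recent *completed* season) can reach back
  more than a year; we chose containment.

Three nonlinear functional forms of monthly temperature are supported, as
is standard in the climate-impacts literature:

* **binned counts**: months falling in 2 °C bins with open-ended extremes
  (<14, 14–16, …, 34+), the 24–26 °C bin omitted as reference. Only the
  omitted bin's edges are canonical; the 2 °C width is a package default.
* **degree-months**: $\sum_m \max(0, T_m - 25)$, cumulative heat above
  25 °C;
* **quartic polynomial**: per-month power sums
  $(\sum T_m, \sum T_m^2, \sum T_m^3, \sum T_m^4)$ for prior-year models,
  and powers of the window *mean* for lifetime models (a lifetime window
  length varies by child, so per-month sums would conflate exposure with
  age; month-of-survey models apply each form to the single month).

Precipitation enters linearly through two controls: the interview month's
precipitation and the cumulative previous 12 months.

## The estimating equation

The main regression, estimated by `fit_fe_ols()`, is survey-weighted least
squares of the child Z-score on the temperature features, with the survey
month's temperature as a control (except when the window *is* the survey
month, where it would be collinear), demographic controls (mother's
education as indicators, mother's age linear, birth order fully interacted
with sex, birth month as indicators), precipitation controls, and three
absorbed fixed-effect dimensions: subnational region, country-by-year, and
calendar month of interview. Identification therefore comes from children
of the same region surveyed at different times under different weather.
Errors are clustered at the country-by-year level and the cluster dimension
is configurable independently of the fixed effects (they coincide by
default but the code never assumes it).

The high-dimensional fixed effects are absorbed by iterated weighted group
demeaning (alternating projections), applied jointly to the outcome and all
regressors, then the demeaned system is solved by a QR decomposition of the
weight-scaled, column-equilibrated design. By the Frisch–Waugh–Lovell
theorem the slopes equal the explicit dummy-variable regression; the test
suite enforces this to $10^{-8}$ against `lm()` on random designs.

**Numerical choices.** Columns are scaled to unit maximum absolute value
before demeaning, so the convergence tolerance ($10^{-10}$ on the maximum
absolute weighted group mean, cap 10 000 sweeps, non-convergence an error)
is scale-free — raw quartic temperature sums are of order $10^6$ and an
absolute tolerance there would chase double-precision noise. Rank checks
run after demeaning: controls that become collinear with the fixed effects
(common in small subgroups) are dropped with a warning; a temperature
feature in that position is an error, because the effect of interest is
then unidentified. Binned designs drop bins that no child's window ever
visits. The joint Wald statistic is computed in correlation form (it is
invariant to diagonal rescaling) because the raw quartic coefficient block
is badly scaled.

**Inference.** The covariance is the CR1 cluster sandwich
$(X'WX)^{-1}\left[\sum_g s_g s_g'\right](X'WX)^{-1}\cdot
\frac{G}{G-1}\frac{N-1}{N-K}$ with $s_g = X_g' W_g e_g$. $K$ counts the
estimated slopes plus absorbed fixed-effect coefficients, *excluding*
fixed-effect dimensions nested within the clusters — the convention of
standard high-dimensional fixed-effects software; counting cluster-nested
dimensions visibly deflates the null Wald statistic in simulation. Single
coefficients use $t_{G-1}$ intervals; the joint test of the polynomial
terms uses $\chi^2_{|s|}$. Both are asymptotic in the number of clusters,
and the simulations below quantify how close they get under the study
conditions.

`crop_weighted_fit()` estimates the growing-season regression separately
per crop with weight = sampling weight × local area share, so fully
specialized locations dominate the crop's identification.
`cross_section_fit()` is the descriptive counterpart: a weighted quartic of
regional mean outcome on regional long-run mean temperature (via
`stats::lm`, with the overall F for the four slopes). `fit_by_group()` and
`residence_filter()` implement the age-band/urban-rural splits and the
migration-robustness subset.

## The synthetic world

Everything is validated on generated data with known truth, because the
real inputs of such analyses (survey microdata, bulk climate archives) are
access-restricted; the generators are first-class, tested code.

**Climate** (`generate_climate_grid()`): temperature = latitudinal linear
base + seasonal cosine (peak January south of the equator, July north) +
linear trend + a per-cell stationary AR(1) *annual* anomaly + independent
monthly weather noise, on a 0.5° grid at monthly resolution.
Defaults (base 25 °C, gradient −0.5 °C/°lat, amplitude 2 °C, anomaly SD
0.4 °C with lag-1 autocorrelation 0.4, monthly SD 1 °C, trend
0.15 °C/decade) are of the order seen in tropical-Africa station data. The
monthly noise term is a deliberate addition: identification of monthly
exposure effects requires sub-annual weather variability, which an annual
anomaly alone cannot supply. Precipitation is i.i.d. lognormal — enough to
exercise the controls; no drought persistence or wet-season structure is
claimed.

**Cohort** (`generate_cohort()`): countries ⊃ regions ⊃ survey clusters
(villages) ⊃ children. Regions are north–south strips of grid cells, so a
region spans a range of base temperatures — this matters for the quartic's
conditioning (see below). Clusters sit at a uniform point of a random cell
in their region and children inherit the cluster's coordinates, matching
how cluster GPS coordinates work in real surveys. The latent WHZ is

baseline + injected temperature response + ν·(survey-month temperature) +
linear control effects + region FE + country-year FE + calendar-month FE +
cluster random effect + child noise,

with Gaussian components (defaults: noise 0.9σ, cluster 0.3σ, region 0.3σ,
country-year 0.2σ, month 0.1σ, baseline −1σ — wasting prevalence around
10–20%, in the range of high-burden surveys). All control effects lie in
the span of the regression's control dummies, so control adjustment is
exactly testable. Raw weight and height are back-computed through the
inverse LMS reference; rescoring reproduces the latent Z to ~$10^{-15}$.
Sampling weights are lognormal normalized to mean 1; 85% of children are
resident their whole life, the rest a uniform fraction of it. Ages default
to 12–59 months (children over age one), the restriction used to avoid
fetal-selection and infant-mortality confounding.

The default injected response is a hinge: −0.08/12 σ per degree-month
above 25 °C, i.e. a year uniformly 1 °C hotter costs 0.08σ — translated
exactly for the degree-month form, to bin-midpoint effects for the binned
form, and to a least-squares quartic for the polynomial form. An optional
age interaction (`age_effect_slope`) multiplies the injected response by a
linear function of age; the tests use it to verify that group-wise fits
recover age-intensifying effects in the right order.

**Crops** (`generate_crop_map()`): per-cell area shares from a symmetric
Dirichlet over the crops plus an "other" remainder (so shares sum to ≤ 1;
concentration 0 degenerates to single-crop cells), and one contiguous
season per crop anchored to the cell's warmest month.

In a multi-crop world the generator applies each crop's growing-season
response *at full strength wherever the crop is grown*, with the area
share entering only the regression weights. This is a deliberate modelling
choice: if damage were instead proportional to the share, the
share-weighted regression's estimand would be attenuated by
$E[s^2]/E[s]$ and could not recover the injected coefficient in a
mixed-cropping world — a caveat that applies to real-data estimates too.
Under the full-exposure world the estimator is consistent, which is the
property the tests verify.

**Projections** (`generate_projection_series()`): per-region monthly
series for 2015–2100 equal to the region's recent monthly climatology in
2015 plus a linear warming ramp (optionally noise after 2015); a
0.5 °C/decade ramp reaches +4.25 °C by 2100, around a high-emissions
end-of-century signal for the region.

Determinism: every generator is a pure function of (config, seed), with
named substreams per component so, e.g., a change to the cohort layout
never perturbs the climate realization under the same master seed.

**What the synthetic world does not emulate:** multi-stage survey
sampling design (only weights and clusters), GPS displacement noise,
spatially correlated weather anomalies, precipitation seasonality,
crop-yield dynamics, or measurement error in dates and anthropometry.
Passing tests show the estimator and projection machinery are correct and
calibrated under the stated data-generating process, not that the
substantive effect sizes in any real population are right.

## Projection method

`project_wasting()` takes the pooled per-month quartic fit (the
rural+urban combined model; rural-only is a configuration, not the
default), regional monthly projections, and the baseline survey-weighted
WHZ distribution per region. For each region-year the annual shift is
$\Delta = \sum_{m=1}^{12}\left[p(T^{year}_m) - p(T^{2015}_m)\right]$ with
$p$ the fitted per-month polynomial; the baseline distribution is
translated uniformly by $\Delta$ (no quantile-specific damage), and
wasting prevalence is the survey-weighted mass below −2σ. Percent change
uses the 2015 prevalence as denominator and is exactly zero in 2015;
regions with baseline prevalence below $10^{-6}$ raise an error rather
than report unstable percentages. Parameter-uncertainty bands redraw the
temperature coefficients from a multivariate normal centred at the
estimates with their cluster-robust covariance (symmetric repair at
$10^{-10}$, eigendecomposition square root), recompute the whole
trajectory per draw, and report equal-tailed 2.5/97.5 percentiles over
1000 draws by default; climate-scenario spread and precipitation are
deliberately excluded. The four-region partition (west/central/east/south)
is a user-supplied mapping of cells and of baseline children. Whether
the baseline year's climatology should be projected or observed is
unresolved in general; the package anchors on the projection input's own
2015 values, which makes the anchoring exact by construction.

## Calibration of the simulation studies

The package's acceptance-style tests run four simulation studies whose
conditions were fixed at design time:

* **Parameter recovery** (n = 20 000; 5 countries × 4 regions × 25
  villages × 40 children, surveys 2008–2012): replicate-mean estimates of
  all three injected forms sit within two Monte-Carlo standard errors of
  truth over 20 seeded replicates. These fits are correctly specified, so
  replicates share one climate realization (estimates are conditionally
  unbiased given weather).
* **Size control** (n = 2 000, 500 replicates, zero injected effect):
  the degree-month 95% interval excludes zero at close to the nominal
  rate, and polynomial joint-Wald p-values are close to uniform. Both
  checks are asymptotic in the number of clusters and sensitive to
  leverage: the conditions use 2 000 one-child villages spread 10 per
  country-year (G ≈ 200), a wide temperature support (latitudes spanning
  ~11.5°, gradient −1 °C/°lat, monthly SD 1.5 °C) so the quartic is well
  conditioned, and homogeneous weights with homoskedastic errors. With
  few villages per country-year cell the cluster-level exposure
  concentrates leverage and the 4-df cluster Wald is visibly far from
  $\chi^2_4$ — a finding worth remembering when interpreting joint tests
  in designs with exposure constant within clusters.
* **Crop separation**: two crops with disjoint 4-month seasons (one
  around the warm peak, one on the shoulder), distinct injected effects
  (−0.03 and −0.01 σ per degree-month), mixed shares
  (Dirichlet 0.5), a warm (26 °C) flat-gradient world with no interannual
  anomaly so the two seasons' weather is independent. Because each
  per-crop fit omits the other crop's response, replicates redraw the
  whole world; the share-weighted fits recover both truths within two
  Monte-Carlo standard errors.
* **Anthropometry round trip**: $10^5$ children scored back to their
  latent Z within $10^{-9}$; the flag filter agrees exactly with an
  exhaustive scan (the scenario widens the latent SDs so the ±6σ tails
  are genuinely populated).

Problem sizes throughout were chosen so the studies are informative while
a full test run stays comfortably in minutes on one core.

## Known limitations

* The Wald joint test references $\chi^2$; at a few hundred clusters its
  rejection rate at 5% is nearer 6%, the usual finite-cluster behaviour.
  No wild-cluster bootstrap or Bell–McCaffrey correction is provided.
* No two-way clustering and no instrumental variables.
* The quartic extrapolates badly outside the temperature support; response
  curves warn outside −20..50 °C but users should check support overlap
  before projecting far beyond observed temperatures.
* The projection shifts distributions uniformly; quantile-specific damage,
  population growth and demographic change are out of scope.
* Daily temperature exposure, humidity and heat-index measures are not
  implemented.
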