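---
title: "Radon mass balance for lake groundwater discharge: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radon mass balance for lake groundwater discharge: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakegw)
```

## The model and its assumptions

`lakegw` inverts a whole-lake ²²²Rn mass balance for the groundwater radon
flux. The balance has four sources (groundwater, sediment diffusion, inlet
streams, in-situ production from dissolved ²²⁶Ra) and three sinks
(atmospheric evasion, outlet export, radioactive decay), all in Bq d⁻¹.
Three assumptions make the inversion algebraic:

1. **Steady state** over the radon residence time
   τ = 1/(λ + Q_outlet/V + k/h), typically 2–3 days for small lakes with
   moderate flushing. The `steady_state_check()` diagnostic quantifies
   "stable conditions" as the coefficient of variation of daily-mean wind
   over max(3 d, 3τ) before sampling; the default threshold of 0.5 is a
   deliberate, configurable convention since no sharp criterion exists.
2. **A well-mixed water column.** The budget concentration is the mean of
   lake-surface samples (median by option); deep samples are excluded from
   the budget and serve only as a mixing check.
3. **No groundwater outflow.** A lake that loses water through its bed
   would violate the balance in the direction that makes the estimate a
   *minimum*; accordingly a negative solved flux is clamped to zero and
   flagged rather than treated as an error.

Uncertainties are carried as 1-σ values on every term and combined in
quadrature, treating terms as independent — no covariances are modelled,
matching the deterministic first-order propagation the budget is built on.

## Gas exchange

Transfer velocities come from wind-based k₆₀₀ models evaluated on hourly
wind adjusted to 10 m by a neutral log profile (roughness 10⁻⁴ m). The
default `"wind_46lakes"` model uses the wind + lake-area functional form
`k₆₀₀ [cm h⁻¹] = a + b·u₁₀ + c·u₁₀·log₁₀(area)` with a calibration domain
of 0–13 m s⁻¹ and 0.018–1342 km²; its coefficients are config-overridable
because multi-lake calibrations are periodically refit. `"cole_caraco"`
(`2.07 + 0.215·u₁₀^1.7`) and `"vachon_prairie"` are built in for
sensitivity analysis. Out-of-domain evaluations warn but never error: a
survey should not die because one gusty hour exceeded the calibration
range.

Gas-specific k uses `(Sc/600)^−n` with the standard regime convention
n = 2/3 below 3.7 m s⁻¹ and 1/2 above; Schmidt numbers are freshwater
third-order polynomials in temperature (CH₄: 615.8 at 20 °C). Radon
partitioning uses the Weigel form `0.105 + 0.405·exp(−0.0502 T)`, and the
CH₄ atmospheric equilibrium uses the Wiesenburg–Guinasso solubility
function at salinity 0 with a default mixing ratio of 1.9 ppm.
Atmospheric radon is taken as zero by default (lake water is orders of
magnitude above equilibrium with air), configurable.

Hours preceding the sampling time are weighted `exp(−Δt/τ)` over a 3τ
window, normalised to one. The exponential kernel is a design choice: the
tracer itself forgets forcing at a 1/τ rate, so degassing events are
discounted on the same timescale. A record that only partially covers the
window is accepted (old hours carry little weight); a record that misses
the window entirely is an error. k and τ depend on each other through the
window length, so `rn_budget()` solves them by three fixed-point sweeps —
τ is insensitive to k at these scales, and the iteration converges to
machine precision in two.

## Monte-Carlo endmember resampling

The solved flux with its σ defines a normal distribution, truncated at
zero by resampling (a negative groundwater radon flux is unphysical under
the no-loss assumption; the literature is silent on handling, so
truncation is documented rather than assumed universal). Each of the 1000
draws (the conventional ensemble size; summaries are stable against 10⁵)
is divided by an endmember ²²²Rn concentration resampled with replacement
from the measured groundwater samples, and by a resampled Rn:CH₄ ratio
for the CH₄ load. Whether the concentration and the ratio should come from
the *same* groundwater sample is genuinely ambiguous; both modes are
implemented (`endmember_mode = "independent"` is the default, reading the
random selection literally; `"paired"` is one switch away). Summaries are
always median/IQR with linear-interpolation percentiles (R type 7) — the
convention is fixed and tested because no source states one.

Each lake-season gets its own RNG stream derived from the master seed and
a stable hash of the lake id, so per-lake results are independent of
processing order and parallelisation.

## CH₄ budget

Stream CH₄ loads are normalised by lake area (`q·c·16.04/A`). Diffusive
emission applies the same flux law with the CH₄ transfer velocity; the
emission ledger floors at zero and reports invasion separately, because
the budget treats the atmosphere as an output while an undersaturated
lake is still a physically meaningful observation. Ebullition is not
measured but scaled: diffusion is assumed to be a fixed fraction of total
emission, default 0.17 — the conservative end of a long-term
three-lake record in which diffusion contributed 17–52% of the ice-free
flux — making the ebullition and total-emission figures deliberate
*maxima*. Both endpoints are accepted by config. The across-lake
regression of total emission on inflow is plain OLS on untransformed
values with exact small-sample inference, and uses the Monte-Carlo
medians per lake (the alternative — maximum-scenario totals — is not the
default and is recorded here as an open choice).

## Spatial driver statistics

Predictors are screened pairwise by Spearman correlation: within each
significant pair (α = 0.05) the later-listed predictor is dropped, so
ordering encodes priority. p-values use the exact null for n < 10 and the
t approximation otherwise. PLS is single-response NIPALS on standardised
predictors with leave-one-out CV choosing the component count (first
minimum of RMSE, i.e. fewest components on ties); VIP uses the standard
weights-normalised formula over the retained components, whose squared
scores average to exactly one. "Stepwise" model search is implemented as
*exhaustive* all-subsets OLS — at the p ≤ 12 scale of catchment tables
enumeration is cheap and avoids greedy-path ambiguity — ranked by
`AIC = n·ln(RSS/n) + 2(k+1)` (Gaussian form, constants dropped
consistently so only differences matter), ties to fewer terms. The
reference spatial model
`Q_gw = 7.3 + 3.5·depth − 5.7·log₁₀(wetzone) − 0.27·log₁₀(slope)`
is exported as `reference_mlr_predict()` and drives the synthetic driver
generator.

## The synthetic generator, and what passing tests do not show

`generate_survey()` emulates the statistical structure of a small
sub-Arctic mire-lake survey: a 5 ha, 2.8 m deep lake; groundwater
endmembers lognormal with median 3500 Bq m⁻³ (quartile ratio 2100:8800)
for ²²²Rn and median 150 μM (ratio 49:210) for CH₄, drawn as correlated
pairs (log-scale correlation 0.5, since both derive from the same
active-layer source); n = 41 endmembers; stream concentrations at the
observed stream medians; AR(1) hourly wind (mean 4 m s⁻¹, lag-1 0.8,
truncated at 0) inside the k-model calibration range; observation noise
10% on concentrations, 15% on discharges and 30% on the sediment flux —
typical field uncertainty, all configurable. The lognormal calibration
fixes the median and the quartile *ratio*; asymmetric quartile anchors
cannot both hold around a fixed median, and the ratio is the
self-consistent choice.

The forward model computes the steady-state lake concentration in closed
form, using the *empirical median of the generated endmember set* as the
effective source concentration. This is deliberate: if truth used the
population median while the inversion divides by resampled measured
endmembers, every recovery test would mostly measure the sampling error
of 41 endmembers (~20% CV) rather than the pipeline. With this
convention, forward-then-invert is exact to numerical precision at zero
noise — the module's central identity, property-tested over random
parameter sets and against an independent ODE integration of the
transient balance.

What passing tests therefore show: the inversion, uncertainty machinery
and statistics are internally correct and recover known truths under the
stated noise model. What they do not show: performance under real-field
violations the generator does not emulate — spatial heterogeneity of the
radon signal, non-steady forcing (rain events, abrupt wind shifts),
biased endmember sampling, ice cover, or CH₄ oxidation between source and
surface. Per-lake sediment fluxes in real surveys are measured, not
order-of-magnitude defaults.

## Numerical choices and problem sizes

Percentiles: linear interpolation (type 7) everywhere. Unit conversions
pass through a single layer (1 cm h⁻¹ = 0.24 m d⁻¹; CH₄ 16.04 mg
mmol⁻¹). Degenerate inputs fail loudly with classed conditions
(`lakegw_validation_error`, `lakegw_domain_error`) listing offending rows;
defaults applied silently nowhere — every one is a logged message. The
recovery suites use 200 synthetic surveys at 1000 Monte-Carlo iterations,
100 driver replicates at n = 24 lakes, and 100 randomised
forward–inverse parameter sets; these sizes give stable pass/fail margins
(binomial SE below 2 percentage points on coverage rates) while keeping
the full suite under a minute on a laptop-class core.

The driver-recovery check asserts *per-coefficient* 95%-interval coverage
(≥ 0.9 observed rate per coefficient) plus selection of the generating
predictors. Joint coverage of several marginal intervals is ~0.85 for a
perfectly specified model, so a joint criterion would mis-measure
correctness by construction.

## Known limitations

Transient (time-dependent) inversion and spatially segmented budgets are
out of scope, as are instrument-format ingestion and GIS catchment
processing. The uncertainty model is first-order and covariance-free; the
Monte-Carlo stage captures endmember spread but not, for example,
correlated errors between inlet discharge and inlet concentration. The
ebullition figure is a scaling, not a measurement, and should be read as
an upper bound conditional on the chosen diffusive fraction.
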