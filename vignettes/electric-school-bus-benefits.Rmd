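---
title: "Assessing the health and climate benefits of school bus electrification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the health and climate benefits of school bus electrification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebusbenefits)
```

## The assessment model

Replacing a diesel school bus with an electric one changes two externality
streams: ambient fine particulate matter (PM2.5) that the diesel tailpipe
would have caused, and greenhouse gases. `ebusbenefits` quantifies both as a
chain of linear and near-linear stages:

1. **Emissions.** A bus driving `vmt` miles per year with emission factors
   `EF_p` (g/mile) emits `EF_p * vmt * 1e-6` t/yr of each pollutant
   (primary PM2.5 and the secondary-PM precursors NOx, SO2, NH3, VOC).
   County emissions are spread over grid cells in proportion to population,
   on the assumption that buses drive where people live.
2. **Dispersion.** A source-receptor matrix (SRM) maps a marginal emission
   in a source cell to a marginal ambient PM2.5 change in every receptor
   cell: `dC_r = sum_s sum_p SRM(s, r, p) E(s, p)`. The unit contract is
   (ug/m^3) per (t/yr); missing sparse entries mean exactly zero.
3. **Health burden.** For each receptor and age group, attributable cases
   are `M0 * pop * (1 - exp(-beta * max(dC - threshold, 0)))`: adult (25+)
   mortality with baseline rates `M0`, and asthma onset among at-risk
   children (those not currently with asthma), with a log-linear slope
   `beta = ln(HR)/IQR = ln(1.33)/6.53 ≈ 4.4%` per ug/m^3 and no threshold.
4. **Monetization.** Deaths are valued at a VSL of $9.3M (2014) updated to
   $12.4M (2022 dollars and income levels, income elasticity 1.0), times a
   cessation-lag present-value factor (30% of benefits in year 1, 50%
   uniform over years 2–5, 20% over years 6–20, discounted at 3%/yr with
   the exposure year undiscounted). Asthma cases are valued at a VSC of
   $610,000 in the exposure year.
5. **Electric side.** Grid generation for charging is
   `1.54 kWh/mile / ((1 - 0.10)(1 - 0.048))` (charging and transmission
   losses), valued at 2.2 attributable deaths per TWh in the 2018 base year
   scaled by projected grid-emission declines; the asthma-to-mortality
   ratio is transferred from the diesel side of the same run rather than
   hard-coded.
6. **Climate.** Diesel CO2 is `10,180 g/gal / 7.36 mpg ≈ 1,383 g/mile`;
   electric use-phase CO2 follows the grid intensity (492 lb/MWh) through
   the same losses; battery production adds `59.5 kg/kWh x 166 kWh ≈ 9.9 t`
   charged entirely to year one. Net annual reductions over the 13.5-year
   lifetime (13 full years plus a half-weighted 14th, mileage uniform) are
   valued with a social cost of CO2 interpolated linearly from $228.10/t
   (2023) to $281.77/t (2036) and discounted at 2%/yr, first year
   undiscounted.

Per-mile benefits are the monetized impacts of the replaced bus minus the
replacement's, at the time the mile is driven (cessation lag already
inside). Per-bus benefits multiply by 190,134 lifetime miles and a uniform-
flow present-value multiplier at 3%.

## Worked example

```{r example}
spec <- domain_spec(n_cells = 400, n_counties = 12, seed = 1)
domain <- generate_domain(spec)
srm <- generate_srm(domain)
efs <- generate_emission_factors()

scenario <- replacement_scenario("MY2005", "electric",
                                 region = "large_central_metro")
res <- evaluate_scenario(scenario, domain, srm, efs)
res
```

## The synthetic domain: what it emulates and what it does not

The real study rests on a national reduced-complexity air-quality model
(52,411 variable-size cells), county emission inventories and census
population tables — inputs far outside a reproducible test suite. The
synthetic generator emulates the *structure* the analysis depends on:

* heterogeneous population density (log-normal, default meanlog `log(100)`
  people/km^2, sdlog 1.2) with a single smooth metro core, so that density
  contrasts between urban-rural classes exist;
* contiguous counties (near-equal runs of cells along a serpentine lattice
  path) classified into six urban–rural classes by density sextile;
* a Gaussian dispersion kernel `k_p exp(-d^2 / (2 L_p^2))` with a short
  decay length for primary PM2.5 (5 km) and long ones for the secondary
  species (50 km), mirroring the fact that primary particle impacts occur
  close to the source while secondary formation spreads widely;
* kernel amplitudes (`6e-3` for primary PM2.5, `1e-5`–`2e-5` for the
  precursors, in (ug/m^3)/(t/yr)) chosen once so that per-ton damages land
  at realistic magnitudes — hundreds of thousands of dollars per ton of
  primary PM2.5 in dense areas versus tens of thousands per ton of NOx —
  and hence per-mile impacts of old diesel buses come out at tenths of a
  dollar with a 50–60% primary-PM share in metro areas;
* steeply declining emission factors by model year, pinning the
  MY2005:MY2010 ratios at exactly 12 (primary PM2.5), 4 (NOx) and 5 (VOC);
* age-structured populations with national-style age fractions, a mortality
  schedule rising steeply with age, childhood asthma incidence averaging
  about 12.5/1,000 across child ages, and prevalence rising with age.

It does **not** emulate real geography, real meteorology or chemistry
(secondary formation is strictly linear here), census-block population
weighting (cell populations stand in), or correlated spatial structure
beyond the single metro core. Tests passing on this domain therefore
demonstrate the correctness and the qualitative orderings of the pipeline
(dense > sparse benefits, old > new buses, primary PM more local than NOx),
not the national dollar figures, which require the real inputs.

## Numerical and design choices

* **SRM units.** (ug/m^3) per (t/yr). The source model's normalization is
  not published; this is a repository convention that makes every
  downstream unit check explicit.
* **Kernel truncation.** Entries below 1e-12 of the self-cell value are
  dropped; the self-cell entry is the row maximum by construction.
* **Integer populations.** Largest-remainder rounding within counties and
  within cells' age vectors, so county and cell totals are conserved
  exactly.
* **Per-pollutant attribution.** The nonlinear attributable fraction is
  applied channel by channel (the default), which keeps per-species
  decompositions well defined; `attribution = "proportional"` applies it to
  the joint concentration and splits by concentration share. At the
  exposure increments buses cause (`beta * dC` well below 1e-2) the two
  agree within 1%.
* **Mortality slope.** The pooled-cohort (GEMM-style) shape parameters are
  not published in usable form here, so the default mortality CRF is
  log-linear with a repository-supplied slope of 0.0077 per ug/m^3 (≈ RR
  1.08 per 10 ug/m^3, mid-range across major chronic-exposure cohorts);
  `gemm_slope()` evaluates the full logistic-weighted log-hazard derivative
  for user-supplied parameters.
* **Cessation-lag factor.** With first-year benefits undiscounted,
  `sum_t w_t 1.03^-(t-1) = 0.9061`.
* **Driving-year discounting.** Mid-year discounting
  (`(1+r)^-(t-0.5)`, multiplier 0.8244 at 3% over 13.5 years) is the
  default because it reproduces the published per-bus health figure from
  the published per-mile one within its rounding; start-of-year (0.8366) is
  selectable for sensitivity.
* **Climate discounting.** Start-of-year with the first year undiscounted,
  which reproduces the published climate benefit under the linear SCC
  interpolation.
* **Electric use-phase reference.** 492 lb/MWh x 1.54 kWh/mile through the
  stated losses gives ≈401 g/mile by the formula; the published value is
  381 g/mile, and the loss composition behind it is not fully specified.
  The package exposes the formula (`electric_co2_per_mile()`) and carries
  381 as the pinned reference used in reproduction paths, with both
  documented.
* **Grid projection scalers.** The reference-case grid projections are
  emulated by a linear decline from 0.40 to 0.17 of the 2018 damage
  intensity over 2023–2036 (mean ≈0.29, consistent with NOx and SO2
  falling roughly 3x and 4x); with these defaults electric buses cause
  about $0.013–0.014 per mile in health impacts.
* **VSL indexes.** The official earnings and deflator series are not
  shipped; small editable series (real income +10%, deflator ratio chosen
  so the combined factor is exactly 12.4/9.3) pin the 2022 endpoint.
* **Negative benefits** are reported, never clipped; a battery exceeding
  the use-phase CO2 difference yields a negative reduction with a warning.
* **Degenerate inputs.** Zero-population counties error unless the
  uniform-area fallback is enabled; zero total population errors in intake
  fractions; malformed density or kernel parameters are rejected at spec
  construction.

## Problem sizes

The shipped examples and tests use 100–400-cell domains with 6–12 counties,
which exercise every code path (sparse dispersion, class aggregation,
district crosswalks) while keeping the full suite to a few seconds; the
generator scales to tens of thousands of cells if a larger synthetic
domain is wanted.

## Limitations

Beyond the synthetic-domain caveats above: secondary-PM chemistry is
linearized; ozone, acute exposure, in-cabin exposure and non-battery
life-cycle emissions are out of scope; cost is a single scalar
differential (default $156,000) rather than a fleet cost model; and
equity-stratified exposure or valuation is not modeled.
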