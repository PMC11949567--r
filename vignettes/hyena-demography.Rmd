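---
title: "Estimating hyena survival, abundance and density from sighting records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hyena survival, abundance and density from sighting records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hyenademog` turns a decade of sightings of individually known spotted
hyenas into three linked sets of estimates: annual apparent survival by
age class and sex, seasonal abundance, and seasonal density. This
vignette is the package's account of the science behind each step — the
models and their assumptions, the conventions that had to be fixed where
several were defensible, what the built-in simulator does and does not
emulate, and what the test suite can and cannot tell you about real
field data.

## From sightings to encounter structures

The raw inputs are two tables: `individuals` (id, clan, sex ∈ {F, M, U},
birth date, known death date if any, collaring flag) and `sightings`
(id, date, planar coordinates in km). All spatial work is planar;
longitude/latitude data should be projected (e.g. a local
transverse-Mercator) before entering the package.

`build_occasion_grid()` lays contiguous, half-open 2-month bins over the
study window; June 2010 – November 2019 gives exactly 57 occasions.
`build_cjs_history()` collapses each individual's sightings to a binary
57-vector. Conventions fixed here:

* **Known deaths are excluded** from the survival analysis (they would
  require a joint recovery/recapture model, and they are few); the count
  is reported in the object and the run log.
* **Age classes** are cub (0–1 y), subadult (1–3 y), adult (3+ y), with
  boundaries assigned upward on calendar anniversaries: an animal on its
  first birthday is a subadult. The class used for an occasion is
  evaluated at the occasion midpoint, which minimizes misclassification
  within a 2-month bin; the same convention is used by the simulator, so
  simulated truth and model output are directly comparable.
* **Seasons**: wet is December–April, dry May–November; December is
  labelled with the following year's wet season (wet-2014 = Dec 2013 –
  Apr 2014), which matches labelling seasonal estimates from 2011
  onward when monitoring starts mid-2010.

`build_seasonal_histories()` produces one window per (season, year) with
monthly bins — 5 wet, 7 dry — retaining only individuals detected in the
window (as closed models require) together with every member sighting's
coordinates for the area estimate.

## The survival model

The Cormack–Jolly–Seber model conditions on first detection, so animals
can enter the marked population whenever they are first identified.
Between occasions, survival φ is constant within an age × sex cell
(9 cells; the unknown-sex class U is a real level, not missing data).
Detection is where individual hyenas differ enormously — den attendance,
boldness, range overlap with roads — so each individual carries a
log-odds deviation:

$$p_i = \mathrm{logit}^{-1}(\mu_p + \varepsilon_i), \qquad
  \varepsilon_i \sim \mathcal N(0, \sigma_p^2).$$

The likelihood of a history after first capture is computed by a
two-state forward recursion over alive/dead, marginalizing all death
times exactly; the familiar χ ("never seen again") term is the dead-state
accumulator. The test suite proves the recursion equal to brute-force
death-time enumeration on every 8-occasion history to 1e-10.

**Priors and sampling.** Every φ cell and the inverse-logit of μ_p are
Uniform(0, 1); σ_p is Uniform(0, 10) — wide enough that the data, not
the bound, decides (the bound is configurable via `mcmc_config()`).
Sampling is Metropolis-within-Gibbs, written in C++: logit-scale random
walks for φ cells and μ_p, per-individual walks for ε_i, a log-scale
walk for σ_p, with proposal step sizes adapted toward 44% acceptance
during burn-in only. Defaults mirror the analysis the package
reproduces: 3 chains × 5000 retained draws after 500 burn-in. The ε_i
are sampled jointly with the hyperparameters; a 20-node Gauss–Hermite
marginalization of the same likelihood is provided
(`cjs_marginal_loglik()`) as an independent cross-check and agrees with
dense numerical integration to 1e-4 in the tests.

**Annualization.** Non-cub classes see six 2-month steps per year:
annual φ is the step value to the 6th power. Cubs are first detected at
a mean age of 2.41 months (den emergence), leaving 9.59 months — 4.795
steps — of their first year observable, so cub annual survival is the
step value to the power 4.795. Annualization is applied per posterior
draw and then summarized, which preserves credible-interval coverage;
annualizing the posterior mean would not. A consequence worth
understanding: the "annual cub survival" this defines is survival from
first detectability to the first birthday, not from birth — mortality in
the den before emergence is unobservable by construction.

**Verification analyses.** Two model-free checks accompany every run.
`approximate_cub_mortality()` assumes cubs at dens are always detected,
counts cubs that could have reached age 1 before the study end, and
flags those never seen in an older class. Two ratios are reported:
never-resighted over resighted (the headline rate) and never-resighted
over all eligible, labelled `mortality` and `mortality_naive` — the two
are distinct whenever some cubs are censored, and both are printed so
the reader can choose. `collaring_effect()` refits the CJS model with an
additive logit-scale effect of radio-collaring on adult survival;
collaring is declared survival-neutral when the 95% credible interval of
the contrast spans zero (prior: Normal(0, 10²)). `fit_sex_specific_p()`
replaces the individual random effect with sex-level detection and
returns per-sex p — in data where rarely seen animals stay unsexed, the
U class comes out lowest, and that deficit is a diagnostic of the sexing
process, not a biological difference.

**Diagnostics.** Rank-normalized split R-hat and bulk ESS (Geyer initial
monotone sequence) are computed for every monitored parameter; any R-hat
above 1.1 flags the whole fit (`converged = FALSE`) with a warning —
never silently.

## Seasonal abundance and model choice

Closed models assume no births, deaths or movement within a season;
within a 5–7 month window for a long-lived territorial carnivore this is
the standard approximation, and it is exactly what the model assumes —
the simulator can violate it (animals do die mid-season there), which is
one reason the closed-model tests use purpose-built closed simulations
for their oracles.

Data augmentation appends all-zero pseudo-histories up to
M = ⌈factor × n_obs⌉ (default factor 3) and estimates each row's
inclusion probability ψ; N̂ = Σ w_i. If the upper 2.5% of N draws reach
M the fit is flagged and a larger factor advised — the default is a
guarded choice, not an assumption. M0 (shared p) enjoys fully conjugate
Gibbs updates; Mh adds a logit-normal deviation per (real or pseudo)
individual with Metropolis updates and prior refresh for excluded rows.

**DIC.** The per-draw deviance marginalizes both the inclusion
indicators and, for Mh, the individual deviations by Gauss–Hermite
quadrature, so the DIC focus is (ψ, μ_p, σ_p); the plug-in deviance uses
the posterior means of those parameters (Spiegelhalter's pD). Whether
latent quantities sit inside or outside the deviance changes DIC in
hierarchical models; this choice is fixed and documented here precisely
because it is a choice. Under heterogeneous truth (σ_p = 1, n = 200) the
suite requires ΔDIC > 10 in favour of Mh — the scaled-down version of
the decisive preference the seasonal data show — and M0's
well-known negative bias under heterogeneity is asserted directionally.

## Study area and density

The seasonal study area is the smallest region holding 90% of the
utilization mass of a Gaussian kernel density over all member sighting
locations (duplicates retained — they carry real utilization weight).
The bandwidth defaults to the reference (ad hoc) normal bandwidth
h = σ̂ n^(−1/6) of the home-range tradition, configurable; the grid is
the bounding box padded by 3h at 400 × 400 cells. The isopleth area is
computed by ranking cells by density and accumulating mass — tested
against the closed form for a single Gaussian kernel (2π·ln 10 ≈
14.47 km² at h = 1 km, within 2%), for monotonicity in the level, for
< 1% change under grid refinement, and for exact quadratic scaling.
Density divides every abundance draw by the area, so
`D_draws * A == N_draws` holds identically.

The first two wet seasons of a growing study typically lack a defensible
sighting-based area; `impute_wet_area()` substitutes the mean wet-season
area of 2013–2019 and marks the result `imputed_mean_wet_2013_2019` in
every table.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults describe the study system the package is built
around: 11 clans on a planar grid, ~21 animals per clan at start,
recruitment pulsed uniformly through the year, class-specific annual
survival (cub 0.75, subadult 0.99, adult 0.86) applied per 2-month step
as the annual rate to the power 1/6, logit-normal detection
(μ_p = logit 0.575, σ_p = 0.8), wet-season observation restricted to a
core subset of 6 clans, and a sexing process with
P(ever sexed) = 1 − exp(−k · detections). The published record gives no
recruitment rate, so it is a free knob; the defaults were calibrated
once against the descriptive scale of the study — roughly 660 known
individuals, ~58% of them sexed, ~20,000 sightings, ~13 known deaths —
and then left alone.

Two default features deliberately break the CJS model's assumptions,
because the real data break them too:

* the **wet-season clan restriction** makes detection occasion-dependent
  for non-core clans;
* the **sexing process** makes the U label a collider: animals are
  unsexed *because* they were rarely seen (low ε_i) or died young, so
  per-label survival estimates for U are biased low and F/M slightly
  high — the simulator reproduces this known limitation of the field
  analysis faithfully.

Parameter-recovery tests therefore use a model-matched variant
(`wet_range_contraction = 1`, everyone sexed): over 20 replicate
populations of ~650 individuals × 57 occasions, 95% credible intervals
must cover the generating rates for ≥ 90% of age × sex cells, with
coverage assessed on the 2-month scale where generator and model
parameterizations coincide for every class. Passing this says the
estimator is calibrated *when its assumptions hold*; it does not say
field estimates for the U class are unbiased — they are not, and the
run report should be read with that in mind. Other things the simulator
does not attempt: dominance hierarchies, dispersal between clans,
fission–fusion movement, birth seasonality.

## Numerical choices and degenerate inputs

* Forward recursion works in probability space (histories are ≤ 57
  occasions; no underflow at realistic rates); an impossible history
  under the proposed parameters returns −Inf and is rejected by the
  sampler.
* Empty φ cells (no individual ever occupies the cell) are refreshed
  from their prior and excluded from summaries and diagnostics.
* `augment(factor = 1)` is allowed but warned (it forces N̂ ≤ n_obs);
  all-zero rows in the *observed* matrix are rejected since augmentation
  supplies the zeros.
* The KUD wrapper passes 4h to `MASS::kde2d`, which divides its
  bandwidth argument by 4 internally; the tests pin the effective kernel
  sd to h against the analytic Gaussian.
* An isopleth level whose mass is not reachable on the padded grid is an
  error advising a larger `pad_factor`, never a silently truncated area.
* Dates are calendar-based throughout (anniversaries, not day counts /
  365.25), so class boundaries land exactly on birthdays.

## Problem sizes

The default test suite runs populations of roughly 650 individuals × 57
occasions for recovery (20 replicates at 3 × 1500 retained draws),
closed-model oracles at N = 200, and 400²–800² KUD grids; the full suite
completes in a few minutes on one core. Full-length chains (3 × 5000)
on one population take well under a minute; end-to-end pipeline runs
scale linearly in the number of seasonal windows.

## Known limitations

* Apparent survival confounds death with permanent emigration; nothing
  in the data can separate them.
* The U-class biases described above propagate into any quantity
  aggregated over sex labels.
* Closed-season abundance inherits whatever closure violations the field
  season contains; the models do not correct for them.
* Density compares N̂ (a population quantity) with an area estimated
  from *sighting* locations; where effort is spatially clustered the 90%
  isopleth under-covers the population's true range and densities are
  correspondingly optimistic. Seasonal areas make estimates comparable
  within, not across, effort regimes.
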