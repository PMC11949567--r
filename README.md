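# hyenademog

Demographic analysis of individually identified spotted hyenas (*Crocuta
crocuta*) from long-term sighting records: age- and sex-specific annual
apparent survival, seasonal abundance, and seasonal population density,
plus an agent-based population simulator with known ground truth for
validating the whole pipeline.

The package is aimed at carnivore ecologists working with photographic
capture–recapture data from clan-living species: sightings of known
individuals accumulate opportunistically and through focal follows, many
animals are never sexed, observation effort contracts seasonally, and the
monitored area grows over the years — all of which the estimators here
are built to accommodate.

## The models

**Survival.** Sightings are binned into 2-month occasions (June 2010 –
November 2019 gives 57 occasions by default). A Bayesian
Cormack–Jolly–Seber (CJS) model conditions on each animal's first
detection and estimates apparent bi-monthly survival φ with fixed effects
of age class (cub 0–1 y, subadult 1–3 y, adult 3+ y) and sex (F, M, and
an unknown class U), while detection is individual-specific:

    y[i,t] | alive  ~ Bernoulli(p_i),   p_i = logit⁻¹(μ_p + ε_i),
    ε_i ~ Normal(0, σ_p²)

The likelihood marginalizes the latent alive/dead process by forward
recursion (so the "never seen again" χ term is exact), and a
Metropolis-within-Gibbs sampler (Rcpp) draws φ-cells, μ_p, σ_p and the
ε_i jointly under uniform priors. Annual survival is computed per
posterior draw as φ⁶, except for cubs, which enter the data at a mean age
of 2.41 months and are annualized as φ^(6·(12−2.41)/12) = φ^4.795.
Convergence is checked with rank-normalized split R-hat and bulk ESS.

**Abundance.** Each wet season (December–April, 5 monthly occasions) and
dry season (May–November, 7 monthly occasions) is analysed with closed
capture–recapture models via data augmentation: an inclusion indicator
w_i with Pr(w_i = 1) = ψ turns unknown population size into a
zero-inflation problem, and N̂ = Σ w_i. Two detection structures are
fitted — shared p (M0) and logit-normal individual heterogeneity (Mh) —
and compared by DIC (ΔDIC > 10 read as decisive).

**Density.** The seasonal study area Â is the 90th-percentile isopleth
area of a kernel utilization distribution fitted to all member sighting
locations; density is the per-draw ratio D̂ = N̂ / Â, so its credible
interval inherits the abundance posterior exactly.

## Worked example

```r
library(hyenademog)

cfg <- run_config(
  sim = sim_config(n_clans = 5, initial_clan_size = 15,
                   study_end = as.Date("2014-06-01"), seed = 2024),
  mcmc = mcmc_config(n_iter = 1000, n_burnin = 300, seed = 7),
  seasons = c("dry-2011", "wet-2012", "dry-2012"), seed = 7)
report <- run_pipeline(cfg)
print(report)
```

```
Hyena demography run report
===========================
Seed 7, package version 0.1.0

Annual survival (mean [95% CRI]):
  cub       F  0.90 [0.70, 0.99]
  subadult  F  0.97 [0.88, 1.00]
  adult     F  0.88 [0.77, 0.96]
  cub       M  0.82 [0.59, 0.97]
  subadult  M  0.95 [0.82, 1.00]
  adult     M  0.90 [0.82, 0.97]
  cub       U  0.43 [0.26, 0.62]
  subadult  U  0.95 [0.83, 1.00]
  adult     U  0.75 [0.63, 0.85]

Cub mortality check: 26/81 never resighted after age 1 -> 47.3%

Seasonal density (median [95% CRI], /km^2):
  dry-2011  N= 88 A=  313.0 km^2  D=0.28 [0.28, 0.29]
  dry-2012  N=104 A=  352.6 km^2  D=0.29 [0.28, 0.32]
  wet-2012  N= 71 A=  194.8 km^2  D=0.36 [0.30, 0.50]
```

Reading the output: each survival row is the posterior of the annualized
apparent survival for one age × sex cell — note how the unknown-sex (U)
cells sit below the sexed ones, the signature of rarely seen animals
staying unsexed (and dying unnoticed). The cub-mortality line is the
model-free verification count (cubs are assumed perfectly detectable at
the den, so a cub never resighted past its first birthday is treated as
dead). Each density row divides the closed-model abundance posterior for
that season by the 90% isopleth area of that season's sightings; the
DIC comparison between M0 and Mh for every window is in
`report$dic_table`, and `write_run_report()` dumps all tables, the event
log and isopleth polygons (GeoJSON) to a directory.

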