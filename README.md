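# dissimogram

Quantifying the degree of randomness in the species composition of
spatially referenced ecological communities.

## The problem

When two nearby sites host different species, is that because their
environments differ, or because community assembly is partly a lottery?
`dissimogram` implements a spatial estimator of the stochastic fraction of
community composition, aimed at community ecologists working with
repeated regional surveys (breeding-bird point counts, vegetation plots,
microbiome samples with spatial metadata).

The estimator assumes the deterministic drivers of composition are
spatially autocorrelated while chance is not. Regress the pairwise Jaccard
dissimilarity `1 − |A∩B|/|A∪B|` of all site pairs on the geographic
distance between them (a *dissimogram*, the compositional analogue of a
variogram) and fit

```
Gompertz:              D(d) = a · exp(−b · exp(−c·d))
negative exponential:  D(d) = a − b · exp(−c·d)
```

by Gauss–Newton least squares. The fitted intercept — the **nugget**
(`a·e^−b`, resp. `a − b`) — is the dissimilarity remaining at zero
distance, interpreted as the fraction of composition driven by random
processes; the **asymptote** `a` is the dissimilarity between infinitely
distant sites. A nugget/asymptote ratio near 1 means composition is
indistinguishable from random; near 0, fully environment-driven.

Around that core the package provides the full analysis pipeline
(survey-record ingestion with max-over-rounds abundance and cumulative
species lists, management-intensity median splits, inter-annual turnover
filtering, Table-style across-year summaries with t confidence intervals),
MacKenzie-style single- and multi-season occupancy likelihoods for
detectability checks, and a spatially explicit metacommunity simulator
with a tunable deterministic/random mixture `rho` for validating the
estimator against known ground truth.

## Worked example

Simulate one region at a half-random mixture (`rho = 0.5`), build the
cumulative pair table and fit the dissimogram:

```r
library(dissimogram)

cfg <- sim_config(n_regions = 1, rho = 0.5, seed = 2112)
sim <- simulate_metacommunity(cfg)

years <- sort(unique(sim$surveys$year))
per_year <- lapply(years, function(yr)
  to_presence(max_abundance(sim$surveys, yr, plots = sim$plots$plot_id)))
cum <- cumulative_composition(per_year)
pairs <- build_pair_table(cum, sim$plots)

fit <- dissimogram(dissimilarity ~ distance,
                   data.frame(distance = pairs$distance_m,
                              dissimilarity = pairs$dissimilarity))
fit
#> Dissimogram fit (gompertz family), 1225 pairs
#>          a          b          c
#> 0.50731912 0.18360614 0.00002901
#> nugget: 0.4222  asymptote: 0.5073  pseudo-R2: 0.023
#> converged: TRUE  valid: TRUE
```

All 1,225 pairs of the 50 plots enter the fit. The nugget 0.42 against an
asymptote 0.51 (ratio 0.83) says most — but not all — of the compositional
variation in this half-random community looks random; the low pseudo-R²
(distance explains ~2% of the pairwise scatter) is typical and does not
invalidate the intercept. The one-call pipeline gives the across-year
summary instead:

```r
res <- run_analysis(sim$surveys, sim$plots, families = "gompertz",
                    strata = "all")
res$summary
#>   region stratum   family  mean     sd   min   max n
#> 1     R1     all gompertz 0.544 0.0108 0.532 0.555 5
```

`nugget_recovery_study()` closes the validation loop: the mean
nugget/asymptote ratio rises monotonically with the generating `rho`
(~0.4 at `rho = 0`, ~1 at `rho = 1` under perfect detection).

## Documentation

The methods vignette
(`vignettes/randomness-in-community-composition.Rmd`) describes the model,
its assumptions, the numerical choices in the fitter, what the synthetic
generator does and does not emulate, and known limitations.
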