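# reefstatus

Why do some coral reefs recover after a cyclone while their neighbours slide
into turf and macroalgae? `reefstatus` is an R package for monitoring
programs that want to answer that question statistically. It turns raw
monitoring records — point-intercept video transects, point-quadrat coral
censuses, stationary point counts (SPC) of fishes, belt-transect
macroinvertebrate counts, and watershed water-quality samples — into
site-level **recovery status**, and relates status to two manageable local
stressors, **water quality** and **herbivory**, including their
interaction. A seeded synthetic-data generator emulates a 17-site
high-island monitoring program so the whole pipeline can be exercised and
tested without field data.

## The statistics at the core

For each site *i*, replicate records are reduced to status metrics: percent
cover per benthic category, the benthic substrate ratio

  R = (coral + soft coral + coralline) / (macroalgae + turf + inhibitive coralline),

coral species richness per 1 m² quadrat, Margalef's d = (S − 1)/ln N,
herbivore biomass per SPC (W = A·L^B summed over scrapers, excavators and
detritivores), and macroinvertebrate density. Water quality enters as a
rank-based index (per constituent, watersheds ranked so lower concentration
= higher rank; the index is the mean rank and is invariant under monotone
transforms of concentrations). Variables are z-scored within geological
reef type; sites are classified high/low recovery by paired t-tests on the
temporal change of the two sensitive metrics; the continuous status score
is z(richness change) + z(substrate-ratio change). Candidate regressions

  status ~ β₁·x₁^λ₁ + β₂·x₂^λ₂ (+ product term x₁^λ₁·x₂^λ₂)

are fitted by OLS with exponents from a grid search and ranked by
AIC = n·ln(RSS/n) + 2(k + 1); the replicate-crossed interaction term is the
exhaustive cross-product of standardized replicate sets (its mean
factorizes exactly as mean(h)·mean(w)). The selected model is interpolated
over the water-quality × herbivory plane with a threshold contour at the
minimum status among high-recovery sites.

## Worked example

```r
library(reefstatus)

res <- run_pipeline(scenario_config(seed = 11), out_dir = "run")
#> reef type(s) 3 have < 3 sites and are excluded from standardized analyses

res$models$stressors$table[, c("rank", "model", "r_squared", "aic")]
#> # A tibble: 6 x 4
#>    rank model                           r_squared   aic
#>   <int> <chr>                               <dbl> <dbl>
#> 1     1 wq + herbivory + wq x herbivory    0.568   6.46
#> 2     2 wq x herbivory                     0.419   6.93
#> 3     3 (null)                             0      13.1
#> 4     4 wq                                 0.0699 14.0
#> 5     5 herbivory                          0.0300 14.6
#> 6     6 wq + herbivory                     0.0799 15.8

table(res$classification$category)
#>         high          low unclassified
#>           13            2            2

res$threshold
#> [1] -1.952806
```

The AIC table says the model containing the water-quality × herbivory
product term beats every additive and single-stressor alternative — the
synthetic world is interaction-dominated by construction, and the pipeline
recovers that from raw records alone. Thirteen sites kept both sensitive
metrics statistically stable (high recovery), two declined in both (low),
and the status threshold −1.95 is the weakest status still observed among
high-recovery sites. `autoplot(res$surface)` draws the contour surface with
that threshold dashed.

Individual stages are ordinary tibble-in/tibble-out functions and chain
with the pipe: `generate_study()`/`write_study()`/`read_study()`,
`estimate_cover() |> substrate_ratio()`, `richness_per_quadrat()`,
`margalef()`, `herbivore_biomass()`, `wq_index()`, `standardize()`,
`interaction_term()`, `classify_recovery()`, `status_score()`,
`compare_groups()`, `ks_size_comparison()`, `species_centered_pca()`,
`power_search()`, `fit_model()`/`select_model()` (with `tidy()`/`glance()`
methods), `build_surface()`.

## Acceptance script

`scripts/acceptance.R` re-runs the entire pipeline from scratch —
simulating the default 17-site scenario under the given seed, computing all
metrics and indices, classifying recovery, selecting models by AIC and
building the status surface — and writes the machine-readable report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/reefstatus-methods.Rmd`) documents the
model assumptions, every tunable default, what the synthetic generator does
and does not emulate, and known limitations.
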