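# heatmargin

Climate-vulnerability analysis for ectotherm heat tolerance: phylogenetic
imputation of critical thermal maxima (CT<sub>max</sub>), daily
plasticity-adjusted thermal limits, and overheating metrics aggregated
from local species occurrences to 1°×1° grid-cell assemblages.

The package is written for comparative physiologists and macroecologists
who have (a) a sparse laboratory compilation of heat-tolerance limits with
sampling errors and assay metadata, (b) a dated phylogeny, (c) species
occurrences on a grid, and (d) daily maximum operative body-temperature
series per cell, microhabitat and warming scenario — and who want
species- and assemblage-level overheating risk with honest uncertainty. A
synthetic-data generator reproduces the statistical structure of all four
inputs, so the whole pipeline runs and is tested entirely offline.

## The model

**Imputation (BACE — Bayesian augmentation with chained equations).** For
record *i* of species *s*:

    y_i = x_i' β + u_s + b_s (t_i − t̄) + ε_i,   ε_i ~ N(0, σ²_e / w_i),  w_i = 1/se_i²

with species intercepts `u ~ N(0, σ²_u (λ C0 + (1−λ) I))` — `C0` the tree
correlation matrix, so `λ` is Pagel's lambda (the phylogenetic proportion
of non-residual variance) — and acclimatization random slopes `b` with the
same structure. A Gibbs sampler (griddy-Gibbs step for each λ) fits
measured species; data-free tips get phylogenetic-conditional (kriging)
draws per posterior draw. Missing covariates cycle through
chained-equation sub-models. Output: for every species, standardized
CT<sub>max</sub> (mean ± SE) at the 5th/50th/95th percentile of the
range-wide daily maximum temperatures.

**Plasticity.** Per species, inverse-variance weighted regression of the
three standardized estimates on acclimatization temperature; the slope is
the acclimatization response ratio (ARR, °C/°C). Daily CT<sub>max</sub> is
the prediction at the trailing 7-day mean of daily maxima.

**Exposure and metrics.** Daily series are restricted to the warmest
contiguous 91-day quarter of each post-burn-in year (10 years × 91 = 910
days). Per occurrence: thermal safety margin TSM = CT<sub>max</sub> −
daily maximum (inverse-variance weighted mean); overheating probability
`Φ((T_d − CTmax_d)/σ)` with σ capped at 1 °C; expected overheating days
`p̄·910` with binomial SE `sqrt(910·p̄(1−p̄))`; binary risk = any day over
the point-estimate limit. Assemblage aggregation returns weighted TSM,
overheating-species counts and proportions per cell.

## Worked example

```r
library(heatmargin)

# A small synthetic world: 60 species on a Yule tree, half of them with no
# laboratory CT_max data, occurring between 25S and 25N.
cfg <- run_config(
  sim = sim_config(n_species = 60L, prop_missing = 0.5,
                   grid = list(lat = c(-25L, 25L), lon = c(0L, 2L)),
                   seed = 11L),
  n_cycles = 2L,
  mcmc = hm_mcmc_control(1500L, 500L, 2L),
  mcmc_cycle = hm_mcmc_control(500L, 200L, 2L, lambda_grid_n = 51L),
  mcmc_sub = hm_mcmc_control(300L, 100L, 2L, lambda_grid_n = 21L))
res <- run_full_pipeline(cfg)

print(res$bace$fit)
#> phylo_mixed_fit: 161 records, 60 species
#>   lambda = 0.816 (95% CI 0.520-0.980); var components: phylo 3.891,
#>   species 0.794, slope 3.29e-03, residual 3.349

round(summary(res$plasticity$slope_arr), 3)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.052   0.122   0.134   0.131   0.137   0.195

print(res$headline)
#> headline_stats over 60 species:
#>   scenario microhabitat n_overheating_species n_species_total pct_overheating
#> 1  current      aquatic                     0              60             0.0
#> 2    plus2      aquatic                     4              60             6.7
#> 3    plus4      aquatic                    14              60            23.3
#> 4  current     arboreal                    38              60            63.3
#> ...
#> 7  current  terrestrial                    58              60            96.7
```

Reading the output: the model recovers a strong phylogenetic signal
(posterior mean lambda 0.82, credible interval covering the generating
0.95) from 161 records; species-level ARRs centre on the generating 0.134
°C/°C; and overheating risk is ordered exactly as the biology dictates —
aquatic refugia buffer most, terrestrial ground level least, and every
microhabitat worsens monotonically from current through +2 °C to +4 °C.
(With heavy-tailed synthetic heat waves, "at least one exceedance day out
of 910" is far more common than in the real-world analysis; ratios and
orderings, not prevalences, are the comparable quantities at this scale.)

A command-line front-end mirrors the stages:

```sh
Rscript -e 'heatmargin::hm_cli()' simulate --out world --species 50 --seed 1
Rscript -e 'heatmargin::hm_cli()' impute --traits world/traits.csv --tree world/tree.nwk --cycles 5 --seed 1 --out imputed.csv
Rscript -e 'heatmargin::hm_cli()' expose --temps world/temps_terrestrial_current.csv --out exposure.csv
```

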