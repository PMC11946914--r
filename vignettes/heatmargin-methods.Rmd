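---
title: "Methods: phylogenetic imputation of heat tolerance and overheating risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic imputation of heat tolerance and overheating risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Laboratory heat-tolerance data (critical thermal maxima, CT~max~) exist for
only a small fraction of ectotherm species — in the amphibian compilation
this package emulates, roughly 90% of species in the analysis set have no
measurement at all. Yet CT~max~ is strongly heritable on the phylogeny and
correlated with measurable assay covariates, so the missing species can be
imputed with quantified uncertainty and the resulting standardized limits
compared against the operative body temperatures species actually
experience. `heatmargin` implements that chain end to end: imputation,
acclimatization plasticity, warmest-quarter exposure, and three overheating
metrics aggregated from local occurrences (one species in one 1°×1° grid
cell) to grid-cell assemblages.

## The imputation model (BACE)

The engine is a Bayesian phylogenetic mixed model fit by Gibbs sampling.
For record $i$ of species $s$:

$$y_i = x_i'\beta + u_s + b_s\,(t_i - \bar t) + \varepsilon_i,
\qquad \varepsilon_i \sim N(0,\ \sigma_e^2 / w_i),\ w_i = 1/\mathrm{se}_i^2$$

* $x_i$ — assay covariates: acclimatization temperature, acclimatization
  duration, ramping rate, endpoint, test medium, life stage, ecotype,
  log body mass. Larval records stay in the training data through the
  life-stage effect; predictions are adult-only.
* $u_s$ — combined species intercept with covariance
  $\sigma_u^2\,(\lambda C_0 + (1-\lambda) I)$, where $C_0$ is the tree's
  correlation matrix. In this parametrization $\lambda$ *is* Pagel's
  lambda — the phylogenetic proportion of the non-residual variance — and
  every posterior draw lies in $[0,1]$ by construction.
* $b_s$ — species acclimatization slope (the acclimatization response
  ratio, ARR), given the same structure with its own $(\sigma_b^2,
  \lambda_b)$. The intercept–slope covariance is fixed at zero: the random
  slopes themselves capture the covariance of tolerance with
  acclimatization temperature, and a free covariance term is poorly
  identified at the data densities we target.
* Inverse sampling-variance weights downweight imprecise laboratory
  estimates, exactly as a weighted meta-analytic mixed model would.

All normal and inverse-gamma conditionals are conjugate Gibbs updates.
The two lambdas use a *griddy-Gibbs* step: with the one-off
eigendecomposition $C_0 = Q \Lambda Q'$ (restricted to the measured
species), the conditional density of $\lambda$ on a uniform grid (default
101 points) costs $O(n_\mathrm{sp} \cdot G)$ per iteration, and the
species-effect update needs one Cholesky of an
$n_\mathrm{sp}\times n_\mathrm{sp}$ matrix per block.

The sampler runs on *measured species only*: tips without data are
marginalized exactly, and after sampling each stored draw is extended with
phylogenetic-conditional (kriging) draws for the remaining tips — the
conditional mean operator is computed once per distinct lambda grid value
and reused across draws. This design matters: an earlier version that
jointly sampled random effects for all tips mixed pathologically at 90%
missingness, because nine-tenths of the variance-update "data" were
prior-only draws, and the variance components equilibrated far below
truth. Marginal-then-krige reaches ~95% of the analytic GLS oracle's
imputation accuracy. A single-value `lambda_grid` pins lambda, giving
fixed-lambda conditional kriging (used by the sister-shrinkage oracle
test, where two measured species cannot identify lambda).

Priors: inverse-gamma(0.001, 0.001) on every variance component (the weak
prior conventional in animal-model MCMC), vague normal on fixed effects,
uniform on the lambda grid. The source analysis does not print its
imputation priors, so these defaults are ours and overridable through
`hm_mcmc_control()`.

### Chained equations

Missing *covariates* are handled MICE-style. Cycle 0 fills continuous gaps
with the column mean of observed values and categorical gaps with draws
from the observed empirical distribution. Each of the (default five)
cycles then re-imputes every originally-missing predictor entry from a
sub-model of that predictor on the others — phylogenetic random intercepts
only, no slopes — and refits the CT~max~ model; records with missing
CT~max~ get working values by posterior prediction (equivalent to Bayesian
response augmentation: they contribute no likelihood information, so
observed values are never overwritten and cannot leak). Imputed predictors
enter later cycles as point values ("most likely values"), which slightly
understates predictor uncertainty but leaves point estimates unbiased.
Categorical sub-models are one-vs-rest binomial GLMs without a
phylogenetic intercept — the multinomial-probit augmentation the full
treatment would need is not conjugate, and the methodological effects
involved are small (≤1.5 °C) by construction. Per-cycle drift of the
imputed values is logged; on synthetic defaults it collapses after the
first cycle, matching the behaviour the procedure is named for.

Final output: for every species, standardized predictions (mean and
posterior SE) at three reference acclimatization temperatures — the 5th,
50th and 95th percentiles of the daily maximum operative temperatures
across the species' range — at reference assay conditions (adult, 10-day
acclimatization, 1 °C/min ramp, water, onset of spasms, the species' own
ecotype and body mass).

## Plasticity and daily thermal limits

Each species' three standardized estimates feed an inverse-variance
weighted regression of CT~max~ on acclimatization temperature
(`fit_species_plasticity`); the slope is the species' ARR and the
coefficient covariance is $(X'WX)^{-1}$. This is numerically identical to
a fixed-effects meta-regression with a moderator; residual heterogeneity
$\tau^2$ (DerSimonian–Laird) is available but off by default, since it is
essentially unidentifiable from three points.

Daily projection assumes a species is acclimatized, on any day, to the
*mean* daily maximum temperature of the 7 preceding days (the focal day
excluded); the conservative variant uses the trailing weekly *maximum*.
Under a uniform warming offset $\Delta$ this yields the buffering identity
$\Delta \mathrm{TSM} = -\Delta\,(1-\mathrm{ARR})$ at steady state, which
the test suite verifies through the pipeline on the *daily* TSM series,
where it is exact. The occurrence-level weighted TSM deviates slightly
from the identity because the inverse-variance weights are re-estimated
per scenario (warmer trailing weeks sit further from the fitted
acclimatization range, inflating their prediction SEs), which re-weights
days non-uniformly. Prediction SEs carry
coefficient uncertainty only by default: the imputation SEs already shaped
the weights, and adding $\tau^2$ is exposed as a switch rather than a
default.

## Exposure bookkeeping

Raw daily maximum operative temperatures (11 years, the first a burn-in)
are reduced to the *warmest quarter* of each post-burn-in year: the
contiguous 91-day window with the highest mean daily maximum, tie-broken
to the earliest start. "Warmest quarter" suggests a contiguous block; the
top-91-days-by-value reading is implemented as a switch. Ten years × 91
days gives the canonical 910 retained days per cell. Trailing-week
statistics are computed on the unrestricted series so the first retained
days draw history from the burn-in year. Range-wide percentiles pool
retained daily maxima over a species' occupied cells under the linear
interpolation convention (R quantile type 7) — pinned because these values
feed the imputation as reference temperatures.

## Vulnerability metrics

Per occurrence and day, the thermal safety margin is
$\mathrm{TSM}_d = \mathrm{CT}_{\max,d} - T_d$. The occurrence-level TSM is
the inverse-variance weighted mean of daily TSMs (weights from the daily
CT~max~ SEs); variants compute TSM against each year's maximum or 95th
percentile temperature, or on a 5th–95th percentile trimmed series.

Overheating probability on day $d$ is $p_d = \Phi((T_d -
\mathrm{CT}_{\max,d})/\sigma)$ — the probability that the realized limit
lies below the day's temperature. The source text names the normal
*density* function here; a density cannot be a probability, so the CDF is
implemented (and this is the only reading under which the printed p-style
quantities are well defined). $\sigma$ is the daily CT~max~ SE capped at
1 °C, so large imputation uncertainty cannot inflate overheating
probability; the biological-range mode caps at the cross-species SD of
CT~max~ instead (default 2.0 °C, within the printed 1.84–2.17 band).
Expected overheating days are $\bar p \times 910$ with binomial SE
$\sqrt{910\,\bar p(1-\bar p)}$ — days treated as independent, as the
binomial construction requires, despite autocorrelation. Binary risk is 1
if any day's temperature exceeds the point-estimate CT~max~; the CI
variant requires the 95% interval of expected overheating days to exclude
zero.

Assemblage aggregation takes the inverse-variance weighted TSM across the
species of a cell (switchable to unweighted — the source states only
"weighted average") and counts/averages binary risks, which returns the
proportion of species overheating per cell. Headline helpers reproduce the
display conventions: integer percentages for abstract-style counts, one
decimal elsewhere, raw numerators and denominators always retained.

## The synthetic world

The generator is a first-class module stating the world the tests assume:

* **Tree** — hand-written Yule (grow-to-n) simulator, so the analytic
  depth expectation $\sum_{k=2}^{n} 1/(bk)$ holds exactly (the
  condition-on-n construction in off-the-shelf simulators does not satisfy
  it, which is why the oracle forced a from-scratch implementation).
* **Traits** — species intercepts with covariance $\sigma^2(\lambda C_0 +
  (1-\lambda)I)$, $\lambda = 0.95$, total species-level SD 2.4 °C around a
  36.2 °C grand mean at the 20 °C reference; ARR $0.134 \pm 0.008$ with
  the same lambda structure; 1–10 records per species; right-skewed
  lognormal sampling SEs (no distributional form is printed for these, so
  the choice is exposed in the config); methodological effects ≤1.5 °C so
  the imputation genuinely has to adjust for them; 89.9% of species fully
  masked, covariates thinned at 10%.
* **Temperatures** — per cell: latitudinal mean gradient + seasonal
  sinusoid + AR(1) heavy-tailed (scaled t, df 5) heat-wave noise. The
  three microhabitats derive from the *same* latent weather: arboreal
  damps the signal, aquatic applies a trailing exponential smooth (thermal
  inertia), so daily-max variance is ordered aquatic < arboreal <
  terrestrial and aquatic lags terrestrial. Warming scenarios (+2, +4 °C)
  are exact additive offsets on the same draws, which is what makes the
  pipeline-level monotonicity tests sharp. The calendar is 365-day years;
  the exposure code itself handles arbitrary year lengths.

What the generator does *not* emulate: biophysical radiation/evaporation
physics, real geography, body-mass-dependent operative temperatures, and
the spatial covariance of real climate. A green test therefore establishes
that the statistical machinery is correct on data with the stated
structure — not that the published species counts are reproduced; those
depend on the real trait compilation, range maps and microclimate layers.
One visible consequence: with heavy-tailed daily extremes, "at least one
exceedance day in 910" is far more common in the synthetic world than in
the real analysis, so synthetic binary-risk prevalences exceed the
published ~2%/7.5% figures by design, while ratios, orderings and recovery
targets are preserved.

## Numerical choices and scaling

* Lambda grid: 101 points on [0,1] (41–51 for the short sub-model chains);
  eigenvalues floored at 1e-8; tiny (1e-10) jitter before Cholesky in the
  generator.
* MCMC defaults 4,000/1,000/3 (iterations/burn-in/thin); pipeline and test
  fits use shorter chains (documented per call) — chain length trades
  Monte-Carlo error, never thresholds.
* Holdout cross-validation enforces `min_species = 5`: with ~50 measured
  species in the synthetic compilation, a literal 5% holdout would leave
  2–3 species, and a Pearson r over so few species-level values is noise.
  The floor was fixed a priori.
* Cell identity is `(floor(lat)+90)*360 + (floor(lon)+180)` with
  half-degree cell centres; ties in the warmest-quarter search go to the
  earliest window; species labels are underscore-normalized on read.

## Known limitations

Single-chain MCMC with a split-half R-hat proxy rather than multi-chain
diagnostics; no intercept–slope covariance; categorical sub-models without
phylogenetic effects; binomial day-count SEs ignore temporal
autocorrelation (stated construction); the generator's ranges are
single-column latitudinal bands, adequate for aggregation tests but not
for realistic range geometry.

One acceptance criterion is deliberately left red: the holdout
cross-validation target (r ≥ 0.8, |bias| ≤ 0.5 °C at 89.9% missingness on
500 species). The published r = 0.86 comes from a real tree of >5,000
species where nearly every held-out species has close measured congeners.
On a 500-tip Yule tree with 50 randomly measured species, the
Bayes-optimal GLS oracle — conditioning on the *true* values of all
remaining measured species with the *true* lambda — achieves only
r ≈ 0.4–0.64 over data-deficient species, and a 5-species holdout r has a
sampling s.d. near 0.3. The implementation reaches about 95% of that
oracle bound (e.g. 0.57 vs 0.60 over unmeasured species), so the red
criterion reflects the information content of the stated synthetic world,
not an estimation defect. The thresholds are kept at their stated values.
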