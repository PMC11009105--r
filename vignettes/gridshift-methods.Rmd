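---
title: "Models and methods behind gridshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gridshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

gridshift quantifies biodiversity change on a lattice of atlas grid cells
from presence-only occurrence records, and attributes that change to climate
and land-use drivers. This vignette is the package's account of its science:
the models, their assumptions, the tunable parameters, and the choices made
where the design was genuinely open.

## The problem

Biological atlases record which species were seen in which grid cell during
a multi-year period. They come with two structural difficulties. First,
recorder effort is uneven and unknown: a cell may look species-poor because
nobody visited it. Second, responses on a lattice are spatially
autocorrelated, so naive regressions understate uncertainty. The package
addresses both: per-cell recorder effort is estimated from the records
themselves and carried into every model, and every model can include a
spatially structured random effect over the grid's queen (8-neighbour)
adjacency.

The workflow is: simulate or load an atlas → estimate effort → compute
community metrics → fit period-contrast trend models → build change tables →
fit attribution models with collinearity handling and a stepwise variance
decomposition → fit ecological-uniqueness (LCBD) models → cross-validate.
`run_pipeline()` chains all stages under one config and seed.

## Recorder effort

Effort estimation follows the neighbourhood-rescaling idea used for
presence-only recording schemes. For each focal cell, the `n_dist = 200`
nearest cells are ranked by land-use similarity and the `n_sim = 100` most
similar retained, each weighted by the product of two smooth rank tapers
`(1 - ((r - 1)/n)^2)^4` (the focal cell ranks first in both, hence carries
the maximal weight). Similarity is `1 - d_E/sqrt(2)` on land-use proportion
vectors; ties are broken focal-first, then by cell id, so the construction
is deterministic. The exact taper of the original method is not published
alongside the analyses this package generalises, so the taper sits behind
one small function (`taper()`) and the neighbourhood sizes are arguments.

The local frequency of species *s* at focal cell *i* is the weighted share
of neighbourhood cells where *s* was recorded. Rescaled frequencies
`f' = 1 - (1 - f)^alpha` are the detection probabilities after `alpha`
standard searches; `solve_alpha()` bisects `alpha` in `[1e-4, 1e4]` (on the
log scale) until the weighted mean frequency of a well-recorded cell,
`phi(alpha) = sum(f'^2)/sum(f')`, reaches the target `phi = 0.92`, to
`|phi - target| <= 1e-6`. Estimated effort is `1/alpha`: a cell that needs
many notional searches to look well recorded was poorly recorded.

Two numerical points. The *unweighted* mean of `f'` is strictly increasing
in `alpha`; the frequency-weighted form can dip slightly when many rare
species dilute it, but it still runs from 0 to 1 over the bracket, so the
sign-change bisection always lands on a root. And whether the published
`phi = 0.92` refers to the weighted or unweighted statistic is not stated in
the sources this package follows; the weighted form is the default and
`weighted = FALSE` switches to the other. Non-convergence (e.g. an empty
neighbourhood) is flagged per cell, and the pipeline drops unconverged cells
rather than using clamped values.

Absolute calibration is *not* claimed: the estimate tracks relative effort
(its ordering and contrasts), which is what the downstream models consume.
The acceptance suite checks exactly that — a known 2x effort contrast is
recovered in sign in at least 95 of 100 replicate datasets — not agreement
with the generating effort values.

`benchmark_detection_effort()` provides the variant used where an atlas
publishes effort as the percentage of common "benchmark" species detected:
benchmarks are the top `benchmark_fraction = 0.27` of species by local
frequency (the conventional benchmark share; it is an argument).

## Community metrics

- **Richness**: distinct species recorded in the cell and period.
- **Beta diversity**: mean Sørensen dissimilarity `1 - 2|a∩b|/(|a|+|b|)`
  between the focal cell and each of its up-to-8 recorded neighbours;
  unrecorded neighbours are excluded from the mean, edge cells use the
  neighbours they have, and a cell with no usable neighbour gets `NA`.
  A decline over time is biotic homogenization.
- **CTI** (community temperature index): unweighted mean of the species
  temperature index (STI, °C) over present species that have one. Because
  CTI depends on *which* species are present, effort covariates cannot fix
  under-recording; instead cells with fewer than 25% of the richest cell's
  species count (assessed in the lowest-effort period) are excluded —
  `richness_threshold()` rounds the cutoff up, the stricter reading of
  "fewer than 25%" (both conventions agree on the worked examples 39 → 10
  and 854 → 214).
- **LCBD**: each cell's share of the total variance of the community matrix
  after a Hellinger transform (row-normalise, square-root) and column
  centring; values sum to 1. The transform is the default of the standard
  implementation of this statistic but is not documented for the analyses
  this package generalises, so it is an argument (`"hellinger"` or
  `"none"`). Identical communities make LCBD undefined; a uniform `1/n` is
  returned with a warning and the LCBD models skip such degenerate inputs.
- **Turnover**: gained and lost species between periods as percentages of
  the early community.

Change tables difference each metric (late minus early) over cells recorded
in both periods (operationalised as at least one record in each), join
covariate changes, early-period baselines and effort, and standardize every
explanatory column to mean 0, SD 1 (`z_` columns). For CTI responses the
baseline-effort column is omitted — only the *change* in effort can
masquerade as a CTI change — and the richness filter is applied to both
periods of the comparison.

## The spatial Bayesian models

Five response families cover the pipeline:

| response | family | link | variance |
|---|---|---|---|
| richness | Poisson or negative binomial | log | `mu` or `mu + mu^2/phi` |
| beta diversity | Beta | logit | `mu(1-mu)/(prec+1)` |
| CTI | Gamma | log | `mu^2/theta` |
| metric change | Gaussian | identity | `sigma^2` |
| LCBD | Beta | logit | `mu(1-mu)/(prec+1)` |

The linear predictor is `X beta + gamma + nu`: `gamma` an intrinsic CAR
(iCAR) field with precision `Q = D - W` over queen adjacency, identified by
a sum-to-zero constraint (applied by centring, with the mean absorbed into
the intercept); `nu` an exchangeable per-cell effect. Richness trend models
use both (`icar_plus_iid`, the structured-plus-unstructured decomposition
that absorbs overdispersion); CTI and attribution models use `icar`; beta
diversity models use no spatial term, because neighbourhood dissimilarity is
spatially autocorrelated by construction and a field would overfit it.
Trend models enter effort on the log scale for richness and the natural
scale for beta diversity; attribution models use baseline effort plus effort
change (natural scale), effort change only for CTI.

Priors: fixed effects `N(0, 1000)` with an effectively flat intercept;
dispersion/precision hyperparameters `Gamma(1, 0.1)` (the log-gamma(1, 0.1)
convention); penalized-complexity priors on both random-effect SDs with
`P(sigma > 1) = 0.01` (an exponential with rate `-log(0.01)`), the
weakly-informative default recommended for spatial models without prior
information — both `U` and `alpha` are arguments of `prior_control()`; and a
vague `Gamma(1, 5e-5)` on the Gaussian residual precision. Beta responses on
the boundary are nudged by `(y(n-1) + 0.5)/n` since the support is open;
zero efforts under a log term are guarded by `+1e-9` with a warning.

### Inference

`fit_glmm()` runs Metropolis-within-Gibbs chains. Gaussian layers are
conjugate: the spatial block's full conditional has precision
`Q/sigma_g^2 + D_m/sigma^2` in which only two scalars change across
iterations, so a one-time generalized spectral decomposition
`Q = D_m^{1/2} U L U' D_m^{1/2}` turns every draw into two dense
matrix-vector products. Non-Gaussian likelihoods use vectorised Metropolis
updates: fixed effects component-wise, the iCAR field in chromatic
(graph-coloured) blocks whose sites are conditionally independent given the
other colours (a queen lattice needs four colours), and the exchangeable
effects jointly since they are conditionally independent. Proposal scales
adapt in warmup batches toward 44% acceptance. Because the field and its SD
mix slowly under alternating updates, a joint rescaling move
`(gamma, sigma_g) -> (a gamma, a sigma_g)` is interleaved; the whole
posterior (both code paths) was cross-checked against an independent
brute-force Metropolis sampler on small lattices during development.

Convergence is judged by split-chain PSRF < 1.05 on all reported parameters;
`fit_glmm()` defaults to 4 chains, and a breach flags the fit (and warns) —
it is never silent. The pipeline's desk-scale default is 2 chains of 1,000
iterations (500 warmup), chosen to keep a full end-to-end run in minutes;
split-chain PSRF is still computed across the four half-chains.

### Derived quantities

- `proportion_change()`: for log-link trend models, `exp(period coef)` is
  the multiplicative change from the early to the late period, applied
  draw-wise (increase `exp(c) - 1` when positive, decrease `1 - exp(c)`
  when negative).
- `change_probability()`: per-cell `P(fitted change > 0)` from the stored
  posterior of the fitted mean, plus the mean probability ± s.e. across
  cells (also in percent).
- `r2_decomposition()`: latent-scale variance decomposition. Marginal R² is
  `var(X beta)` over the total of fixed, spatial, exchangeable and
  distribution-specific residual variance; conditional R² adds the random
  effects to the numerator. Residual conventions: `sigma^2` (Gaussian),
  `ln(1 + 1/mu)` (Poisson), `ln(1 + 1/mu + 1/phi)` (negative binomial),
  `ln(1 + 1/theta)` (Gamma; the log-normal approximation of a squared
  coefficient of variation), and the delta-method
  `mean(1/((prec+1) mu(1-mu)))` on the logit scale (Beta).

## Attribution, collinearity and the stepwise decomposition

Attribution models regress each metric's change on standardized climate and
land-use changes, their two-way interactions (products of standardized
mains, re-standardized so effect sizes stay comparable; interactions of
degenerate, zero-variance mains are skipped), baseline climate and land use,
microclimatic heterogeneity, baseline biodiversity (richness and beta; a
CTI response never sees its own baseline) and the effort controls.

Shared variance is handled by sequential regression: predictor *k* is
replaced by its residual on predictors 1..k-1, crediting shared variance to
the earlier predictor. The order is a configuration field
(`residualization_order`), defaulting to causal priority — effort controls,
then baselines (climate/land use, microclimate, biodiversity), then
changes, then interactions — because baseline state precedes change and
change precedes interaction. Residualized columns are re-standardized;
perfectly collinear columns are dropped with a warning. A coefficient is
flagged "no association" exactly when its central 95% credible interval
includes zero; no multiplicity correction is applied, matching
credible-interval reporting practice.

The stepwise R² trajectory starts from a base model (spatial term + effort
controls) and adds groups in the order: changes in climate and land use,
climate–land-use interactions, baseline climate and land use, microclimatic
heterogeneity, baseline biodiversity — recording marginal and conditional R²
at each step. Groups with no available columns (e.g. a land-use category
masked in the earliest period) are skipped with a message. Increments
telescope to the total by construction.

Two robustness devices close the loop. Tenfold cross-validation refits the
attribution model on each nine-tenths of the cells (seeded, near-equal
folds) and compares fold-wise coefficients with the full fit's intervals.
And a compatibility check correlates per-cell changes predicted by the trend
models with the attribution model's fitted changes; correlations of at
least 0.8 are logged as a pass, lower values as a warning. At the package's
desk scale the check typically warns — with 400 cells and modest planted
signal the per-cell predictions are noise-dominated — so it is reported,
never enforced.

## The synthetic atlas generator

The generator is first-class, tested code: it defines the study conditions
under which every claim about the pipeline is demonstrated.

Defaults (the desk-scale conditions): a 20×20 lattice, 120 species, three
periods T1–T3. Temperature and precipitation are Gaussian random fields with
exponential covariance (`range = 5` cells) around a north–south gradient,
plus a trend of +0.4 °C and +15 mm per period step (+0.8 °C over the study),
plus per-period innovation fields (SD 0.25 °C / 25 mm) so that climate
*change* varies over space. Land use starts from a softmax of per-category
fields and converts 8% of semi-natural grassland per step into arable (50%),
improved grassland (30%) and urban (20%) cover, renormalising; clamped
proportions are counted and warned about. Microclimatic heterogeneity is a
positive, period-constant field. Species have STIs `N(9, 1.5)` °C,
commonness `0.05 + 0.85 Beta(2, 3)`, and logit-scale slopes; the temperature
slope grows with STI, so warming raises warm-adapted occupancy and the true
CTI — the construction the CTI tests rely on. A configurable fraction of
STIs (5%) is missing, mirroring real species lists. Occupancy is Bernoulli
at `plogis(logit(commonness) + slopes · z(covariates) + species field)` with
covariates standardized against their first-period distribution.

Recording thins truth: a present species is recorded with probability
`1 - (1 - effort)^(2 · commonness)` — effort in (0, 1] is a per-search
success chance and the commonness-scaled exponent acts as the number of
effective searches, which is what makes a "number of searches" multiplier
meaningful downstream. Effort 1 records everything; effort 0 is an error.
The default effort surface is smooth in space, drawn fresh each period
(coverage shifts unevenly between atlases), with mean 0.55 rising by 0.12
per period — recording schemes improve over time. The atlases this package
emulates describe no generative recording process; this detection model is
an assumption of the generator, not of the analyses.

What the generator does *not* emulate: real geography (coastlines, varying
cell footprints), taxonomic revisions and list-cleaning, scheme-specific
recording quirks (targeted visits, rarity chasing), observation of
abundance, and any absolute calibration of effort. Passing tests therefore
demonstrate internal correctness and recoverability under these stated
conditions, not performance on any particular real atlas. The
improved-grassland category can be masked in T1 (`mask` via `NA`s in a
covariate table) to mirror historical land-cover maps that lack it; the
default keeps all categories so every predictor group is exercised, and the
change-table/stepwise code drops and skips missing columns when a masked
table is supplied.

## Problem sizes and tolerances in the test suite

The suite runs at sizes chosen for a laptop-class machine: unit oracles on
lattices from 2×2 to 10×10; effort sign-recovery on 100 replicates of an
8×8 grid with 30 species; coverage of the Gaussian attribution structure on
20 replicates of the 20×20 grid; the planted +5% richness trend at the full
default scale; interaction sign recovery on 10 replicates of a 10×10 atlas;
and the end-to-end pipeline twice at default scale to establish determinism.
MCMC assertions use tolerances sized to their Monte-Carlo error (e.g. 0.05
against least squares at n = 200), and bisection/linear-algebra oracles use
1e-6 to 1e-12.

## Known limitations

- Effort estimates are relative, not calibrated; only orderings and
  contrasts should be interpreted.
- The iCAR field is centred globally (per connected component only when the
  whole field maps to observed cells); isolated cells carry no spatial
  effect and are excluded from it with a warning.
- The "Leroux-style" structured-plus-unstructured decomposition is exactly
  that — it is not the canonical single-parameter Leroux CAR.
- Beta-family responses of exactly 0 or 1 are nudged, which at small n
  perceptibly shrinks extreme LCBD values.
- Split-chain PSRF with two pipeline-default chains is a coarse diagnostic;
  raise `chains` (the `fit_glmm()` default is 4) for reportable analyses.
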