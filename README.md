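# coraldemog

Stage-structured demographic modelling of coral populations on remote
atolls: how do reef corals recover from mass mortality when most of their
recruitment arrives from elsewhere, and what happens to coral cover when
human pressure — near-field (habitation: pollution, nutrification,
overfishing, turbidity) or far-field (climate change: bleaching, disease,
acidification) — chips away at recruitment and periodically kills the
standing stock?

The package is written for population ecologists and reef scientists who
want a tested, reproducible implementation of this class of analysis:
size-based Lefkovitch matrices built by Monte-Carlo resampling of
literature life tables, open-population projection with larval
immigration, eigenvalue elasticities, hindcast fitting of recruitment and
disturbance-survival assumptions, and multi-decade impact forecasts. All
user-facing functions take and return tibbles (or small S3 result objects
with `tidy()` / `glance()` / `autoplot()` methods), so analyses compose
with the pipe.

## The model

Five size classes, defined by colony radius, correspond to coral life
stages: spat (<1 cm), recruits (<5 cm), juveniles (<10 cm), mature medium
colonies (10–20 cm) and large colonies (>20 cm, open-ended). The
population vector **n**(t) evolves by the affine projection

    n(t+1) = A n(t) + nu

where **A** is a 5×5 stage-transition matrix and **nu** is an immigration
vector, zero except for externally supplied spat entering the smallest
class — the open-population term that models larval connectivity among
reefs. Fertility (local recruitment) may additionally occupy A[1,4] and
A[1,5]; with it zeroed the population is fully open.

Matrix entries come from stage survivals σᵢ and fixed stage durations Tᵢ:
the probability that a surviving individual advances out of stage *i* in a
year is

    gamma_i = (sigma_i^T_i − sigma_i^(T_i − 1)) / (sigma_i^T_i − 1)

with the limit 1/Tᵢ as σᵢ → 1, giving growth rates Gᵢ = σᵢγᵢ
(subdiagonal) and loops Pᵢ = σᵢ(1 − γᵢ) (diagonal), so Gᵢ + Pᵢ = σᵢ. The
open-ended largest class is absorbing (P₅ = σ₅). Uncertainty in the life
tables is propagated by combining per-stage (σ, T) draws independently in
10,000 Monte-Carlo trials and averaging the trial matrices arithmetically;
the spread of the dominant eigenvalue λ across trials measures parameter
uncertainty, and without fertility every trial matrix is substochastic, so
λ < 1 always.

Coral cover is proxied by giving each colony the circular area at its
class's representative radius (1, 3, 5, 10 cm for classes 2–5; spat are
invisible in phototransects) and summing.

On top of this sit: eigenvalue **elasticities** (Caswell's
e./λ · vᵢwⱼ formula, averaged over a fertility grid), a global
**sensitivity** ranking of fertility vs recruitment level vs recruitment
timing, a **hindcast** grid search that projects candidate
(fertility, yearly-import, 1998-survival) assumptions from a
post-bleaching start and accepts those reproducing a later observed size
distribution to within 10% in every class, and **impact scenarios**
combining cumulative annual recruitment loss (additive: 1 %/yr = 50% lost
by year 50) with episodic mortality of the non-recruit classes every 8
years.

## Worked example

```r
library(coraldemog)

lt <- life_table(c(0.02, 0.35, 0.65, 0.84, 0.92), c(1, 2, 3, 5))
tm <- build_transition_matrix(lt)
tm
#> <transition_matrix: branching_encrusting>  lambda = 0.9200
#>          spat recruit juvenile medium large
#> spat     0.00  0.0000   0.0000  0.000  0.00
#> recruit  0.02  0.2593   0.0000  0.000  0.00
#> juvenile 0.00  0.0907   0.5175  0.000  0.00
#> medium   0.00  0.0000   0.1325  0.725  0.00
#> large    0.00  0.0000   0.0000  0.115  0.92
```

λ = 0.92 < 1: without immigration this population declines 8% a year.
Supply 1000 spat a year from outside and it recovers from bare substrate:

```r
project_series(tm, rep(0, 5), recruitment = 1000, years = 8,
               mode = "imported_only") |> tail(3)
#>    year class_1 class_2 class_3 class_4 class_5 cover_cm2
#> 1     6    1000    27.0    4.55   0.976  0.0946      320.
#> 2     7    1000    27.0    4.80   1.31   0.199       386.
#> 3     8    1000    27.0    4.93   1.59   0.334       454.

cover_from_distribution(affine_fixed_point(tm, 1000))
#> [1] 1526  # cm^2 of live cover at the open-population equilibrium
```

Eight years after a mass mortality the modelled transect carries ~450 cm²
of cover, still climbing toward its ~1500 cm² equilibrium — the
hindcast-style recovery the package fits against observed size
distributions. Forecasts then follow from `run_scenario()` /
`synergy_grid()`; `chagos_like_world()` and `generate_recovery_fixture()`
build the fully synthetic study system (life-table pools, phototransects,
recovery trajectories with known ground truth) used throughout the tests,
and `run_pipeline()` executes the whole chain into an output directory
with a reproducibility manifest.

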