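# lumrewb

Land-use-mix exposure in sausage network buffers, and random-effects
within-between (REWB) models of walking and cycling.

## The problem

Whether a more mixed residential environment makes middle-aged and older
adults walk or cycle more is usually studied cross-sectionally, which
confounds environmental effects with residential self-selection. A
longitudinal design follows people who *stay at the same address* while
the land use around them changes, and separates two questions:

* **between individuals** — do people whose surroundings are, on average,
  more mixed walk/cycle more than people in less mixed surroundings?
* **within individuals** — when the mix around a (non-moving) person
  changes over the years, does their walking/cycling change with it?

`lumrewb` implements that full exposure-to-inference pipeline for
panel cohorts with geocoded residences, plus a synthetic world with known
ground truth so every stage is testable without restricted cohort data.

## Exposure: entropy in sausage network buffers

The residential environment is the *sausage network buffer*: all road
segments reachable within a network distance d (default 500, 1000 and
1600 m) of the residence — walking along accessible roads only, highways
excluded — dilated by a 25 m corridor and unioned. Land-use mix (LUM)
inside a buffer is the normalized entropy over an N = 11 class scheme,

    LUM = - [ Σ_j p_j ln p_j ] / ln N ,

with p_j the share of class j in the buffer area and 0·ln 0 = 0. LUM is 0
when a single class covers the buffer and 1 for a perfectly even mix. N
stays fixed at the scheme size regardless of how many classes occur, so
scores are comparable across buffers and years. Each survey wave is
linked to the land-use snapshot of a *preceding* year (exposure precedes
outcome). In the models the score is multiplied by 10 so coefficients
read as minutes/week per 10% change in mix.

## Inference: the REWB (hybrid/Mundlak) model

Outcomes (average minutes/week walking or cycling, harmonized from the
SQUASH and LAPAQ questionnaires) are modelled as

    PA_it = β0 + β1W (x_it − x̄_i) + β2B x̄_i + β3 Z_i + β4 γ_it + v_i + ε_it

with x̄_i the person's mean exposure (between part), x_it − x̄_i the
deviation from it (within part), Z_i time-invariant covariates (sex,
education, cohort), γ_it time-varying covariates (age, marital status,
income, employment), and a random person intercept v_i. Estimation is
REML via `lme4`, inference is Wald; covariate missingness is handled by
chained-equations multiple imputation with Rubin pooling. On balanced
data the within coefficient equals the fixed-effects estimator and the
between coefficient equals the between-means OLS slope — the "best of
both worlds" property, which the test suite verifies to 1e-6.

## Worked example

```r
library(lumrewb)

cfg   <- world_config(seed = 42)        # synthetic world, known truth
world <- generate_world(cfg)
net   <- build_network(world$roads)     # drops highways, merges endpoints

b   <- network_buffer(c(2050, 1950), net, d = 1000)  # 1000-m sausage buffer
tab <- clip_land_use(b, world$parcels_by_year[["2003"]])
entropy_lum(tab)
#> [1] 0.2656802

panel <- generate_panel(cfg)            # truth: β1W = -5, β2B = +10 (walking)
panel$lum_scaled_1000 <- panel$lum_scaled_true
fit <- rewb(walk_min_wk ~ sex + education + age + marital_status + income +
              employment + cohort_id,
            data = panel, exposure = "lum_scaled_1000")
fit
#> REWB random-intercept model (REML), outcome: walk_min_wk
#>   2000 persons, 6000 person-observations; exposure: lum_scaled_1000
#>   within  (x_dev):    0.527  [-9.495; 10.549]
#>   between (x_bar):    7.995  [3.007; 12.983]
#>   var(v_i) = 2581.124, var(eps) = 10031.829
```

The entropy 0.266 says this buffer is about a quarter of the way from a
single-use to a perfectly even 11-way mix. In the model fit, one
simulated realization of the default world, the between effect (7.99
minutes/week per 10% of mix, CI excluding 0) is recovered near its truth
of +10, while the noisy within effect (truth −5, per-replicate SE ≈ 5)
lands at 0.5 with a wide interval — single panels rarely pin the within
effect down, which is why the test suite checks recovery over 200
replicates. `run_pipeline()` chains the full sequence (buffers →
exposure → harmonization → non-mover restriction → imputation → pooled
REWB fits) and `inst/cli/lumrewb.R` exposes `simulate` and `run`
subcommands over it.

## Acceptance script

`scripts/acceptance.R` recomputes the package's analytic entropy anchors
from scratch — the score of a buffer split exactly equally among all 11
classes and the score of a single-class buffer — and writes them to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
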