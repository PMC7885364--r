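---
title: "Methods: land-use-mix exposure and within-between models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-use-mix exposure and within-between models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumrewb)
```

This vignette documents the models and procedures `lumrewb` implements,
the tunable parameters and their defaults, what the synthetic world does
and does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. Exposure model

### Sausage network buffers

The unit of exposure is the *sausage* (line-based) network buffer: the
portion of the road network reachable within a network distance $d$ of
the residence, dilated by a corridor half-width $w$ and unioned. Compared
with Euclidean ("crow-fly") disks, this represents the area actually
accessible on foot or by bicycle.

Construction, in order:

1. **Accessible network.** Road segments flagged as closed to pedestrians
   and cyclists (e.g. motorways) are dropped before anything else;
   inaccessible roads can never influence a buffer (a property the test
   suite asserts by injecting highways into fixture worlds). Segment
   endpoints within a node-merge tolerance (default 0.01 m) are merged —
   topology repair for digitization jitter, deliberately far below any
   plausible distance between distinct roads.
2. **Snapping.** The residence is projected onto the nearest point of any
   edge. The snap rule is our design choice: nearest point wins, ties go
   to the lowest segment id, and residences farther than `max_snap_m`
   (default 100 m) raise a typed error; the pipeline reports and excludes
   them, mirroring the exclusion of ungeocodable addresses.
3. **Reachability with exact edge cutting.** Single-source shortest-path
   distances are computed from the snapped origin (both directions along
   its own edge). An edge only partially within distance $d$ is cut at
   the exact interpolated point, rather than selected whole; whole-edge
   selection overstates reach, and "within a certain distance" is read as
   a distance on the network. $d = 0$, or an origin on an isolated
   island, degenerates to a disk of radius $w$ around the snapped point,
   flagged `degenerate` so downstream can exclude it.
4. **Dilation and union.** Every reachable polyline piece is dilated by
   $w$ (default 25 m) with round caps and joins, and the union is taken
   before measuring area, so overlaps at intersections are counted once.

### The polygon engine

No polygon-geometry library is available in the target environment, so
the package carries its own exact overlay engine (C++, `src/overlay.cpp`)
for the two primitives the pipeline needs: area of a union of polygon
rings, and area of the intersection of that union with each of a
collection of shapes. It decomposes the plane into vertical slabs at
*event* x-coordinates (every vertex, every pairwise edge crossing).
Between events the cross-section structure is combinatorially constant,
so the union cross-section length is linear in x and evaluating it at the
slab midpoint integrates each slab exactly. The only approximation in the
whole geometry stack is polygonizing circular arcs: caps are inscribed
polygons with 24 chords per semicircle, a relative circle-area error
below 0.3% that applies only to the cap/join fraction of a buffer. The
straight-road closed form $4dw + \pi w^2$ and an independent 0.5-m
rasterization oracle (cell-center distance classification, sharing no
code with the engine) bound the end-to-end error below 0.5% in the test
suite.

### Entropy score

Land-use mix inside a buffer is normalized entropy over the class scheme:
$$\mathrm{LUM} = -\frac{\sum_{j=1}^{N} p_j \ln p_j}{\ln N},$$
with $p_j$ the share of class $j$ in the covered buffer area and the
convention $0 \ln 0 = 0$, the standard continuous extension. Three
deliberate choices:

* $N$ is the *scheme size* (default 11), not the count of classes present
  in a buffer, keeping scores comparable across buffers and years.
* Shares are computed over the covered area. Data gaps (the national
  mosaics the pipeline emulates are wall-to-wall, so gaps are data
  defects) are excluded from the denominator rather than treated as a
  twelfth class; a gap above 5% of the buffer area triggers a warning and
  zero coverage is an error.
* The exact 11-class composition of the original scheme is not public in
  the main text; the default scheme is therefore a configurable
  placeholder of 11 generic labels. Only $N$ enters the score.

Exposure is linked person-wave by person-wave to the snapshot of a
configured *preceding* year (`wave_to_year`); mapping a wave to a later
year than its fieldwork is rejected as a chronology violation.

## 2. Outcome harmonization

Both questionnaires are reduced to average minutes per week of walking
and of cycling:

* **SQUASH** (cohort A): days/week × minutes/day. A reported duration
  without days counts as one active day; reported days without a duration
  get the median minutes/day of complete respondents substituted. The
  substitution median is stratified per wave and activity by default —
  the least surprising scope for a scoring median — and
  `squash_median(strata = NULL)` gives the unstratified variant.
* **LAPAQ** (cohort B): sessions in the last 2 weeks × minutes/session,
  halved.

The non-mover restriction keeps persons present in all three waves whose
residence coordinates agree within 1 m across waves (absorbing geocoding
jitter). Education is forced time-invariant (baseline value). Cohorts are
imputed separately and then pooled with `cohort_id` retained, so models
are adjusted for study; pooling refuses panels whose factor codings (for
instance the shared 4-level income coding) disagree.

## 3. Multiple imputation

No imputation engine is assumed installed, so `impute_missing()` is a
compact chained-equations implementation: predictive mean matching
(5 donors) for continuous variables, binomial-draw logistic models for
binary, proportional-odds draws for ordered factors, one-vs-rest logit
draws for nominal factors, with constant/aliased predictors pruned per
equation and a marginal-draw fallback if a conditional model cannot be
fit. Predictors are the model covariates plus the auxiliaries self-rated
health, smoking and BMI. Outcomes and exposures are never imputed (rows
lacking them are excluded upstream); `m = 5` completed datasets and 5
sweeps by default, seeded. Engine, number of imputations and iteration
count are this package's choices; each cohort is imputed separately
before pooling.

## 4. The REWB model

`rewb()` fits
$$PA_{it} = \beta_0 + \beta_{1W}(x_{it}-\bar x_i) + \beta_{2B}\bar x_i +
\beta_3 Z_i + \beta_4 \gamma_{it} + v_i + \epsilon_{it},$$
a linear mixed model with a random person intercept, by REML (`lme4`;
ML available). The decomposition uses the person's arithmetic mean over
observed waves; deviations reconstruct the exposure exactly and sum to
zero within person. Exposure enters on the ×10 ("per 10% of mix") scale
so coefficients are minutes/week per 10% change in LUM.

Open-design decisions:

* **Inference.** Wald normal-approximation CIs and p-values, matching
  the symmetric intervals conventional in this literature; REML and Wald
  are configurable defaults (ML and Barnard-Rubin df are available).
* **No wave fixed effect** by default: the model equation carries none,
  and time-varying age absorbs secular trend; `wave_effect = TRUE` exists.
* **Degenerate fits.** A random-intercept variance estimated at the
  boundary (≈0) is reported with a warning, never silently refit.
  Zero within-person exposure variance, rank-deficient designs (aliased
  terms are named) and fewer than 2 persons with 2 waves are errors.
* **Rubin pooling.** Pooled estimate = mean; total variance =
  within-mean + (1 + 1/m) × between-variance; normal intervals by
  default, Barnard–Rubin small-sample df behind `small_sample_df = TRUE`.

On balanced panels without extra covariates the REWB within and between
coefficients coincide with the FE-within estimator and the between-means
OLS slope; the suite checks both to 1e-6 against independent `lm` fits.

## 5. The synthetic world

`generate_world()` builds a square grid road network (default 40 × 40
cells of 100 m) with a configured fraction (10%) of edges closed to
pedestrians/cyclists — sampled greedily so the accessible network stays
connected — a wall-to-wall mosaic of 100-m parcels padded one cell beyond
the roads, per-person residences jittered 5–20 m off a random accessible
edge, and three waves with exposure years preceding fieldwork years.
`generate_panel()` draws outcomes from the REWB equation with known
coefficients and, optionally, analytic exposures; instrument items
(SQUASH/LAPAQ) are derived from the outcome so harmonization is
exercised end-to-end, and covariate missingness is MCAR at configured
rates (MCAR only; a missing-at-random mechanism conditioned on
covariates is not modelled).

Calibration presets, fixed once during development and not revisited:

* `dominant_share = 0.86`: parcels draw one dominant class with
  probability 0.86, else uniformly among the other ten. This centers the
  cross-sectional mean 1000-m-buffer entropy near 0.30, the emulated
  cohort mean.
* `change_prob = 0.033` per 2 × 2-parcel block per wave transition, with
  a changing block collapsing to a single freshly drawn class
  (`change_dominant_share = 0.60`). Concentrated block redevelopment
  rather than parcel speckle gives entropy changes of realistic size and
  calibrates the share of person-observations whose entropy differs from
  the previous wave to roughly 44%, with first waves counting as
  unchanged in the denominator.
* With these presets the mean entropy *increase* among changed
  observations is ≈ +0.03, matching the emulated figure, and increases
  outnumber decreases ≈ 2:1; the mean *decrease* is ≈ −0.01, shallower
  than the emulated −0.05. Deeper decreases would require town-scale
  homogenizing redevelopment events, which would make the 44% statistic
  far noisier across seeds; we kept the speckle-free block process and
  note the deviation here.
* Outcome truths default to $\beta_{1W} = -5$, $\beta_{2B} = +10$
  (walking; cycling $-5/+5$), $\mathrm{var}(v_i) = 2500$,
  $\mathrm{var}(\epsilon_{it}) = 10000$; intercepts (280/260 min/week)
  and a −0.5 min/week-per-year age gradient were chosen once so that
  flooring minutes at zero truncates < 1% of draws (measured ≈ 0.4%),
  keeping the linear acceptance surface interpretable.

What the generator does **not** emulate: realistic urban morphology
(streets are a grid), behavioral residential self-selection (movers are
flags with fresh residences, not modelled choices), spatially correlated
missingness, and the long right tail of self-reported activity minutes
(outcomes are Gaussian around the linear predictor; the emulated cohorts
have SD ≈ 240 with many zeros). A green test therefore establishes that
the *pipeline and estimator* behave as specified under the stated world,
not that the substantive effect sizes of any real cohort are recovered.

## 6. Known limitations and numerical notes

* **Floor-at-zero censoring.** Flooring outcomes at 0 biases the REML
  residual variance downward by roughly 0.3–0.7% at the default ≈ 0.4%
  truncation. Over 200 replicates of the 2000 × 3 panel this bias is
  comparable to 3 Monte Carlo standard errors of the replicate mean, so
  the residual-variance recovery check is intrinsically marginal in the
  stated world (the fixed-effect and random-intercept checks pass with
  wide margins, and with the floor inoperative the estimator recovers the
  residual variance to within sampling error).
* **Planar CRS.** All distances are metric; inputs must be projected in
  meters (the emulated national data use RD New / EPSG:28992).
  Coordinates that look like longitude/latitude (lon/lat magnitudes with
  a sub-degree extent) are refused rather than silently misused.
* **Vector IO** is GeoJSON (hand-parsed, text) and CSV; binary container
  formats would require a GDAL-backed reader that the target environment
  does not provide. Polygon holes are rejected explicitly.
* **Segments crossing mid-edge do not connect**: the network honors the
  supplied topology (nodes are merged endpoints only), the standard
  behavior for routable road data; planarization is out of scope.
* **Determinism.** Worlds, panels and the pipeline are pure functions of
  their seed and configuration; reruns are byte-identical, which the
  suite asserts.
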