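---
title: "Quadrat-based spatial coupling of CD8+ TILs and cancer cells: models and methods"
author: "quadtil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrat-based spatial coupling of CD8+ TILs and cancer cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadtil)
```

## Scope and data model

`quadtil` analyses two-class planar point patterns — the coordinates of
cancer cells and CD8+ T cells exported by an image-analysis platform
from a resected tumor slide — together with a subject-level clinical
table. All coordinates enter in micrometres "as exported" and are
rescaled exactly 1:1000 to millimetres; every operation downstream is
translation- and reflection-invariant, so the export's axis orientation
is irrelevant.

The observation window of a subject is the bounding box of all of that
subject's annotated points (both classes). The platform's tumor-region
polygon is not exported with the points, and the bounding box is the
only window reproducible from the coordinates alone; since quadrats
empty of both classes are discarded anyway (next section), the choice
affects little beyond the raster extent of the display maps.

## Preprocessing: TIL selection and subject inclusion

Only CD8+ cells within 50 um of a tumor gland are treated as
tumor-infiltrating lymphocytes; cells at exactly the threshold are kept
(the rule is "less than or equal"). When the platform supplies a
distance-to-gland column it is preferred, because it measures distance
to annotated gland *objects*; otherwise the package falls back to the
distance to the nearest cancer-cell centroid and records which source
was used per subject. Distances are exact (all-pairs, chunked), not
approximate.

Subjects with fewer than 10 cancer cells or fewer than 10 CD8 cells are
excluded, with the reason recorded. The rule is applied after TIL
filtering by default — the excluded subjects are those with inadequate
residual cancer, and the downstream models only ever see filtered
cells — but a pre-filter variant is available
(`quadtil_config(inclusion_after_filter = FALSE)`).

## Quadrat counting

The window is tessellated into 500 um x 500 um quadrats anchored at the
window's minimum corner, with `ceiling(extent / size)` rows and columns
so partial edge quadrats are included as ordinary quadrats (their area
deficit is absorbed by the count model, which carries no area offset).
Cells are half-open `[lo, hi)` with the last row and column closed, so
every point belongs to exactly one quadrat and none is lost on the
maximum edge. Quadrats with zero counts for both classes — mostly
outside the cancer region — are flagged inactive and excluded from all
statistics.

One consequence of zero-zero exclusion worth knowing: a quadrat with no
cancer cells stays active only if it happens to contain a CD8 cell.
Where cancer-free quadrats occur *inside* the analysed region, this
selection slightly inflates the apparent CD8 level at zero cancer and
therefore attenuates a fitted slope by a small amount (of the order of
a tenth of the slope's sampling SD in the regimes exercised here). It
is a property of the zero-zero rule itself, not of the estimator; the
parameter-recovery checks therefore generate tumor-region quadrats
(at least one cancer cell each, the regime the rule is meant to carve
out), and the effect is absent there.

## The subject-level coupling statistic

For each subject, over active quadrats $j$:

$$\mathrm{cd8}_j \sim \mathrm{NB}(\mu_j, \theta), \qquad
\log \mu_j = \alpha + \beta \, \mathrm{cancer}_j ,$$

fitted by maximum likelihood with $\theta$ estimated jointly
(`MASS::glm.nb`-style alternation). The slope $\beta$ — the spatial
coupling of CD8 load to local cancer load — is the quantity carried
forward. Through the log link, an increment of $n$ cancer cells
multiplies the expected CD8 count by $\exp(n\beta)$, exposed as
`fold_change(beta, n)` and printed to 2 decimals at the presentation
layer (slopes to 4).

Edge cases: if the $\theta$ estimate diverges (variance $\approx$ mean)
the subject is refit as a Poisson GLM and flagged, keeping the slope
comparable; constant cancer counts are a degenerate design and an
error; subjects whose fit does not converge after the fallback are
excluded from cohort models and always reported. The per-subject model
is intentionally plain intercept-plus-slope — no area offsets, no
spatial autocorrelation adjustment — treating quadrats as independent
observations.

## Cohort-level contrasts

**Log-slope regression.** OLS of $\log\beta$ on treatment, sex, age
(linear, years), tumor grade and stage; reference levels are naive, G1
and stage I. The slope distribution is right-skewed, hence the log.
A slope can be non-positive, and no transform of a negative slope
reproduces a log; the default policy excludes such subjects and reports
their ids (`excluded_nonpositive`), with a shifted-log
$\log(\beta + c)$ sensitivity variant behind
`policy = "shift"`. The treatment coefficient $c$ exponentiates to the
implied NAT/naive ratio of coupling slopes.

**Heterogeneity regression.** The quadrat-wise standard deviation of a
subject's cancer counts proxies intratumoral heterogeneity; OLS with
the same covariates estimates the NAT effect on it (negative = NAT more
homogeneous). Covariates with a single observed level are dropped with
a warning; genuinely aliased designs are an error naming the terms.

**NB mixed model.** Pooling all subjects' active quadrats:

$$\log \mu_{ij} = \beta_0 + b_i + \beta_c\,\mathrm{cancer}_{ij}
 + \beta_t\,\mathrm{NAT}_i
 + \beta_{ct}\,\mathrm{cancer}_{ij}\mathrm{NAT}_i,
 \qquad b_i \sim N(0, \sigma_b^2),$$

with NB response and a subject random intercept only (a random-slope
extension would re-ask the per-subject question the GLM already
answers). The fixed effects are the model's scientific content:
$\exp(100\beta_c)$ is the naive 100-cell fold change,
$\exp(100(\beta_c+\beta_{ct}))$ the NAT one, and
$\exp(100\beta_{ct})$ their ratio. Main-effect clinical covariates are
deliberately not included — the model contrasts count-coupling, not
survival. Fitting is Laplace-approximate ML (glmmTMB, `nbinom2`). As a
verification mode, `method = "agq"` refits by adaptive Gauss-Hermite
quadrature (lme4, at least 5 nodes; 7 by default) with $\theta$ fixed
at the Laplace estimate — no available engine offers AGQ with a free NB
size parameter — and the two agree to well under 1% relative on the
fixtures tested. Non-convergence is never silent: the optimizer code
and Hessian status are attached and warned about.

## Survival analysis

Subjects are dichotomised at the whole-cohort median slope
(`HigherSlope` iff $\beta \ge$ median; ties go Higher; `LowerSlope` is
the reference). Kaplan-Meier curves use the product-limit estimator
with log-log confidence intervals for the median; a curve that never
crosses 0.5 reports its median as not reached. The multivariate Cox
model (Efron ties — the low-bias default of the survival ecosystem;
the data source is silent on ties handling) includes the slope group,
treatment, sex, the dichotomised `AgeCat` (cutoff 70 years, the cohort
median age, with 70 itself in the upper level), grade and stage. A
HigherSlope hazard ratio below 1 reads as protection. Monotone
likelihood (separation) is detected and flagged; sparse stage levels
can optionally be collapsed into the adjacent level, logged. Linear age
is available as a configuration alternative.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, and its defaults *are*
the study conditions the models are calibrated to:

| parameter | default | rationale |
|---|---|---|
| subjects | 27 naive + 39 NAT | cohort arm sizes |
| window | 8 x 6 mm | ~192 quadrats of 0.5 mm |
| cancer process | Thomas: $\kappa$ = 3/mm2, $\mu$ = 38 (naive); $\kappa$ = 12/mm2, $\mu$ = 9.5 (NAT); $\sigma$ = 0.1 mm | equal intensity 114 cells/mm2 (~28 cancer cells per active quadrat, ~5k cells/subject); few large glands vs many small ones gives the NAT arm a quadrat-wise cancer SD lower by ~12 counts |
| slope law | $\beta \sim$ lognormal, arm medians 0.0078 / 0.017, sdlog 0.6 | observed arm medians; spread covers the observed slope range |
| CD8 law | NB, $\alpha \sim N(\log 2.4, 0.5)$, $\theta = 2$ | ~5 CD8 per active quadrat |
| TIL band | emitted CD8 carry platform distances in [0, 50] um; a ~30% background beyond 50 um is added for the filter to remove | exercises the filter without distorting the NB law |
| survival | exponential, slope-group HR 0.33, NAT HR 2.0, grade/stage/age log-HRs 0.2-1.2; baseline median 678 d at the centred linear predictor | cohort-scale survival with ~73% events under Uniform(0, 3500 d) censoring |
| ages | uniform-normal mixture on 46-88 y | median 70, ~49% at 70+ |

Each subject consumes an RNG stream derived from the master seed, so a
cohort is byte-reproducible and stable under subject-level parallelism.
CD8 placement has two modes: the *quadrat-generative* mode (counts
drawn from the exact NB law, points uniform within the quadrat — the
generative twin of the fitted model) and a *continuous* mode
(inhomogeneous Poisson with intensity $\exp(a + b\cdot$ smoothed cancer
density$)$, reducing to homogeneous Poisson at $b = 0$).

What the generator does *not* emulate: cell morphology, segmentation
error, pathologist annotation drift, irregular (non-rectangular) tumor
regions, and spatial autocorrelation of CD8 counts beyond what the
shared cancer surface induces. Passing recovery tests therefore
demonstrate correctness of the estimators under the stated generative
laws, not robustness to those real-data features.

## Numerical and testing choices

* Distances and binning are exact and are tested against brute-force
  enumeration oracles; the boundary conventions (50 um kept; half-open
  quadrats, last row/column closed; $\beta \ge$ median goes Higher) are
  asserted at their exact boundary points.
* The Cox implementation is cross-checked against a direct optimization
  of the explicitly coded Efron partial likelihood on a 6-subject toy
  with a tied death; Kaplan-Meier against a hand product-limit
  computation.
* Parameter-recovery checks run at deliberately modest sizes chosen as
  typical for this design — ~200 active quadrats per subject, cohorts
  of 60-200 subjects, hazard-ratio replication at a four-fold cohort —
  and estimate population quantities (bias, coverage, type-I error)
  from enough replicates that their Monte-Carlo error is small against
  the bound being checked.
* Null-calibration of the Cox Wald p-value is checked at the four-fold
  cohort size: with 9 parameters and ~48 events the Wald test is
  measurably anti-conservative (a known small-sample artifact of the
  normal approximation, visible here as ~7.6% type-I error at the 5%
  level), so uniformity is an asymptotic property and is tested where
  the approximation holds (~5.8% type-I at n = 264).
* The quartic (biweight) kernel density maps use bandwidth 0.25 mm
  (half a quadrat) by default, no edge correction; they are
  presentation-layer only and no downstream statistic consumes them.
* Degenerate inputs fail loudly and specifically: missing columns,
  non-numeric coordinates (with line numbers), empty cancer sets,
  constant designs, all-censored groups, empty treatment arms.

## Known limitations

The per-subject GLM ignores residual spatial autocorrelation between
neighbouring quadrats; quadrat size is fixed at 500 um by convention
and results carry the usual modifiable-areal-unit caveat; the
log-slope model cannot represent non-positive slopes except by
exclusion or shift; and the Cox model assumes proportional hazards
without diagnostic testing. These mirror the boundaries of the analysis
design the package implements, and extending them is out of scope.
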