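---
title: "Regional WMH burden and cognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional WMH burden and cognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bullseyeWMH)
```

White-matter hyperintensities (WMH) are bright lesions on T2/FLAIR MRI with
a presumed vascular origin. Their cognitive impact depends not only on how
much lesion tissue a person carries but on *where* it sits: periventricular
lesions cross long association tracts, juxtacortical lesions mostly short
U-fibres. This package implements a complete analysis chain for that
question — segmentation of WMH from multimodal intensities, a 36-region
"bullseye" parcellation of the white matter, probability-mass volumetrics,
and covariate-adjusted rank-based association with cognitive scores — plus
a seeded synthetic generator so every stage is testable without clinical
data. This vignette documents the models, their assumptions, the tunable
parameters and the design decisions that were genuinely open.

## The segmentation model

Voxel intensities over the co-registered channels (T1-like, FLAIR-like,
FSE-like) are modelled as a multivariate Gaussian mixture with two kinds of
classes:

* **healthy tissue** — CSF, cortical grey matter and white matter, each
  with one or more full-covariance Gaussian components. Spatial tissue
  priors (here derived from the phantom's labels, optionally smoothed;
  in clinical pipelines from atlas propagation) enter as voxel-wise mixing
  weights scaled by `1 - outlier_prior`, the standard prior-constrained EM
  formulation. There is no Markov-random-field smoothing; spatial
  information enters only through the priors.
* **unexpected observations** — a single broad Gaussian (mean at the global
  intensity mean, covariance `outlier_cov_inflation` = 4 times the pooled
  healthy covariance) with constant voxel-wise weight `outlier_prior`
  (default 0.05). Lesions, artifacts and partial-volume exotica land here.

Two safeguards keep the decomposition identifiable, both adopted after the
obvious free-for-all formulation proved degenerate:

1. the outlier component's parameters are *fixed* at their broad
   initialization (`outlier_update = FALSE`). A freely updated outlier
   component drifts into the dense healthy bulk and stops being an outlier
   model at all.
2. during model selection, a candidate in which a *healthy* component
   becomes FLAIR-hyperintense (its FLAIR mean above the grey-matter
   reference plus `flair_hyperintensity_k` SDs) is rejected. Otherwise a
   second white-matter component happily absorbs the lesions — they are,
   after all, a coherent Gaussian blob — and the outlier class never sees
   them.

The number of components per healthy class is chosen per subject by greedy
incremental search over the Bayesian information criterion: starting from
one component each, the class whose split most improves BIC gains a
component until no admissible addition improves it or
`max_components_per_class` (default 2) is reached. BIC was chosen as the
simplest standard reading of "balance between model fit and complexity";
the search never removes components.

EM runs to a relative log-likelihood change below `em_tolerance` (1e-5) or
`em_max_iters` (100). Monotonicity of the log-likelihood is asserted at
every iteration (tolerance 1e-8 relative); a singular covariance is
ridge-regularized by `1e-6` times the mean channel variance, escalating
tenfold until Cholesky succeeds.

**Lesion probability.** The candidate map is the posterior responsibility
of the outlier class, gated to voxels whose FLAIR intensity exceeds the
fitted grey-matter FLAIR mean by `flair_hyperintensity_k` SDs (default
1.5). A gate is required because the outlier class also absorbs
*hypo*intense unexpected observations; grey matter is the brightest healthy
FLAIR tissue, so "brighter than GM plus margin" is the natural
hyperintensity criterion. False-positive correction then zeroes probability
outside white matter and basal ganglia and removes 26-connected components
of the thresholded (&gt; 0.5) map smaller than `min_lesion_size` voxels
(default 3). Total probability mass never increases under correction.

## The bullseye parcellation

Depth is the ratio `d = d_v / (d_v + d_c)` of Euclidean distances to the
ventricular surface and the cortical sheet, so `d = 0` on voxels touching
the ventricle and `d = 1` on voxels touching the cortex. Distances are
taken to the nearest surface-voxel centre minus one voxel, which puts
face-adjacent voxels exactly on the surface on the default isotropic 1 mm
grid. The ratio field was preferred over Laplace-equation streamlines as
the simplest field that is 0/1 on the two surfaces and supports equidistant
binning; the choice matters little for layer volumes at these geometries.

Layers are the four equidistant half-open bins `[0, .25), [.25, .5),
[.5, .75), [.75, 1]` — `layer = 1 + floor(4 d)` with `d = 1` closed into
layer 4, stated explicitly so voxel counts are bit-reproducible. Layer 1 is
the most periventricular band. Crossing layers with the nine lobar segments
(frontal, temporal, parietal, occipital, left/right, plus basal ganglia)
gives `region_id = (lobe - 1) * 4 + layer` in the fixed order FR, FL, TR,
TL, PR, PL, OR, OL, BG — the order used by every table and plot. Layered
voxels without a lobe label are counted as "unassigned", reported and
excluded from the total load rather than silently dropped or silently
included.

Basal ganglia use the same depth field and the same two reference surfaces
as everything else.

## Quantification

The load of region *r* is the lesion-probability mass over *r* times the
voxel volume; `load_total` is the sum over the 36 regions. Relative load
divides by the region volume. Additivity of the regional decomposition is
exact by construction and asserted in tests to 1e-6 relative.

## Cognition and association

Fourteen outcomes (seven verbal-memory-binding outcomes, seven WAIS-IV
subtests) are z-scored against the analysis sample itself — the wording
"normalized raw scores" implies internal normalization, not external norms
— and averaged unweighted within domain to give `memory_z` and
`executive_z`. Semantic proactive interference (second-list learning as a
percentage of first-list learning) is included in the memory composite by
default; both that inclusion and the weighting are configurable because
neither is fixed by the method description. A subject who learned no
first-list words has an undefined interference score: flagged missing,
never imputed.

The association engine, for every predictor (total and 36 regional loads)
crossed with every outcome:

1. residualizes the load on age, sex, education, APOE-ε4 allele count and
   total intracranial volume, and the outcome on the same covariates minus
   TIV, by ordinary least squares with intercept ("adjusted" is not further
   specified by the method; rank-based residualization is available as a
   robustness option). Residual orthogonality is asserted on every call.
2. computes Spearman's rho (Pearson on mid-ranks) between the residuals,
   with a Fisher-z 95% CI.
3. computes a permutation p-value by reassigning the outcome vector
   `n_perm` times *without resampling* — each reassignment a bijection —
   and, in the default literal mode, counting the permutations whose rho is
   **lower** than the observed one, divided by `n_perm`. This left-tail
   definition can return exactly 0 and is directional; it is sensible here
   only because every hypothesized load–cognition association is negative.
   A two-sided mode and an add-one smoothing option `(1+k)/(1+N)` are
   provided and used wherever a calibrated two-sided test is wanted.

The regional tests of one outcome share a permutation stream (cheaper,
marginally valid); independent streams per cell are a switch. Significance
is flagged at p &lt; 0.05 with **no** multiplicity correction in the
headline map, mirroring the original analysis across 37 × 16 cells; a
Benjamini–Hochberg column is reported alongside, clearly labelled as an
extra. Missing values are dropped listwise per analysis cell with counts
reported. Sensitivity re-runs append extra confounders (cardiovascular
risk, depression, medial-temporal-atrophy scores as generic numeric
columns) to both covariate sets and report sign and significance flips per
cell.

Fisher-z was chosen for the CIs; with n in the hundreds it is numerically
indistinguishable from bootstrap intervals for |rho| &lt; 0.2, but the
choice is a convention, not a derivation.

## The synthetic generator

**Image level.** The phantom is a set of concentric ellipsoids (ventricular
CSF core, white-matter shell, 2.5 mm cortical sheet) with eight angular
lobar sectors and a ninth basal-ganglia segment, rendered at 1 mm isotropic
resolution with Gaussian channel noise (SD 6 intensity units against a
lesion–WM FLAIR contrast of 50). The basal ganglia are two lateral
ellipsoidal blobs that touch the ventricle medially and reach toward the
cortex laterally. A closed shell ring around the ventricle — the obvious
alternative — makes a complete parcellation impossible: it blocks every
cortical lobe's periventricular layer and itself spans only shallow depths,
so a full 36-region table could never occur. Spherical lesions (radius 2–4
mm) are planted in white matter and basal ganglia with placement
probability proportional to `exp(-bias * depth)` (default bias 2, favouring
periventricular lesions) and a fitting constraint that keeps each sphere
inside the white-matter domain. What the phantom deliberately does *not*
model: cortical folding, bias fields, registration error, partial-volume
anisotropy (the clinical FLAIR/FSE are 1×1×3 mm), and non-Gaussian noise.
Passing recovery tests on phantoms therefore demonstrates correctness of
the estimation machinery, not clinical segmentation accuracy.

**Table level.** Generating hundreds of full phantoms for statistics tests
would be waste; the cohort generator draws regional loads directly. Total
WMH load is log-normal with median 1.94×10³ mm³ and quartiles
1.13–3.69×10³ mm³ (the reference distribution), with log-load rising 0.07
per year of age and the residual spread reduced accordingly so the marginal
quartiles still match. The 36 regional loads are Dirichlet shares of the
total (concentration 50), with expected shares weighted by layer
(periventricular-heavy: 0.40/0.25/0.20/0.15) and lobe (occipital and
frontal heaviest, basal ganglia lightest) to mirror the reported regional
distribution. This construction makes the regional sum exact, keeps every
load positive and right-skewed (sample skewness well above 1), and induces
realistic inter-region correlation through the shared total. Covariates
follow the reference cohort: age 57.4 (7.5), 60.9% female, education 13.7
(3.5) years, APOE-ε4 counts with probabilities 0.490/0.383/0.126, TIV
log-normal around 1.42×10⁶ mm³. QC flags fire with probabilities 10/608
and 37/608.

Cognitive scores are generated on a latent z-scale:
covariate terms (−0.25 per age-SD, +0.30 per education-SD) plus planted
effects plus Gaussian noise (SD 0.9), then mapped to each outcome's
reference mean/SD and clamped to its printed range. Planted effects
`beta[r, m]` multiply the *standardized, age-adjusted log load* of region
r, so beta is interpretable as a latent partial Pearson correlation:
with the default noise, `beta = -0.3` yields a residualized Spearman rho of
about −0.25 to −0.30 (the rank transform and the skew-induced nonlinearity
absorb the difference). With `beta = 0`, loads and cognition are
independent given covariates — the null-calibration property the
permutation tests are checked against.

## Numerical choices and degenerate inputs

* Connected components use 26-connectivity on the 0.5-threshold map.
* A white-matter voxel with zero distance to both surfaces raises a
  geometry error naming the voxel; constant vectors make Spearman rho
  undefined (flagged NA, never silently propagated); zero-variance
  subtests abort composite computation by name; rank-deficient adjustment
  designs abort listing the collinear columns.
* Permutation tie handling: statistics equal to the observed value up to
  1e-10 are treated as ties, so the discrete left-tail count matches
  exhaustive enumeration at small n.
* Every generator and every permutation stream is a pure function of its
  seed; identical seeds give byte-identical tables.

## Problem sizes used in the test-suite

The suite exercises full 48³ default phantoms for the parcellation and
recovery checks (ten seeded phantoms for the recovery experiment), 40³
phantoms elsewhere; permutation calibration uses 500 simulated cohorts of
n = 200 with 400 permutations each in two-sided mode, and the
planted-effect experiment 50 cohorts of n = 500. These sizes give
Monte-Carlo error comfortably below the asserted bands while keeping the
suite quick to run.

## Known limitations

* The phantom's geometry is convex and noise Gaussian; segmentation
  performance numbers on it are upper bounds.
* The left-tail permutation p-value is the literal historical definition;
  for any two-sided scientific claim use `sidedness = "two_sided"`.
* The equidistant-layer volume balance holds for slab-like geometry only;
  on curved shells outer layers are genuinely larger — the parcellation is
  equidistant in depth, not equal-volume.
* Bootstrap CIs for rho are not implemented; Fisher-z is used throughout.
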