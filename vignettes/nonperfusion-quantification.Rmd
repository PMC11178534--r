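---
title: "Quantifying retinal nonperfusion on a spherical model eye"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal nonperfusion on a spherical model eye}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retnpi)
```

## The measurement problem

Ultra-widefield (UWF) fluorescein angiography images most of the retina in a
single frame, which makes it the natural modality for tracking ischemic
retinal vasculopathies in which capillary nonperfusion begins in the far
periphery and advances toward the posterior pole. The price of the wide
field is geometric distortion: the retina is (approximately) a sphere, the
image is a plane, and no projection preserves area. A nonperfusion burden
expressed as a fraction of *image pixels* therefore systematically misweights
the periphery relative to the same burden expressed as a fraction of
*retinal surface area*.

`retnpi` implements the area-true measurement chain:

1. a **spherical model eye** linking image pixels to retinal positions,
2. **per-pixel retinal areas** computed by spherical trigonometry,
3. a **geodesic zone partition** (posterior pole < 10 mm, mid periphery
   10–15 mm, far periphery > 15 mm from the fovea, measured along the
   retinal surface),
4. **guided segmentation** of perfused retina with manual positive/negative
   corrections and artifact exclusion,
5. the **nonperfusion index (NPI)**: nonperfused gradable area divided by
   total gradable area (TA), per zone and overall, and
6. a **mixed model for repeated measures (MMRM)** estimating piecewise
   annual rates of NPI change with random effects for patient and for eye
   within patient.

Because clinical UWF angiograms of this rare disease are not publicly
available, the package ships a synthetic generator for every stage —
ground-truth spherical geometry with closed-form NPIs, rendered
angiogram-like images, and longitudinal cohorts with known effect
structure — so the full chain is testable end to end.

## The model eye

The retina is modeled as a perfect sphere of radius $R$ (default 12 mm, a
Navarro-style posterior radius) with the fovea at the pole of the imaged
cap. A pixel at planar radius $\rho$ from the foveal pixel maps to
colatitude $\theta$ by the inverse projection; the default projection is
stereographic from the point antipodal to the fovea,
$\rho = 2R\tan(\theta/2)$, with an azimuthal-equidistant alternative
($\rho = R\theta$). Geodesic distance from the fovea is simply $R\theta$.

```{r}
m <- eye_model()
m
```

Two geometric defaults deserve comment:

* **Zone radii are geodesic.** The 10 mm and 15 mm circles are interpreted
  as distances along the retinal surface from the foveal center, which is
  what makes the zone areas projection-independent. Whether a vendor's
  free-hand calipers measure geodesic or projected-plane millimetres is not
  documented; geodesic is the declared choice here and the radii are
  configurable.
* **The field extent is calibrated, once.** The gradable field of a real
  UWF angiogram is not a published constant. The default
  `field_geodesic_radius = 19.14` mm is the unique value for which the
  closed-form spherical-cap areas put 32% of the imaged surface inside
  10 mm at $R = 12$ mm ($\theta_f = \arccos(1 - (1-\cos(10/12))/0.32)$);
  the resulting analytic split is 32.0/34.9/33.2 across
  posterior/mid/far. The calibration uses only the closed form — the
  per-pixel numerical summation is independent of it, which is what makes
  the reproduction of the zone split a real test of the area machinery.

### Per-pixel areas

`pixel_area_map()` maps the four corners of every pixel onto the sphere,
splits the footprint into two spherical triangles, and evaluates each
triangle's area from its spherical excess via L'Huilier's theorem. Corner
sharing makes areas exactly additive under grid refinement, and the summed
area converges to the closed-form cap area $2\pi R^2(1-\cos(\theta_f))$:

```{r}
am <- pixel_area_map(eye_model(image_size = c(256, 256)))
sum(am$area) / cap_area(am$model)
```

A consequence of stereographic projection worth stating explicitly: the
plane-to-sphere area ratio is $\sec^4(\theta/2)$, so a fixed image pixel
covers monotonically *less* retina with eccentricity. Uniform pixel
("voxel") counting therefore overweights the periphery. Both dialects are
exposed in `compute_npi(..., dialect = c("area", "voxel"))` because
voxel-based tools remain in clinical use; the area dialect is the default.

## Segmentation and corrections

Interactive level-set delineation is replaced by a transparent,
deterministic stand-in: intensities inside a closed `threshold_band` are
candidates, the connected components containing a seed are kept, and the
boundary is regularized by a morphological closing-then-opening (disc
radius `smoothing`). Intensities exactly at a band edge are included
(closed interval). The grader's operations are first-class:
`apply_correction()` implements positive/negative corrections of either
the perfusion label or the gradable area, and `exclude_artifacts()`
removes eyelash-like occlusions from all area sums. Manual gradings
produced outside the package enter as coded masks via `read_mask_png()`.

The segmentation parameters are exposed, not asserted as any particular
clinical tool's settings. On rendered two-level images with Gaussian noise
of $\sigma = 10$ against a 150-level contrast, the recovered masks agree
with the generating truth at a median Dice above 0.99 (the test suite
checks $\ge 0.95$ over 20 random geometries).

## The NPI and its transforms

For zone $z$ with gradable area $TA_z$ and nonperfused gradable area
$N_z$, $\mathrm{NPI}_z = N_z / TA_z$; the overall index
$\sum_z N_z / \sum_z TA_z$ is identically the TA-weighted mean of the zone
indices. Indices are proportions internally and percentages at I/O
boundaries. Because overall and posterior-pole indices can be exactly
zero, they are shrunk off the boundary before modeling with the affine map

$$T(\mathrm{NPI}) = \frac{\mathrm{NPI}\,(n-1) + 0.5}{n}, \qquad n = 20,$$

which is order-preserving and exactly invertible
(`transform_npi()` / `inverse_transform_npi()`); mid and far periphery are
left untransformed. Supporting clinical measures use their conventional
transforms: $\log_{10}$ of OCT central subfield thickness, and the
logMAR/Snellen correspondence $X = 20 \cdot 10^{\mathrm{logMAR}}$ for the
20-foot scale; counting-fingers acuity maps to logMAR 1.9 by convention and
is flagged as a non-numeric source.

## The longitudinal model

The repeated-measures model for response $y_{ijt}$ (patient $i$, eye $j$,
time $t$ in years) is

$$y_{ijt} = \beta_0 + \beta_1 \min(t, 1) + \beta_2 \max(t-1, 0)
  + b_i + c_{ij} + \varepsilon_{ijt},$$

with $b_i \sim N(0, \sigma_p^2)$, $c_{ij} \sim N(0, \sigma_e^2)$,
$\varepsilon \sim N(0, \sigma^2)$. The piecewise basis makes $\beta_1$ and
$\beta_2$ the year-1 and year-2 annual rates directly, and their equality
is tested with the Wald contrast $\beta_1 - \beta_2$ — the quantity of
interest when progression is rapid in the first year and plateaus in the
second. A categorical-time parameterization was considered and set aside:
with visits at 0/1/2 the two are equivalent for the rates themselves, and
the piecewise basis generalizes to irregular visit grids without changing
the reported quantities.

Estimation is REML via `lme4`; intervals and tests are Wald (normal).
Satterthwaite small-sample adjustment was deliberately omitted to keep the
inferential machinery transparent; the practical consequence, verified by
simulation in the test suite, is empirical 95% CI coverage of about 93% at
10 patients — inside the 90–99% acceptance band, and approaching nominal
as patients are added. When the mixed fit is degenerate (e.g. a noise-free
response), the fixed effects fall back to OLS on the same design matrix —
the exact limit of the mixed estimator as variance components vanish — and
the fallback is recorded in `fit_meta`.

Secondary analyses mirror the clinical questions: `symmetry_test()`
(exact Wilcoxon signed-rank on OD−OS pairs, exact for ≤ 25 non-zero pairs),
`normative_comparison()` (two-sided Mann-Whitney U with tie correction),
`covariate_and_subgroup_analysis()` (age/sex covariates and an age-45
subgroup split), and `dropout_contrast()` (completer status as a fixed
effect, returning the extra nonperfusion of patients who discontinued).
Both rank tests are cross-checked against exhaustive enumeration oracles
in the test suite for all sample sizes up to 8. Tests are two-sided at
$\alpha = 0.05$ with no multiplicity adjustment.

## The synthetic generator

`simulate_truth()` places a centripetal nonperfusion frontier at geodesic
radius $f$: retina beyond $f$ is nonperfused, optionally with angular
lobes reaching further in. Its per-zone NPI has a closed form from
spherical-cap band areas, e.g. for the mid zone with $f = 12$ mm:

```{r}
tr <- simulate_truth(eye_model(), frontier_radius = 12)
round(tr$analytic_npi, 4)
```

`render_uwf()` rasterizes the truth (perfused 200, nonperfused 50,
off-field 0, Gaussian noise, optional artifact wedges drawn dark at
intensity 10) and returns the rasterized truth mask alongside, so the
segmentation can be scored against it. The generator emulates the
*geometry and statistics* of UWF angiograms — not their appearance: there
are no vessel trees, leakage, laminar dye phases, or montage seams.
Passing tests therefore validate the measurement chain, not robustness to
photographic reality; masks graded from real angiograms enter the same
pipeline through `read_mask_png()`.

`simulate_cohort()` draws longitudinal NPI trajectories from exactly the
variance-component model the MMRM assumes. Defaults are the study
conditions: 10 patients × 2 eyes × visits {0, 1, 2} years, generating
year-1/year-2 rates 7.22 and −0.69 percentage points per year
(total-retina manual rates), and variance components
$\sigma_p = 8$, $\sigma_e = 3$, $\sigma = 2$ percentage points, chosen to
give CI widths of the order reported for cohorts of this size. The
baseline mean is 20% NPI: no baseline cohort mean is published (the mean
per-eye *relative* change cannot be inverted into a cohort mean, because a
mean of ratios is not a ratio of means), and 20% keeps the simulated
values far enough from the [0, 100] boundary that clipping touches under
~2% of values and cannot distort the piecewise slope structure. Values are
still clipped to [0, 100] with the count recorded and a warning beyond 5%.
`simulate_dropout()` adds severity-linked withdrawal:
$\Pr(\text{drop}) = \mathrm{logit}^{-1}(a + 0.08 \cdot \mathrm{NPI}_0)$,
with $a$ solved so a patient at the baseline mean withdraws with
probability 0.35 (about the discontinuation fraction seen in small trials
of this kind); dropped patients keep their pre-dropout visits. True
between-patient variability in this disease is unknown; these defaults
are stand-ins with the right order of magnitude, not estimates.

### Parameter recovery at the study's scale

`replicate_slope_recovery()` simulates replicate cohorts and refits the
MMRM on each. At the default design (10 patients), 200 replicates give a
Monte-Carlo SE of about 0.045 %/yr on each mean slope; the test suite
requires the mean estimates to sit within twice that of the generating
rates, and the empirical CI coverage and bias checks run at the same
scale. Problem sizes throughout (512×512 area maps, 96×96 segmentation
fixtures, 200-replicate recovery, 500-replicate coverage, 1000-replicate
type-I error) were chosen so each check has clear statistical resolution
while the whole suite runs in a few minutes on one core.

## Numerical choices and degenerate inputs

* Pixel membership in the field is decided by the pixel *center*; corner
  footprints at the rim may protrude, and the residual cap-area error
  (≪ 0.5% at 256², shrinking with resolution) is dominated by this rim
  staircase.
* L'Huilier's formula is evaluated with a guard that clamps tiny negative
  round-off under the square root for degenerate (near-collinear) corner
  triangles.
* A zone with zero gradable area yields an `NA` NPI and is excluded from
  the overall aggregate, with a warning; an all-artifact field yields an
  undefined overall NPI rather than 0/0.
* Eyes with a zero baseline are excluded (and counted) from percentage
  change from baseline.
* Constant series yield `NA` correlations with a warning rather than an
  error.
* All generators are pure functions of their arguments and a seed;
  rerunning any pipeline stage with the same inputs is byte-identical.

## Known limitations

* The spherical eye ignores aspheric retinal shape and the optics of real
  devices; the projection family is an idealization of how UWF vendors
  flatten the retina.
* The segmentation stand-in is intensity-based and deterministic; it does
  not reproduce any proprietary level-set implementation, only the
  guided-plus-corrections workflow around one.
* Wald inference without small-sample df correction is mildly
  anti-conservative at 10 patients (coverage ≈ 93% rather than 95%).
* The synthetic cohort generator matches the assumed covariance structure
  exactly — by construction it cannot probe misspecification of the
  random-effects structure itself.
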