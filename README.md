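# retnpi

Area-true quantification of retinal nonperfusion from ultra-widefield (UWF)
fluorescein angiograms, and mixed-model estimation of its annual
progression.

## What problem this solves

In ischemic retinal vasculopathies, capillary nonperfusion typically begins
in the far retinal periphery and advances toward the posterior pole. UWF
angiography can watch this happen across most of the retina at once — but a
UWF image is a planar projection of a sphere, so naive pixel counting
misweights the periphery. `retnpi` is for researchers who need the
**nonperfusion index (NPI)** — nonperfused gradable retinal area divided by
total gradable area (TA) — measured on the *retinal surface*, per retinal
zone and overall, and tracked longitudinally across visits and eyes.

The measurement chain:

* **Spherical model eye** (`eye_model()`): retina as a sphere of radius
  *R* (default 12 mm), image pixels mapped to colatitude/azimuth by
  inverse stereographic (or azimuthal-equidistant) projection; geodesic
  distance from the fovea is *Rθ*.
* **Per-pixel areas by spherical trigonometry** (`pixel_area_map()`):
  each pixel's corner footprint is evaluated on the sphere with
  L'Huilier's spherical-excess formula; the summed map converges to the
  closed-form cap area 2π*R*²(1 − cos *θ<sub>f</sub>*).
* **Geodesic zones** (`assign_zones()`): posterior pole (< 10 mm), mid
  periphery (10–15 mm), far periphery (> 15 mm); on the calibrated default
  field these cover 32% / 35% / 33% of the imaged surface.
* **Guided segmentation** (`levelset_segment()`) with the grading
  workflow: positive/negative corrections (`apply_correction()`) and
  artifact exclusion (`exclude_artifacts()`).
* **NPI and transforms** (`compute_npi()`, `transform_npi()`): per-zone
  and overall indices; zero-handling transform
  T(NPI) = (NPI·(n−1) + 0.5)/n with n = 20 for overall and posterior
  indices; logOCT and logMAR/Snellen helpers.
* **Longitudinal MMRM** (`fit_mmrm()`): piecewise annual rates via the
  fixed basis {min(t,1), max(t−1,0)} with random intercepts for patient
  and eye-within-patient (REML, `lme4`), plus inter-eye symmetry
  (`symmetry_test()`), normative comparison (`normative_comparison()`),
  covariate/subgroup refits, and a completer-vs-dropout contrast.
* **Synthetic generators** (`simulate_truth()`, `render_uwf()`,
  `simulate_cohort()`, `simulate_dropout()`): ground-truth spherical
  geometry with closed-form NPIs, rendered angiogram-like images, and
  longitudinal cohorts with known effect structure, so every stage is
  testable without clinical data.

## Worked example

Render a synthetic angiogram whose nonperfusion frontier sits at 12 mm
geodesic from the fovea, segment it, and quantify:

```r
library(retnpi)

m  <- eye_model()                                  # R = 12 mm, 512 x 512
tr <- simulate_truth(m, frontier_radius = 12)      # truth + analytic NPI
r  <- render_uwf(m, tr, noise_sd = 10, seed = 7)

npi <- quantify_image(r$image, m, seeds = matrix(c(256, 256), 1),
                      threshold_band = c(125, 255), smoothing = 2,
                      patient_id = "P01", eye = "OD", visit_time = 0)
print(npi, digits = 3)
#>   patient_id eye visit_time npi_posterior npi_mid npi_far npi_overall
#> 1        P01  OD          0             0    0.63       1       0.551
#>   t_npi_overall t_npi_posterior n_images
#> 1         0.549           0.025        1

round(tr$analytic_npi, 3)
#> posterior       mid       far   overall
#>     0.000     0.630     1.000     0.551
```

Everything inside 12 mm is perfused, so the posterior pole (which ends at
10 mm) reads NPI 0 and the far periphery (beyond 15 mm) reads 1; the mid
zone is partially lost (0.63), and the measured indices match the
closed-form cap-area values to three decimals. The transformed overall
index (0.549) is the modeling-scale version of 0.551.

Fit the progression model to a simulated two-year cohort (NPI in percent):

```r
co  <- simulate_cohort(cohort_spec(seed = 1))      # 10 patients, 20 eyes
fit <- fit_mmrm(co)
print(fit)
#> Piecewise MMRM fit (REML (lme4))
#>   60 observations, 10 patients, 20 eyes; response: response
#>   slope_year1:   7.61 %/yr  [6.41, 8.82]
#>   slope_year2:  -1.23 %/yr  [-2.43, -0.03]
#>   slope difference p = 7.67e-17
#>   SDs: patient 5.17, eye 3.27, residual 1.94
```

The generating rates were 7.22 and −0.69 %/yr; this single cohort's
estimates land inside their Wald CIs, and the sharp slope-difference
p-value reflects the year-1 progression followed by a year-2 plateau.

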