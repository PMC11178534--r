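#' Ground-truth nonperfusion geometry on the model eye
#'
#' Defines a synthetic nonperfusion pattern on the retinal sphere:
#' perfusion is lost beyond a centripetal frontier (geodesic distance
#' `frontier_radius` from the fovea), emulating the peripheral-to-central
#' advance of ischemia, optionally with additional angular lobes of
#' nonperfusion reaching further toward the pole. The analytic per-zone and
#' overall NPI of the region follow in closed form from spherical-cap
#' areas, providing an exact oracle for the imaging pipeline.
#'
#' @param model An [eye_model()].
#' @param frontier_radius Geodesic radius (mm) of preserved perfusion;
#'   nonperfused beyond it. Must lie in `[0, field_geodesic_radius]`.
#' @param lobes Optional data.frame of angular nonperfusion sectors with
#'   columns `azimuth_start`, `azimuth_end` (radians; sectors must not
#'   overlap) and `inner_radius` (mm, sector nonperfused beyond it).
#' @param seed Unused at present (lobes are deterministic); kept so all
#'   generators share a signature.
#' @return Object of class `truth_region` with the geometry and its
#'   `analytic_npi` (named vector: posterior, mid, far, overall).
#' @examples
#' tr <- simulate_truth(eye_model(), frontier_radius = 12)
#' tr$analytic_npi["mid"]  # (cos(1) - cos(1.25)) / (cos(10/12) - cos(1.25))
#' @export
simulate_truth <- function(model, frontier_radius, lobes = NULL, seed = NULL) {
  stopifnot(inherits(model, "eye_model"))
  if (frontier_radius < 0 || frontier_radius > model$field_geodesic_radius + 1e-9) {
    stop("domain error: frontier_radius must lie within the imaged field")
  }
  if (!is.null(lobes)) {
    lobes <- as.data.frame(lobes)
    stopifnot(all(c("azimuth_start", "azimuth_end", "inner_radius") %in% names(lobes)))
  }
  structure(
    list(model = model, frontier_radius = frontier_radius, lobes = lobes,
         analytic_npi = .analytic_npi(model, frontier_radius, lobes)),
    class = "truth_region")
}

# closed-form per-zone NPI of a frontier + sector-lobe region
.analytic_npi <- function(model, frontier, lobes, zone_radii = c(10, 15)) {
  field <- model$field_geodesic_radius
  bounds <- c(0, pmin(zone_radii, field), field)
  band <- function(a, b) if (b <= a) 0 else cap_band_area(model, a, b)
  npi <- numeric(3)
  ta <- numeric(3)
  for (z in 1:3) {
    a <- bounds[z]; b <- bounds[z + 1]
    ta[z] <- band(a, b)
    nonper <- band(max(a, frontier), max(b, frontier))  # annulus beyond the frontier
    if (!is.null(lobes) && nrow(lobes)) {
      for (k in seq_len(nrow(lobes))) {
        width <- (lobes$azimuth_end[k] - lobes$azimuth_start[k]) %% (2 * pi)
        lo <- max(a, lobes$inner_radius[k])
        hi <- min(b, frontier)  # beyond the frontier the lobe is already counted
        nonper <- nonper + (width / (2 * pi)) * band(lo, max(lo, hi))
      }
    }
    npi[z] <- if (ta[z] > 0) nonper / ta[z] else NA_real_
  }
  overall <- sum(npi * ta, na.rm = TRUE) / sum(ta[!is.na(npi)])
  stats::setNames(c(npi, overall), c(ZONE_NAMES, "overall"))
}

# rasterize the truth region on the pixel grid: TRUE where nonperfused
.rasterize_truth <- function(truth, coords = NULL) {
  model <- truth$model
  if (is.null(coords)) coords <- pixel_sphere_coords(model)
  nonper <- coords$geodesic > truth$frontier_radius
  if (!is.null(truth$lobes) && nrow(truth$lobes)) {
    for (k in seq_len(nrow(truth$lobes))) {
      a0 <- truth$lobes$azimuth_start[k] %% (2 * pi)
      a1 <- truth$lobes$azimuth_end[k] %% (2 * pi)
      in_sector <- if (a0 <= a1) coords$azimuth >= a0 & coords$azimuth <= a1
                   else coords$azimuth >= a0 | coords$azimuth <= a1
      nonper <- nonper | (in_sector & coords$geodesic > truth$lobes$inner_radius[k])
    }
  }
  nonper & coords$inside
}

#' Render a synthetic UWF-like angiogram from a truth region
#'
#' Rasterizes the ground-truth perfusion geometry onto the image grid and
#' renders a grayscale angiogram-like image: perfused retina at
#' `perfused_level`, nonperfused retina at `background_level`, off-field
#' pixels at 0, plus i.i.d. Gaussian noise. Optional artifact wedges
#' (eyelash-like occlusions entering from the field edge) are drawn at a
#' low occlusion intensity and returned as a mask for
#' [exclude_artifacts()]. Rendering is a pure function of its arguments
#' and `seed`; the rasterized truth mask is returned alongside the image
#' so segmentation can be validated against it.
#'
#' @param model An [eye_model()].
#' @param truth A [simulate_truth()] region.
#' @param perfused_level,background_level Intensities (0-255) of perfused
#'   and nonperfused retina; must differ. Defaults 200 and 50.
#' @param noise_sd Gaussian noise SD in intensity units. Default 10.
#' @param artifact_wedges Optional data.frame with columns `azimuth_start`,
#'   `azimuth_end` (radians) and `inner_radius` (mm): wedges occluded from
#'   `inner_radius` out to the field edge.
#' @param seed Integer seed for the noise; `NULL` leaves the RNG state
#'   alone.
#' @return Object of class `uwf_render`: `image` (matrix, clamped to
#'   0-255), `truth_state` (coded 0/1/2 ungradable/perfused/nonperfused),
#'   `artifact_mask` (logical), and the inputs.
#' @export
render_uwf <- function(model, truth, perfused_level = 200,
                       background_level = 50, noise_sd = 10,
                       artifact_wedges = NULL, seed = NULL) {
  stopifnot(inherits(model, "eye_model"), inherits(truth, "truth_region"))
  if (perfused_level == background_level) {
    stop("'perfused_level' and 'background_level' must differ")
  }
  coords <- pixel_sphere_coords(model)
  nonper <- .rasterize_truth(truth, coords)
  img <- matrix(0, model$image_size[1], model$image_size[2])
  img[coords$inside] <- ifelse(nonper[coords$inside], background_level, perfused_level)

  artifact_mask <- matrix(FALSE, nrow(img), ncol(img))
  if (!is.null(artifact_wedges) && nrow(artifact_wedges) > 0) {
    for (k in seq_len(nrow(artifact_wedges))) {
      a0 <- artifact_wedges$azimuth_start[k] %% (2 * pi)
      a1 <- artifact_wedges$azimuth_end[k] %% (2 * pi)
      in_sector <- if (a0 <= a1) coords$azimuth >= a0 & coords$azimuth <= a1
                   else coords$azimuth >= a0 | coords$azimuth <= a1
      artifact_mask <- artifact_mask |
        (in_sector & coords$geodesic > artifact_wedges$inner_radius[k] & coords$inside)
    }
    img[artifact_mask] <- 10  # dark occlusion, below any plausible threshold band
  }

  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img))
  }
  img <- pmin(pmax(img, 0), 255)

  truth_state <- matrix(STATE_UNGRADABLE, nrow(img), ncol(img))
  truth_state[coords$inside] <- ifelse(nonper[coords$inside],
                                       STATE_NONPERFUSED, STATE_PERFUSED)
  structure(list(image = img, truth_state = truth_state,
                 artifact_mask = artifact_mask, model = model, truth = truth,
                 seed = seed),
            class = "uwf_render")
}

#' Specification of a synthetic longitudinal cohort
#'
#' Bundles the generating parameters of the longitudinal NPI simulation.
#' Defaults reproduce the study conditions: 10 patients contributing both
#' eyes at visits 0, 1 and 2 years, piecewise-linear mean progression with
#' a year-1 rate of 7.22 and a year-2 rate of -0.69 percentage points per
#' year (total-retina manual rates), patient-intercept SD 8, eye-within-
#' patient SD 3 and residual SD 2 percentage points. The baseline mean of
#' 20% places the cohort well inside the [0, 100] range so that boundary
#' clipping stays negligible. Dropout is severity-linked: the per-patient
#' withdrawal probability is `plogis(dropout_intercept +
#' dropout_severity_coeff * baseline NPI)`, with the intercept solved so a
#' patient at the baseline mean withdraws with probability 0.35.
#'
#' @param n_patients Number of patients (2 eyes each). Default 10.
#' @param slope_year1,slope_year2 Annual rates of NPI change (%/yr) in
#'   years 1 and 2. Defaults 7.22 and -0.69.
#' @param baseline_mean Mean baseline NPI (%). Default 20.
#' @param sd_patient,sd_eye,sd_residual Standard deviations (percentage
#'   points) of the patient intercept, eye-within-patient intercept and
#'   residual. Defaults 8, 3, 2.
#' @param dropout_severity_coeff Logistic slope per NPI percentage point.
#'   Default 0.08.
#' @param dropout_intercept Logistic intercept; default solved so the
#'   withdrawal probability at `baseline_mean` is 0.35.
#' @param visits Visit times in years, sorted, starting at 0.
#'   Default `c(0, 1, 2)`.
#' @param seed Integer seed. Default 1.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 10, slope_year1 = 7.22,
                        slope_year2 = -0.69, baseline_mean = 20,
                        sd_patient = 8, sd_eye = 3, sd_residual = 2,
                        dropout_severity_coeff = 0.08,
                        dropout_intercept = NULL,
                        visits = c(0, 1, 2), seed = 1L) {
  stopifnot(n_patients >= 1, sd_patient >= 0, sd_eye >= 0, sd_residual >= 0)
  if (is.unsorted(visits) || visits[1] != 0) {
    stop("'visits' must be sorted ascending and start at 0")
  }
  if (is.null(dropout_intercept)) {
    dropout_intercept <- stats::qlogis(0.35) - dropout_severity_coeff * baseline_mean
  }
  structure(list(n_patients = n_patients, slope_year1 = slope_year1,
                 slope_year2 = slope_year2, baseline_mean = baseline_mean,
                 sd_patient = sd_patient, sd_eye = sd_eye,
                 sd_residual = sd_residual,
                 dropout_severity_coeff = dropout_severity_coeff,
                 dropout_intercept = dropout_intercept,
                 visits = visits, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a longitudinal NPI cohort
#'
#' Draws per-eye NPI trajectories from the variance-component model the
#' analysis assumes:
#' `NPI(i,j,t) = baseline_mean + b_i + c_ij + slope_year1*min(t,1) +
#' slope_year2*max(t-1,0) + eps`, with `b_i ~ N(0, sd_patient^2)` shared by
#' both eyes of patient `i`, `c_ij ~ N(0, sd_eye^2)` per eye, and i.i.d.
#' residuals. Values are clipped to [0, 100]; the number of clipped values
#' is recorded in the `"n_clipped"` attribute and a warning is raised if
#' clipping touches more than 5% of values (the generated effect structure
#' is then distorted). Patient age and sex are drawn to resemble the study
#' demographics (ages 36-57, ~73% female). The generator is a pure
#' function of `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A long cohort data.frame: `patient_id`, `eye`, `visit_time`,
#'   `response` (NPI %), `age`, `sex`, `completer` (all `TRUE`; see
#'   [simulate_dropout()]).
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(if (is.null(seed)) spec$seed else seed)
  np <- spec$n_patients
  b <- stats::rnorm(np, 0, spec$sd_patient)
  age <- round(stats::runif(np, 36, 57))
  sex <- ifelse(stats::runif(np) < 0.727, "F", "M")
  rows <- vector("list", np)
  for (i in seq_len(np)) {
    eye_rows <- lapply(c("OD", "OS"), function(e) {
      c_ij <- stats::rnorm(1, 0, spec$sd_eye)
      mu <- spec$baseline_mean + b[i] + c_ij +
        spec$slope_year1 * pmin(spec$visits, 1) +
        spec$slope_year2 * pmax(spec$visits - 1, 0)
      data.frame(patient_id = sprintf("P%02d", i), eye = e,
                 visit_time = spec$visits,
                 response = mu + stats::rnorm(length(spec$visits), 0, spec$sd_residual),
                 age = age[i], sex = sex[i], completer = TRUE,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, eye_rows)
  }
  out <- do.call(rbind, rows)
  n_clipped <- sum(out$response < 0 | out$response > 100)
  if (n_clipped / nrow(out) > 0.05) {
    warning(sprintf(
      "%d of %d simulated values clipped to [0, 100]; the generated effect structure is distorted",
      n_clipped, nrow(out)))
  }
  out$response <- pmin(pmax(out$response, 0), 100)
  rownames(out) <- NULL
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Impose severity-dependent dropout on a simulated cohort
#'
#' Each patient withdraws with probability
#' `plogis(dropout_intercept + dropout_severity_coeff * baseline NPI)`
#' (baseline NPI averaged over the patient's eyes), emulating the sicker-
#' patients-withdraw pattern of the study. A withdrawing patient's dropout
#' time is drawn uniformly among the post-baseline visits; visits at or
#' after it are removed (baseline is always retained) and `completer` is
#' set `FALSE`. Reproducible through `seed`.
#'
#' @param cohort A [simulate_cohort()] table.
#' @param spec The generating [cohort_spec()].
#' @param seed Optional seed override (default `spec$seed + 1`).
#' @return The reduced cohort data.frame with updated `completer` flags.
#' @export
simulate_dropout <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(if (is.null(seed)) spec$seed + 1L else seed)
  base <- cohort[cohort$visit_time == 0, , drop = FALSE]
  base_npi <- tapply(base$response, base$patient_id, mean)
  p_drop <- stats::plogis(spec$dropout_intercept +
                          spec$dropout_severity_coeff * base_npi)
  drops <- stats::runif(length(p_drop)) < p_drop
  if (all(drops)) stop("degenerate cohort: every patient dropped out")
  post <- setdiff(sort(unique(cohort$visit_time)), 0)
  keep <- rep(TRUE, nrow(cohort))
  for (pid in names(base_npi)[drops]) {
    t_drop <- if (length(post) == 1L) post else sample(post, 1L)
    keep <- keep & !(cohort$patient_id == pid & cohort$visit_time >= t_drop)
    cohort$completer[cohort$patient_id == pid] <- FALSE
  }
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate parameter-recovery simulation for the piecewise MMRM
#'
#' Simulates `n_replicates` independent cohorts from `spec` and fits the
#' piecewise mixed model to each, returning the estimated year-1 and
#' year-2 slopes per replicate. Used to validate that the estimation
#' pipeline recovers known generating rates; the mean estimate across
#' replicates should match the generating slopes within Monte-Carlo error.
#'
#' @param spec A [cohort_spec()]; its slopes are the generating truth.
#' @param n_replicates Number of simulated cohorts. Default 200.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param transform Passed to [fit_mmrm()].
#' @return Data.frame with one row per replicate: `replicate`,
#'   `slope_year1`, `slope_year2`.
#' @export
replicate_slope_recovery <- function(spec, n_replicates = 200, seed = 42L,
                                     transform = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  out <- vapply(seq_len(n_replicates), function(r) {
    cohort <- simulate_cohort(spec, seed = rep_seeds[r])
    fit <- fit_mmrm(cohort, transform = transform)
    fit$slopes$estimate
  }, numeric(2))
  data.frame(replicate = seq_len(n_replicates),
             slope_year1 = out[1, ], slope_year2 = out[2, ])
}
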