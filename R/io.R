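COHORT_COLUMNS <- c("patient_id", "eye", "visit_time", "response",
                    "age", "sex", "completer")

#' Read and validate a longitudinal cohort CSV
#'
#' The cohort exchange format is a long CSV with columns `patient_id`,
#' `eye` (`OD`/`OS`), `visit_time` (decimal years, 0 = baseline),
#' `response` (NPI in percent, or a transformed index), `age`, `sex`
#' (`M`/`F`) and `completer` (logical). Validation rejects unknown eye
#' codes (naming the accepted ones), duplicated `(patient, eye, visit)`
#' keys (listing the offending rows) and more than two eyes per patient.
#'
#' @param path CSV file path.
#' @return Validated cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort_csv
#' @param cohort A cohort data.frame to validate.
#' @export
validate_cohort <- function(cohort) {
  miss <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(miss)) {
    stop("cohort CSV missing columns: ", paste(miss, collapse = ", "))
  }
  bad_eye <- !cohort$eye %in% c("OD", "OS")
  if (any(bad_eye)) {
    stop(sprintf("validation error: unknown eye code(s) %s at row(s) %s; use 'OD' or 'OS'",
                 paste(unique(cohort$eye[bad_eye]), collapse = ", "),
                 paste(utils::head(which(bad_eye), 10), collapse = ", ")))
  }
  key <- paste(cohort$patient_id, cohort$eye, cohort$visit_time, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("validation error: duplicated (patient, eye, visit) key at row(s) ",
         paste(which(dup), collapse = ", "))
  }
  n_eyes <- tapply(cohort$eye, cohort$patient_id, function(e) length(unique(e)))
  if (any(n_eyes > 2)) {
    stop("validation error: more than 2 eyes for patient(s) ",
         paste(names(n_eyes)[n_eyes > 2], collapse = ", "))
  }
  cohort$visit_time <- as.numeric(cohort$visit_time)
  cohort$completer <- as.logical(cohort$completer)
  cohort
}

#' Write a cohort table as CSV
#'
#' Emits UTF-8 CSV with the fixed column order of the exchange format and
#' numeric columns rounded to 6 decimals, so identical tables produce
#' byte-identical files.
#'
#' @param cohort Cohort data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  extra <- setdiff(names(cohort), COHORT_COLUMNS)
  out <- cohort[, c(COHORT_COLUMNS, extra), drop = FALSE]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) round(x, 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()]:
#' the cohort source, the response to model, covariates, the quantification
#' dialect, and the seed. Round-trips losslessly through YAML; unknown keys
#' in a configuration file are rejected.
#'
#' @param cohort_csv Path to the cohort CSV (input).
#' @param out_dir Output directory.
#' @param response Response column to model. Default `"response"`.
#' @param covariates Character vector of covariate columns or `NULL`.
#' @param transform Model the zero-handling transformed response?
#'   Default `FALSE`.
#' @param dialect Image quantification dialect, `"area"` or `"voxel"`.
#' @param visits Expected visit schedule (years). Default `c(0, 1, 2)`.
#' @param seed Integer seed recorded in the run log. Default 1.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_csv, out_dir, response = "response",
                            covariates = NULL, transform = FALSE,
                            dialect = c("area", "voxel"),
                            visits = c(0, 1, 2), seed = 1L,
                            log_level = c("info", "quiet")) {
  structure(list(cohort_csv = cohort_csv, out_dir = out_dir,
                 response = response, covariates = covariates,
                 transform = isTRUE(transform), dialect = match.arg(dialect),
                 visits = visits, seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @param config A `pipeline_config` to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  y$covariates <- unlist(y$covariates)
  do.call(pipeline_config, y)
}

#' Run the longitudinal analysis pipeline
#'
#' Reads the configured cohort, fits the piecewise MMRM for the configured
#' response, and writes a result bundle to `out_dir`: `rates.csv` (the
#' zone-by-year rates table), `fit.json` (slopes, CIs, tests, variance
#' components) and `run_log.txt` (seed and configuration hash). The run is
#' a pure function of (inputs, config, seed): rerunning with the same
#' inputs produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The result bundle (list with `fit`, `rates`, `paths`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$cohort_csv)) {
    stop("stage 'read_cohort': missing input ", config$cohort_csv)
  }
  cohort <- read_cohort_csv(config$cohort_csv)
  fit <- tryCatch(
    fit_mmrm(cohort, response = config$response,
             covariates = config$covariates, transform = config$transform),
    error = function(e) stop("stage 'fit_mmrm': ", conditionMessage(e)))
  rates <- rates_table(stats::setNames(list(fit), config$response))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    rates = file.path(config$out_dir, "rates.csv"),
    fit = file.path(config$out_dir, "fit.json"),
    log = file.path(config$out_dir, "run_log.txt"))
  write_rates_table(rates, paths$rates)
  jsonlite::write_json(
    list(slopes = fit$slopes,
         slope_difference_p = fit$slope_difference_p,
         variance_components = as.list(fit$variance_components),
         covariate_effects = fit$covariate_effects,
         fit_meta = fit$fit_meta[c("method", "converged", "n_obs",
                                   "n_patients", "n_eyes", "response",
                                   "transform")]),
    paths$fit, auto_unbox = TRUE, digits = NA, null = "null")
  cfg_hash <- substr(paste(unlist(unclass(config)), collapse = "|"), 1, 1e6)
  writeLines(c(
    sprintf("seed: %d", config$seed),
    sprintf("config: %s", cfg_hash),
    sprintf("n_obs: %d", fit$fit_meta$n_obs)), paths$log)
  if (config$log_level == "info") {
    message("pipeline complete: ", config$out_dir)
  }
  invisible(list(fit = fit, rates = rates, paths = paths))
}

#' Rates table across responses
#'
#' Collects the year-1 and year-2 annual rates (with Wald CIs and the
#' slope-difference p-value) of several fitted models into one tidy table,
#' the layout used to report per-zone progression rates.
#'
#' @param fits Named list of [fit_mmrm()] objects, one per response/zone.
#' @return Data.frame with columns `response`, `slope_year1`, `ci1_lower`,
#'   `ci1_upper`, `slope_year2`, `ci2_lower`, `ci2_upper`,
#'   `slope_difference_p`.
#' @export
rates_table <- function(fits) {
  stopifnot(is.list(fits), length(names(fits)) == length(fits))
  rows <- lapply(names(fits), function(nm) {
    s <- fits[[nm]]$slopes
    data.frame(response = nm,
               slope_year1 = s$estimate[1], ci1_lower = s$ci_lower[1],
               ci1_upper = s$ci_upper[1],
               slope_year2 = s$estimate[2], ci2_lower = s$ci_lower[2],
               ci2_upper = s$ci_upper[2],
               slope_difference_p = fits[[nm]]$slope_difference_p,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @rdname rates_table
#' @param rates A rates table.
#' @param path Output CSV path.
#' @export
write_rates_table <- function(rates, path) {
  num <- vapply(rates, is.numeric, TRUE)
  rates[num] <- lapply(rates[num], function(x) round(x, 6))
  utils::write.csv(rates, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Quantify one graded image end to end
#'
#' Convenience composition of the imaging stages for a single eye and
#' visit: segmentation (unless a pre-graded mask is supplied), artifact
#' exclusion, zone partition, and NPI computation.
#'
#' @param image Grayscale intensity matrix (ignored when `mask` is given).
#' @param model An [eye_model()].
#' @param seeds Seed pixels for [levelset_segment()].
#' @param mask Optional pre-graded `perfusion_mask` (e.g. a manual
#'   grading read with [read_mask_png()]).
#' @param artifacts Optional artifact regions for [exclude_artifacts()].
#' @param dialect `"area"` or `"voxel"`.
#' @param ... Passed on to [levelset_segment()] and [compute_npi()]
#'   (e.g. `threshold_band`, `patient_id`, `eye`, `visit_time`).
#' @return An `npi_measurement` row.
#' @export
quantify_image <- function(image = NULL, model, seeds = NULL, mask = NULL,
                           artifacts = NULL, dialect = "area", ...) {
  dots <- list(...)
  seg_args <- dots[names(dots) %in% c("smoothing", "threshold_band")]
  npi_args <- dots[names(dots) %in% c("n_eyes", "patient_id", "eye", "visit_time")]
  if (is.null(mask)) {
    if (is.null(image) || is.null(seeds)) {
      stop("either a pre-graded 'mask' or an 'image' with 'seeds' is required")
    }
    mask <- do.call(levelset_segment,
                    c(list(image = image, model = model, seeds = seeds), seg_args))
  }
  if (!is.null(artifacts)) mask <- exclude_artifacts(mask, artifacts)
  am <- pixel_area_map(model)
  zones <- assign_zones(model, am, mask)
  do.call(compute_npi,
          c(list(mask = mask, zones = zones, area_map = am, dialect = dialect),
            npi_args))
}
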