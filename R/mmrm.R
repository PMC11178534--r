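#' Mixed model for repeated measures with piecewise annual slopes
#'
#' Fits the longitudinal progression model for eye-level repeated measures:
#' the fixed part is a piecewise-linear time basis `t1 = min(t, 1)`,
#' `t2 = max(t - 1, 0)` (separate year-1 and year-2 annual rates), optional
#' fixed covariates, and the random part has an intercept per patient
#' (within-patient longitudinal correlation) and an intercept per eye
#' within patient (inter-eye correlation). Estimation is by REML through
#' \pkg{lme4}; intervals and tests are Wald (normal). The difference of the
#' two annual slopes is tested with the Wald contrast `t1 - t2`.
#'
#' If the mixed fit fails to evaluate (e.g. a noise-free response leaves no
#' residual variance), the fixed effects are estimated by ordinary least
#' squares on the same design matrix, zero variance components are
#' reported, and `fit_meta$method` records the fallback. With variance
#' components truly at zero the two estimators coincide.
#'
#' An optional eye-by-time interaction (`eye:t1 + eye:t2`) can be added to
#' test whether progression differs between fellow eyes
#' (`interaction_p`, joint Wald chi-square).
#'
#' @param cohort Long data.frame with columns `patient_id`, `eye`
#'   (`"OD"`/`"OS"`), `visit_time` (years from baseline) and the response
#'   column; see [read_cohort_csv()].
#' @param response Name of the response column. Default `"response"`
#'   (NPI in percent, or a transformed index).
#' @param covariates Character vector of additional fixed-effect columns
#'   (e.g. `c("age", "sex")`), or `NULL`.
#' @param transform If `TRUE`, the response (a percent NPI) is converted to
#'   a proportion, passed through [transform_npi()], modeled, and the slope
#'   estimates are back-transformed to percent per year for reporting.
#' @param n_eyes Transform denominator when `transform = TRUE`.
#' @param eye_time_interaction If `TRUE`, adds the eye-by-time fixed
#'   interaction and reports its joint Wald p-value.
#' @param conf_level Confidence level for Wald intervals. Default 0.95.
#' @return An object of class `mmrm_fit` with elements `slopes` (data.frame
#'   of the year-1/year-2 estimates, SEs and CIs), `slope_difference_p`,
#'   `variance_components`, `covariate_effects`, `interaction_p`,
#'   `fit_meta`, and the underlying `model` object.
#' @export
fit_mmrm <- function(cohort, response = "response", covariates = NULL,
                     transform = FALSE, n_eyes = 20,
                     eye_time_interaction = FALSE, conf_level = 0.95) {
  d <- .prepare_mmrm_data(cohort, response, covariates)
  if (length(unique(d$patient_id)) < 2L) stop("design error: need at least 2 patients")
  if (length(unique(d$visit_time)) < 2L) stop("design error: need at least 2 visits")

  scale_back <- 1
  if (transform) {
    d$.y <- 100 * transform_npi(d$.y / 100, n_eyes)
    scale_back <- n_eyes / (n_eyes - 1)  # inverse of the affine slope shrinkage
  }

  fixed <- c("t1", "t2", covariates)
  if (eye_time_interaction) fixed <- c(fixed, "eye", "eye:t1", "eye:t2")
  fmla <- stats::reformulate(c(fixed, "(1 | patient_id)", "(1 | patient_id:eye)"),
                             response = ".y")
  method <- "REML (lme4)"
  convergence <- TRUE
  fit <- tryCatch({
    f <- suppressMessages(lme4::lmer(fmla, data = d, REML = TRUE,
                                     control = lme4::lmerControl(check.conv.singular = "ignore")))
    V <- suppressWarnings(as.matrix(stats::vcov(f)))
    if (any(!is.finite(V))) stop("degenerate covariance")
    f
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    method <- "OLS fallback (degenerate mixed fit)"
    convergence <- FALSE
    fit <- stats::lm(stats::reformulate(fixed, response = ".y"), data = d)
    beta <- stats::coef(fit)
    V <- suppressWarnings(stats::vcov(fit))
    vc <- c(patient = 0, eye_within_patient = 0,
            residual = suppressWarnings(stats::sigma(fit)))
  } else {
    beta <- lme4::fixef(fit)
    V <- suppressWarnings(as.matrix(stats::vcov(fit)))
    vcd <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(patient = vcd$sdcor[vcd$grp == "patient_id"],
            eye_within_patient = vcd$sdcor[vcd$grp == "patient_id:eye"],
            residual = vcd$sdcor[vcd$grp == "Residual"])
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  est <- beta[c("t1", "t2")] * scale_back
  se <- sqrt(diag(V)[c("t1", "t2")]) * scale_back
  slopes <- data.frame(
    term = c("slope_year1", "slope_year2"),
    estimate = unname(est), se = unname(se),
    ci_lower = unname(est - z * se), ci_upper = unname(est + z * se),
    p = unname(2 * stats::pnorm(-abs(est / se))),
    row.names = NULL)

  cvec <- stats::setNames(numeric(length(beta)), names(beta))
  cvec["t1"] <- 1; cvec["t2"] <- -1
  dse <- sqrt(drop(t(cvec) %*% V %*% cvec))
  slope_difference_p <- 2 * stats::pnorm(-abs(drop(cvec %*% beta) / dse))

  covariate_effects <- NULL
  if (!is.null(covariates)) {
    idx <- setdiff(names(beta), c("(Intercept)", "t1", "t2"))
    idx <- idx[!grepl(":", idx)]
    if (length(idx)) {
      ce <- beta[idx]; cse <- sqrt(diag(V)[idx])
      covariate_effects <- data.frame(
        term = idx, estimate = unname(ce), se = unname(cse),
        ci_lower = unname(ce - z * cse), ci_upper = unname(ce + z * cse),
        p = unname(2 * stats::pnorm(-abs(ce / cse))), row.names = NULL)
    }
  }

  interaction_p <- NA_real_
  if (eye_time_interaction) {
    it <- grep(":t[12]$|^t[12]:", names(beta), value = TRUE)
    if (length(it)) {
      bi <- beta[it]; Vi <- V[it, it, drop = FALSE]
      stat <- drop(t(bi) %*% solve(Vi) %*% bi)
      interaction_p <- stats::pchisq(stat, df = length(it), lower.tail = FALSE)
    }
  }

  structure(
    list(slopes = slopes,
         slope_difference_p = slope_difference_p,
         variance_components = vc,
         covariate_effects = covariate_effects,
         interaction_p = interaction_p,
         fit_meta = list(method = method, converged = convergence,
                         n_obs = nrow(d),
                         n_patients = length(unique(d$patient_id)),
                         n_eyes = length(unique(paste(d$patient_id, d$eye))),
                         response = response, transform = transform),
         model = fit),
    class = "mmrm_fit")
}

.prepare_mmrm_data <- function(cohort, response, covariates = NULL) {
  need <- c("patient_id", "eye", "visit_time", response, covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  d <- as.data.frame(cohort)
  d$.y <- d[[response]]
  d <- d[!is.na(d$.y), , drop = FALSE]
  d$patient_id <- factor(d$patient_id)
  d$eye <- factor(d$eye)
  d$t1 <- pmin(d$visit_time, 1)
  d$t2 <- pmax(d$visit_time - 1, 0)
  d
}

#' @export
print.mmrm_fit <- function(x, ...) {
  cat("Piecewise MMRM fit (", x$fit_meta$method, ")\n", sep = "")
  cat(sprintf("  %d observations, %d patients, %d eyes; response: %s\n",
              x$fit_meta$n_obs, x$fit_meta$n_patients, x$fit_meta$n_eyes,
              x$fit_meta$response))
  s <- x$slopes
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %6.2f %%/yr  [%.2f, %.2f]\n",
                s$term[i], s$estimate[i], s$ci_lower[i], s$ci_upper[i]))
  }
  cat(sprintf("  slope difference p = %.4g\n", x$slope_difference_p))
  cat(sprintf("  SDs: patient %.2f, eye %.2f, residual %.2f\n",
              x$variance_components["patient"],
              x$variance_components["eye_within_patient"],
              x$variance_components["residual"]))
  invisible(x)
}

#' Inter-eye symmetry test at one visit
#'
#' Wilcoxon matched-pairs signed-rank test of the OD-OS difference across
#' patients at a given visit (exact distribution for 25 or fewer non-zero
#' pairs, normal approximation above). If every difference is zero the test
#' is degenerate and `p = 1` is returned with a flag.
#'
#' @param cohort Long cohort data.frame (see [fit_mmrm()]).
#' @param visit Visit time (years) at which to compare fellow eyes.
#' @param response Response column name. Default `"response"`.
#' @return List with `p`, `statistic`, `n_pairs`, `method`, and
#'   `all_zero` flag.
#' @export
symmetry_test <- function(cohort, visit, response = "response") {
  d <- cohort[cohort$visit_time == visit, , drop = FALSE]
  od <- d[d$eye == "OD", c("patient_id", response)]
  os <- d[d$eye == "OS", c("patient_id", response)]
  m <- merge(od, os, by = "patient_id", suffixes = c("_od", "_os"))
  if (nrow(m) < 1L) stop("no patients with both eyes at this visit")
  x <- m[[paste0(response, "_od")]]
  y <- m[[paste0(response, "_os")]]
  diffs <- x - y
  if (all(diffs == 0)) {
    return(list(p = 1, statistic = 0, n_pairs = nrow(m),
                method = "degenerate (all differences zero)", all_zero = TRUE))
  }
  exact <- sum(diffs != 0) <= 25
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = exact,
                                            correct = !exact))
  list(p = wt$p.value, statistic = unname(wt$statistic), n_pairs = nrow(m),
       method = wt$method, all_zero = FALSE)
}

#' Comparison against a normative database
#'
#' Two-sided Mann-Whitney U test (with tie correction) of a patient sample
#' against normative reference values, e.g. central subfield thickness
#' against a normative OCT database.
#'
#' @param values Numeric sample (patients).
#' @param normative Numeric reference sample.
#' @return List with `p`, `U` (the Mann-Whitney statistic for `values`),
#'   and `method`.
#' @export
normative_comparison <- function(values, normative) {
  stopifnot(length(values) > 0, length(normative) > 0)
  wt <- suppressWarnings(stats::wilcox.test(values, normative, exact = NULL))
  list(p = wt$p.value, U = unname(wt$statistic), method = wt$method)
}

#' Covariate and age-subgroup analysis of progression
#'
#' Refits the piecewise MMRM adding age and (separately) sex as fixed
#' covariates, and refits within age subgroups (eyes of patients younger
#' vs older than the split age). Reports whether adding each covariate
#' changes the significance (at `alpha`) of the year-1 time effect, and the
#' subgroup slope estimates.
#'
#' @param cohort Long cohort data.frame with `age` and `sex` columns.
#' @param response Response column name. Default `"response"`.
#' @param age_split Age (years) dividing the subgroups. Default 45.
#' @param alpha Significance threshold. Default 0.05.
#' @return List with `base`, `with_age`, `with_sex` (each an `mmrm_fit`),
#'   `subgroups` (named list of `mmrm_fit` or `NULL` for an empty
#'   subgroup), and `covariates_change_significance` (named logical).
#' @export
covariate_and_subgroup_analysis <- function(cohort, response = "response",
                                            age_split = 45, alpha = 0.05) {
  stopifnot(all(c("age", "sex") %in% names(cohort)))
  base <- fit_mmrm(cohort, response)
  with_age <- fit_mmrm(cohort, response, covariates = "age")
  with_sex <- fit_mmrm(cohort, response, covariates = "sex")
  sig <- function(f) f$slopes$p[f$slopes$term == "slope_year1"] < alpha
  changes <- c(age = sig(with_age) != sig(base), sex = sig(with_sex) != sig(base))

  fit_sub <- function(d, label) {
    if (!nrow(d) || length(unique(d$patient_id)) < 2L) {
      warning("subgroup '", label, "' skipped: too few patients")
      return(NULL)
    }
    fit_mmrm(d, response)
  }
  subgroups <- list(
    younger = fit_sub(cohort[cohort$age < age_split, , drop = FALSE], "younger"),
    older = fit_sub(cohort[cohort$age >= age_split, , drop = FALSE], "older"))
  list(base = base, with_age = with_age, with_sex = with_sex,
       subgroups = subgroups, covariates_change_significance = changes)
}

#' Completer-versus-dropout nonperfusion contrast
#'
#' Adds completer status as a fixed effect to the piecewise MMRM and
#' reports the estimated extra nonperfusion of patients who discontinued
#' relative to those who completed, with its standard error and Wald
#' p-value. Several response columns (e.g. overall and per-zone NPIs) can
#' be contrasted at once.
#'
#' @param cohort Long cohort data.frame with a logical `completer` column.
#' @param responses Character vector of response column names.
#' @return Data.frame with one row per response: `estimate` (dropout minus
#'   completer, response units), `se`, `ci_lower`, `ci_upper`, `p`.
#' @export
dropout_contrast <- function(cohort, responses = "response") {
  if (!"completer" %in% names(cohort)) stop("cohort has no 'completer' column")
  if (length(unique(cohort$completer)) < 2L) {
    stop("design error: both completer strata must be present")
  }
  d <- as.data.frame(cohort)
  d$dropout <- factor(ifelse(d$completer, "completer", "dropout"),
                      levels = c("completer", "dropout"))
  out <- lapply(responses, function(resp) {
    fit <- fit_mmrm(d, resp, covariates = "dropout")
    ce <- fit$covariate_effects
    row <- ce[ce$term == "dropoutdropout", , drop = FALSE]
    data.frame(response = resp, estimate = row$estimate, se = row$se,
               ci_lower = row$ci_lower, ci_upper = row$ci_upper, p = row$p,
               row.names = NULL)
  })
  do.call(rbind, out)
}
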