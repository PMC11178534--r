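test_that("noise-free cohorts are interpolated exactly", {
  spec <- cohort_spec(slope_year1 = 8, slope_year2 = -1,
                      sd_patient = 0, sd_eye = 0, sd_residual = 0)
  fit <- fit_mmrm(simulate_cohort(spec))
  expect_equal(fit$slopes$estimate, c(8, -1), tolerance = 1e-9)
  expect_equal(unname(fit$variance_components), c(0, 0, 0), tolerance = 1e-9)
})

test_that("mixed-model slopes equal OLS when variance components vanish", {
  spec <- cohort_spec(sd_patient = 0, sd_eye = 0, sd_residual = 2, seed = 21)
  cohort <- simulate_cohort(spec)
  fit <- suppressWarnings(fit_mmrm(cohort))
  ols <- ols_piecewise_slopes(cohort)
  expect_equal(fit$slopes$estimate, ols, tolerance = 1e-6)
})

test_that("fit_mmrm validates its design and reports Wald inference", {
  spec <- cohort_spec(seed = 3)
  cohort <- simulate_cohort(spec)
  fit <- fit_mmrm(cohort)
  s <- fit$slopes
  expect_true(all(s$ci_lower <= s$estimate & s$estimate <= s$ci_upper))
  expect_true(all(fit$variance_components >= 0))
  expect_true(fit$slope_difference_p > 0 && fit$slope_difference_p <= 1)

  expect_error(fit_mmrm(cohort[cohort$patient_id == "P01", ]), "2 patients")
  expect_error(fit_mmrm(cohort[cohort$visit_time == 0, ]), "2 visits")
  expect_error(fit_mmrm(cohort, response = "nope"), "missing columns")
})

test_that("slope-difference p-value is invariant to affine rescaling of the response", {
  cohort <- simulate_cohort(cohort_spec(seed = 8))
  f1 <- fit_mmrm(cohort)
  cohort$response <- 3.7 * cohort$response + 11
  f2 <- fit_mmrm(cohort)
  expect_equal(f2$slope_difference_p, f1$slope_difference_p, tolerance = 1e-6)
  expect_equal(f2$slopes$estimate, 3.7 * f1$slopes$estimate, tolerance = 1e-6)
})

test_that("transformed-response modeling back-transforms slopes to the raw scale", {
  # the zero-handling transform is affine, so back-transformed slopes must
  # match the raw-scale fit to numerical precision
  cohort <- simulate_cohort(cohort_spec(seed = 14))
  raw <- fit_mmrm(cohort)
  tr <- fit_mmrm(cohort, transform = TRUE)
  expect_equal(tr$slopes$estimate, raw$slopes$estimate, tolerance = 1e-6)
})

test_that("symmetry test matches exhaustive sign enumeration and handles degeneracy", {
  mk <- function(od, os) {
    n <- length(od)
    data.frame(patient_id = rep(sprintf("P%d", 1:n), 2),
               eye = rep(c("OD", "OS"), each = n),
               visit_time = 0, response = c(od, os))
  }
  # identical eyes: degenerate, p = 1
  st <- symmetry_test(mk(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(st$p, 1)
  expect_true(st$all_zero)

  # all-positive differences {1,2,3,4}: one-sided exact p = 1/16
  expect_equal(enum_signed_rank_p(c(1, 2, 3, 4), "greater"), 1 / 16)
  st2 <- symmetry_test(mk(c(2, 4, 6, 8), c(1, 2, 3, 4)), 0)
  expect_equal(st2$p, enum_signed_rank_p(c(1, 2, 3, 4), "two.sided"))

  # exact p equals enumeration for all tie-free paired datasets up to n = 8
  set.seed(31)
  for (n in 4:8) {
    d <- sample(1:20, n) * sample(c(-1, 1), n, replace = TRUE)  # tie-free |d|
    od <- cumsum(abs(d)) + d
    os <- cumsum(abs(d))
    expect_equal(symmetry_test(mk(od, os), 0)$p,
                 enum_signed_rank_p(d, "two.sided"),
                 tolerance = 1e-12, label = paste("n =", n))
  }
})

test_that("Mann-Whitney comparison matches exhaustive rank-split enumeration", {
  # {1,2} vs {3,4}: U = 0, exact two-sided p = 1/3
  nc <- normative_comparison(c(1, 2), c(3, 4))
  expect_equal(unname(nc$U), 0)
  expect_equal(nc$p, 1 / 3)
  expect_equal(enum_mann_whitney_p(c(1, 2), c(3, 4)), 1 / 3)

  # sample against itself: U = n^2/2, p = 1
  x <- c(250, 260, 270, 280)
  self <- normative_comparison(x, x)
  expect_equal(unname(self$U), length(x)^2 / 2)
  expect_equal(self$p, 1)

  # enumeration agreement for tie-free samples up to total size 8
  set.seed(32)
  for (i in 1:5) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    v <- sample(1:50, nx + ny)
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(normative_comparison(x, y)$p, enum_mann_whitney_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("covariate and subgroup analysis: null covariates and symmetric relabeling", {
  spec <- cohort_spec(n_patients = 12, seed = 41)
  cohort <- simulate_cohort(spec)
  out <- suppressWarnings(covariate_and_subgroup_analysis(cohort))
  expect_false(any(out$covariates_change_significance))

  # duplicating the cohort with sex relabeled forces a zero sex effect
  dup <- cohort
  dup$patient_id <- paste0(dup$patient_id, "x")
  dup$sex <- ifelse(cohort$sex == "F", "M", "F")
  both <- rbind(cohort, dup)
  fit <- fit_mmrm(both, covariates = "sex")
  expect_equal(fit$covariate_effects$estimate, 0, tolerance = 1e-6)

  # subgroup fits on a common-slope cohort recover the common truth
  for (sub in out$subgroups) {
    if (is.null(sub)) next
    s <- sub$slopes
    expect_true(s$ci_lower[1] <= 7.22 && 7.22 <= s$ci_upper[1])
  }
})

test_that("age effect is null-covered when the generator has no age effect", {
  # Wald intervals are asymptotic in the number of patients (age is a
  # between-patient covariate), so the null-coverage check runs at 40
  # patients, where the normal approximation is adequate
  set.seed(43)
  seeds <- sample.int(2^31 - 1, 100)
  covered <- vapply(seeds, function(s) {
    cohort <- suppressWarnings(simulate_cohort(cohort_spec(n_patients = 40), seed = s))
    fit <- suppressWarnings(fit_mmrm(cohort, covariates = "age"))
    ce <- fit$covariate_effects
    ce$ci_lower[ce$term == "age"] <= 0 && 0 <= ce$ci_upper[ce$term == "age"]
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("dropout contrast recovers a known between-stratum offset", {
  set.seed(44)
  mk_stratum <- function(prefix, offset, completer, n = 8, seed) {
    co <- simulate_cohort(cohort_spec(n_patients = n, seed = seed))
    co$patient_id <- paste0(prefix, co$patient_id)
    co$response <- pmin(co$response + offset, 100)
    co$completer <- completer
    co
  }
  cohort <- rbind(mk_stratum("c", 0, TRUE, seed = 101),
                  mk_stratum("d", 20, FALSE, seed = 102))
  dc <- dropout_contrast(cohort)
  expect_lt(abs(dc$estimate - 20), 3 * dc$se + 2)

  # identical strata: contrast compatible with zero
  null_cohort <- rbind(mk_stratum("c", 0, TRUE, seed = 103),
                       mk_stratum("d", 0, FALSE, seed = 104))
  dc0 <- dropout_contrast(null_cohort)
  expect_lt(abs(dc0$estimate / dc0$se), 3)

  expect_error(dropout_contrast(cohort[cohort$completer, ]), "strata")
})

test_that("eye-by-time interaction is testable and near-null for exchangeable eyes", {
  cohort <- simulate_cohort(cohort_spec(n_patients = 15, seed = 51))
  fit <- fit_mmrm(cohort, eye_time_interaction = TRUE)
  expect_true(fit$interaction_p > 0 && fit$interaction_p <= 1)
})
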