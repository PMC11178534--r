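test_that("zone labels follow the geodesic thresholds", {
  m <- eye_model(image_size = c(256, 256))
  am <- pixel_area_map(m)
  zp <- assign_zones(m, am)
  pick <- function(d_mm) {
    px <- round(sphere_to_image(m, data.frame(colatitude = d_mm / 12, azimuth = 0.7)))
    zp$zone[px[1], px[2]]
  }
  expect_equal(pick(5), 1L)    # posterior
  expect_equal(pick(12), 2L)   # mid
  expect_equal(pick(17), 3L)   # far
  expect_equal(zp$zone[1, 1], 0L)  # image corner is off the imaged disc

  # partition additivity
  expect_equal(sum(zp$ta_area), zp$ta_area_total)
  expect_equal(sum(zp$ta_voxel), zp$ta_voxel_total)
  expect_equal(zp$ta_area_total, sum(am$area), tolerance = 1e-12)
})

test_that("default model reproduces the 32/35/33 zone split", {
  fr <- zone_area_fractions(eye_model())
  expect_equal(unname(round(100 * fr)), c(32, 35, 33))
})

test_that("NPI arithmetic: boundary masks, toy counts, weighted-mean identity", {
  m <- small_model()
  am <- pixel_area_map(m)

  all_perf <- perfusion_mask(matrix(1L, 96, 96), m)
  zp <- assign_zones(m, am, all_perf)
  npi0 <- compute_npi(all_perf, zp, am)
  expect_equal(npi0$npi_overall, 0)
  expect_equal(c(npi0$npi_posterior, npi0$npi_mid, npi0$npi_far), c(0, 0, 0))

  all_non <- perfusion_mask(matrix(2L, 96, 96), m)
  zp2 <- assign_zones(m, am, all_non)
  npi1 <- compute_npi(all_non, zp2, am)
  expect_equal(npi1$npi_overall, 1)
  expect_equal(c(npi1$npi_posterior, npi1$npi_mid, npi1$npi_far), c(1, 1, 1))

  # toy voxel-dialect count: 37 of 100 posterior pixels nonperfused -> 0.37.
  # a tiny all-posterior patch: use a mask that grades only a 10x10 block
  # near the fovea and marks 37 of those pixels nonperfused
  st <- matrix(0L, 96, 96)
  st[44:53, 44:53] <- 1L
  st[44:53, 44:53][seq_len(37)] <- 2L
  toy <- perfusion_mask(st, m)
  zp3 <- assign_zones(m, am, toy)
  expect_warning(npi3 <- compute_npi(toy, zp3, am, dialect = "voxel"), "undefined")
  expect_equal(npi3$npi_overall, 0.37)
  expect_equal(npi3$npi_posterior, 0.37)

  # overall NPI is the TA-weighted mean of zone NPIs (both dialects)
  set.seed(5)
  st <- matrix(sample(1:2, 96 * 96, TRUE), 96, 96)
  mk <- perfusion_mask(st, m)
  zp4 <- assign_zones(m, am, mk)
  for (dialect in c("area", "voxel")) {
    x <- compute_npi(mk, zp4, am, dialect = dialect)
    ta <- if (dialect == "area") zp4$ta_area else zp4$ta_voxel
    w <- ta / sum(ta)
    expect_equal(x$npi_overall,
                 sum(w * c(x$npi_posterior, x$npi_mid, x$npi_far)),
                 tolerance = 1e-9)
  }
})

test_that("per-zone nonperfused areas sum to the total nonperfused area", {
  m <- small_model()
  am <- pixel_area_map(m)
  set.seed(6)
  st <- matrix(sample(0:2, 96 * 96, TRUE, prob = c(0.1, 0.5, 0.4)), 96, 96)
  mk <- perfusion_mask(st, m)
  zp <- assign_zones(m, am, mk)
  npi <- compute_npi(mk, zp, am)
  per_zone <- c(npi$npi_posterior, npi$npi_mid, npi$npi_far) * zp$ta_area
  total <- npi$npi_overall * zp$ta_area_total
  expect_equal(sum(per_zone), total, tolerance = 1e-9)
  expect_equal(total, sum(am$area[mk$state == 2L & zp$gradable]), tolerance = 1e-9)
})

test_that("repeated measurements of a visit average arithmetically", {
  base <- data.frame(patient_id = "P01", eye = "OD", visit_time = 0,
                     npi_posterior = 0.1, npi_mid = 0.2, npi_far = 0.3,
                     npi_overall = 0.2,
                     t_npi_overall = transform_npi(0.2),
                     t_npi_posterior = transform_npi(0.1), n_images = 1L)
  class(base) <- c("npi_measurement", "data.frame")
  m2 <- base; m2$npi_overall <- 0.2
  m3 <- base; m3$npi_overall <- 0.2
  same <- aggregate_visit(list(base, m2, m3))
  expect_equal(same$npi_overall, 0.2)
  expect_equal(same$n_images, 3L)

  v <- list(base, transform(base, npi_overall = 0.2), transform(base, npi_overall = 0.3))
  v[[1]]$npi_overall <- 0.1
  avg <- aggregate_visit(v)
  expect_equal(avg$npi_overall, 0.2)

  single <- aggregate_visit(list(base))
  expect_equal(single$npi_overall, base$npi_overall)
  expect_equal(single$n_images, 1L)

  other <- base; other$eye <- "OS"
  expect_error(aggregate_visit(list(base, other)), "mix")
})

test_that("zero-handling transform matches its closed form and inverts exactly", {
  expect_equal(transform_npi(0), 0.025)
  expect_equal(transform_npi(0.5), 0.5)
  expect_equal(transform_npi(1), 0.975)
  expect_error(transform_npi(1.2), "domain")
  expect_error(transform_npi(-0.1), "domain")

  p <- seq(0, 1, length.out = 101)
  expect_lt(max(abs(inverse_transform_npi(transform_npi(p)) - p)), 1e-12)
  expect_true(all(diff(transform_npi(p)) > 0))  # order-preserving
  # other n
  expect_equal(transform_npi(0, n_eyes = 10), 0.05)
  expect_lt(max(abs(inverse_transform_npi(transform_npi(p, 7), 7) - p)), 1e-12)
})

test_that("percentage change from baseline averages per-eye relative changes", {
  tbl <- data.frame(
    patient_id = rep(c("A", "A", "B"), each = 3),
    eye = rep(c("OD", "OS", "OD"), each = 3),
    visit_time = rep(0:2, 3),
    npi_overall = c(0.2, 0.2, 0.2,   0.1, 0.2, 0.2,   0.1, 0.15, 0.17))
  out <- pct_change_from_baseline(tbl)
  a_od <- out$per_eye[out$per_eye$patient_id == "A" & out$per_eye$eye == "OD", ]
  expect_equal(a_od$pct_change, c(0, 0))
  a_os <- out$per_eye[out$per_eye$patient_id == "A" & out$per_eye$eye == "OS", ]
  expect_equal(a_os$pct_change[a_os$visit_time == 1], 100)
  expect_equal(out$mean_by_visit$pct_change[out$mean_by_visit$visit_time == 1],
               mean(c(0, 100, 50)))

  # zero baseline: excluded and counted
  tbl$npi_overall[7] <- 0
  expect_message(out2 <- pct_change_from_baseline(tbl), "excluded")
  expect_equal(out2$n_undefined, 1L)
  expect_equal(sort(unique(out2$per_eye$eye[out2$per_eye$patient_id == "B"])),
               character(0))
})

test_that("functional transforms match their worked values", {
  expect_equal(round(log_oct(270), 2), 2.43)
  expect_equal(log_oct(100), 2)
  expect_error(log_oct(0), "domain")
  expect_error(log_oct(-5), "domain")

  expect_equal(snellen_from_logmar(0), 20)
  expect_equal(snellen_from_logmar(0.176), 30, tolerance = 0.01)
  expect_equal(logmar_from_snellen(20), 0)
  expect_equal(logmar_from_snellen(snellen_from_logmar(0.3)), 0.3)
  expect_equal(as.numeric(logmar_count_fingers()), 1.9)
})

test_that("reliability and zone correlations follow the rank/product-moment formulas", {
  mk_tbl <- function(vals1, vals3) {
    n <- length(vals1)
    rbind(
      data.frame(patient_id = sprintf("P%d", 1:n), eye = "OD", visit_time = 0,
                 image_index = 1L, npi_posterior = vals1, npi_mid = vals1,
                 npi_far = vals1, npi_overall = vals1),
      data.frame(patient_id = sprintf("P%d", 1:n), eye = "OD", visit_time = 0,
                 image_index = 3L, npi_posterior = vals3, npi_mid = vals3,
                 npi_far = vals3, npi_overall = vals3))
  }
  # identical paired series -> r = 1; negated -> r = -1
  v <- c(0.1, 0.25, 0.4, 0.6)
  expect_equal(unname(reliability_and_zone_correlations(mk_tbl(v, v))$pearson_first_third),
               rep(1, 4))
  expect_equal(unname(reliability_and_zone_correlations(mk_tbl(v, -v))$pearson_first_third),
               rep(-1, 4))

  # Spearman rho for ranks (1,2,3,4) vs (1,2,4,3) is 1 - 6*2/(4*15) = 0.8
  tbl <- data.frame(patient_id = sprintf("P%d", 1:4), eye = "OD", visit_time = 0,
                    image_index = 1L,
                    npi_posterior = c(0.1, 0.2, 0.4, 0.3),  # ranks 1,2,4,3
                    npi_mid = c(0.1, 0.2, 0.3, 0.4),
                    npi_far = c(0.1, 0.2, 0.3, 0.4),
                    npi_overall = c(0.1, 0.2, 0.3, 0.4))    # ranks 1,2,3,4
  tbl3 <- tbl; tbl3$image_index <- 3L
  rr <- reliability_and_zone_correlations(rbind(tbl, tbl3))
  expect_equal(unname(rr$spearman_zone_overall["npi_posterior"]),
               1 - 6 * sum((rank(tbl$npi_posterior) - rank(tbl$npi_overall))^2) / (4 * 15))
  expect_equal(unname(rr$spearman_zone_overall["npi_posterior"]), 0.8)

  # constant series -> flagged undefined
  const <- mk_tbl(rep(0.2, 4), v)
  expect_warning(cc <- reliability_and_zone_correlations(const), "constant")
  expect_true(all(is.na(cc$pearson_first_third)))
})
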