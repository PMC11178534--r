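ZONE_NAMES <- c("posterior", "mid", "far")

#' Partition the imaged retina into geodesic zones
#'
#' Labels every pixel by its geodesic distance from the fovea along the
#' retinal sphere: posterior pole (< 10 mm), mid periphery (10-15 mm) and
#' far periphery (> 15 mm within the imaged field), and accumulates the
#' total gradable area (TA) of each zone both in mm^2 (from the area map)
#' and in pixel counts (the voxel dialect). Ungradable pixels of `mask`
#' (artifacts, manual exclusions, off-field) are excluded from TA.
#'
#' @param model An [eye_model()].
#' @param area_map Matching [pixel_area_map()].
#' @param mask Optional `perfusion_mask`; when `NULL`, every pixel on the
#'   imaged field is treated as gradable.
#' @param zone_radii Geodesic radii (mm) of the two zone boundaries.
#'   Default `c(10, 15)`.
#' @return An object of class `zone_partition`: matrices `zone` (0 outside,
#'   1 posterior, 2 mid, 3 far) and `gradable`, per-zone vectors `ta_area`
#'   (mm^2) and `ta_voxel` (px) with totals `ta_area_total`,
#'   `ta_voxel_total`, and `zone_radii`.
#' @export
assign_zones <- function(model, area_map, mask = NULL, zone_radii = c(10, 15)) {
  stopifnot(inherits(model, "eye_model"), inherits(area_map, "area_map"))
  if (!identical(dim(area_map$area), as.integer(model$image_size))) {
    stop("shape error: area map does not match the model image size")
  }
  stopifnot(length(zone_radii) == 2L, zone_radii[1] < zone_radii[2])
  if (is.null(mask)) {
    gradable <- area_map$inside
  } else {
    stopifnot(inherits(mask, "perfusion_mask"))
    if (!identical(dim(mask$state), dim(area_map$area))) {
      stop("shape error: mask does not match the model image size")
    }
    gradable <- area_map$inside & mask$state != STATE_UNGRADABLE
  }
  d <- area_map$geodesic
  zone <- matrix(0L, nrow(d), ncol(d))
  zone[area_map$inside] <- 3L
  zone[area_map$inside & d < zone_radii[2]] <- 2L
  zone[area_map$inside & d < zone_radii[1]] <- 1L

  ta_area <- vapply(1:3, function(z) sum(area_map$area[gradable & zone == z]), 0)
  ta_voxel <- vapply(1:3, function(z) sum(gradable & zone == z), 0)
  names(ta_area) <- names(ta_voxel) <- ZONE_NAMES
  structure(
    list(zone = zone, gradable = gradable,
         ta_area = ta_area, ta_area_total = sum(ta_area),
         ta_voxel = ta_voxel, ta_voxel_total = sum(ta_voxel),
         zone_radii = zone_radii),
    class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat("Retinal zone partition (boundaries at",
      paste(x$zone_radii, collapse = " and "), "mm geodesic)\n")
  df <- data.frame(zone = ZONE_NAMES,
                   ta_mm2 = round(x$ta_area, 2),
                   fraction = round(x$ta_area / x$ta_area_total, 4),
                   ta_px = x$ta_voxel)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Zone area fractions of the imaged field
#'
#' Convenience wrapper: numerically sums per-pixel retinal areas per zone
#' (no mask, whole gradable field) and returns each zone's fraction of the
#' total imaged surface area.
#'
#' @param model An [eye_model()].
#' @param zone_radii Zone boundaries in mm, default `c(10, 15)`.
#' @return Named numeric vector of the three fractions (sums to 1).
#' @export
zone_area_fractions <- function(model, zone_radii = c(10, 15)) {
  zp <- assign_zones(model, pixel_area_map(model), zone_radii = zone_radii)
  zp$ta_area / zp$ta_area_total
}

#' Per-zone and overall nonperfusion index
#'
#' The NPI of a zone is the nonperfused gradable area divided by the zone's
#' total gradable area (TA); the overall NPI divides total nonperfused area
#' by total TA and is identically the TA-weighted mean of the zone NPIs.
#' Two quantification dialects are supported: `"area"` sums true retinal
#' areas (mm^2) from the area map (distortion-corrected), `"voxel"` sums
#' raw pixel counts, which is subject to peripheral projection distortion.
#' NPIs are proportions in `[0, 1]`; multiply by 100 for percent. The
#' zero-handling transform ([transform_npi()]) is applied to the overall and
#' posterior-pole indices.
#'
#' A zone with zero gradable area yields `NA` for that zone (undefined) and
#' is excluded from the overall aggregate.
#'
#' @param mask A `perfusion_mask`.
#' @param zones Matching [assign_zones()] partition.
#' @param area_map Matching [pixel_area_map()].
#' @param dialect `"area"` (default) or `"voxel"`.
#' @param n_eyes Transform denominator for [transform_npi()], default 20.
#' @param patient_id,eye,visit_time Optional metadata recorded in the result.
#' @return A one-row data.frame of class `npi_measurement` with columns
#'   `patient_id`, `eye`, `visit_time`, `npi_posterior`, `npi_mid`,
#'   `npi_far`, `npi_overall`, `t_npi_overall`, `t_npi_posterior`,
#'   `n_images`.
#' @export
compute_npi <- function(mask, zones, area_map,
                        dialect = c("area", "voxel"), n_eyes = 20,
                        patient_id = NA_character_, eye = NA_character_,
                        visit_time = NA_real_) {
  stopifnot(inherits(mask, "perfusion_mask"), inherits(zones, "zone_partition"),
            inherits(area_map, "area_map"))
  dialect <- match.arg(dialect)
  if (!identical(dim(mask$state), dim(zones$zone))) {
    stop("shape error: mask does not match the zone partition")
  }
  nonper <- mask$state == STATE_NONPERFUSED & zones$gradable
  w <- if (dialect == "area") area_map$area else (zones$gradable * 1)
  ta <- if (dialect == "area") zones$ta_area else zones$ta_voxel
  num <- vapply(1:3, function(z) sum(w[nonper & zones$zone == z]), 0)
  npi_zone <- ifelse(ta > 0, num / ta, NA_real_)
  if (anyNA(npi_zone)) {
    warning("zone with zero gradable area: its NPI is undefined and excluded from the overall index")
  }
  ta_tot <- sum(ta[ta > 0])
  npi_overall <- if (ta_tot > 0) sum(num[ta > 0]) / ta_tot else NA_real_
  npi_zone <- unname(npi_zone)
  out <- data.frame(
    patient_id = patient_id, eye = eye, visit_time = visit_time,
    npi_posterior = npi_zone[1], npi_mid = npi_zone[2], npi_far = npi_zone[3],
    npi_overall = npi_overall,
    t_npi_overall = if (is.na(npi_overall)) NA_real_ else transform_npi(npi_overall, n_eyes),
    t_npi_posterior = if (is.na(npi_zone[1])) NA_real_ else transform_npi(npi_zone[1], n_eyes),
    n_images = 1L,
    stringsAsFactors = FALSE)
  class(out) <- c("npi_measurement", "data.frame")
  out
}

#' Average repeated measurements of one eye at one visit
#'
#' Grading is repeated on up to three images of the same eye per visit; the
#' per-zone and overall indices are averaged arithmetically and the number
#' of images recorded.
#'
#' @param measurements A list of `npi_measurement` rows (or a single
#'   `npi_measurement` data.frame of rows) for one patient/eye/visit.
#' @return A single averaged `npi_measurement` row.
#' @export
aggregate_visit <- function(measurements) {
  if (inherits(measurements, "npi_measurement")) {
    m <- measurements
  } else {
    stopifnot(is.list(measurements), length(measurements) >= 1L)
    m <- do.call(rbind, measurements)
  }
  if (nrow(m) < 1L || nrow(m) > 3L) {
    stop("aggregation error: expected 1-3 measurements per eye and visit")
  }
  key <- unique(m[, c("patient_id", "eye", "visit_time")])
  if (nrow(key) != 1L) {
    stop("aggregation error: measurements mix patients, eyes or visits")
  }
  out <- m[1, , drop = FALSE]
  num_cols <- c("npi_posterior", "npi_mid", "npi_far", "npi_overall",
                "t_npi_overall", "t_npi_posterior")
  out[num_cols] <- lapply(m[num_cols], mean)
  out$n_images <- nrow(m)
  rownames(out) <- NULL
  class(out) <- c("npi_measurement", "data.frame")
  out
}

#' Zero-handling transform for nonperfusion proportions
#'
#' Affine shrinkage that moves proportions off the boundary before
#' modeling: `T.NPI = (NPI * (n - 1) + 0.5) / n` with `n = 20` eyes by
#' default, mapping `[0, 1]` onto `[0.5/n, 1 - 0.5/n]`. Applied to the
#' overall and posterior-pole indices, where exact zeros occur.
#' `inverse_transform_npi()` is its exact inverse.
#'
#' @param npi Proportion(s) in `[0, 1]`.
#' @param t_npi Transformed proportion(s).
#' @param n_eyes Number of eyes `n`, at least 2. Default 20.
#' @return Transformed (or back-transformed) proportions.
#' @examples
#' transform_npi(c(0, 0.5, 1))        # 0.025 0.500 0.975
#' inverse_transform_npi(transform_npi(0.37))
#' @export
transform_npi <- function(npi, n_eyes = 20) {
  stopifnot(n_eyes >= 2)
  if (any(npi < 0 | npi > 1, na.rm = TRUE)) {
    stop("domain error: NPI proportions must lie in [0, 1]")
  }
  (npi * (n_eyes - 1) + 0.5) / n_eyes
}

#' @rdname transform_npi
#' @export
inverse_transform_npi <- function(t_npi, n_eyes = 20) {
  stopifnot(n_eyes >= 2)
  (t_npi * n_eyes - 0.5) / (n_eyes - 1)
}

#' Percentage change from baseline per eye
#'
#' For each eye, computes `100 * (value_t - value_0) / value_0` at every
#' post-baseline visit, then averages across eyes per visit. Eyes with a
#' zero (or missing) baseline are undefined, excluded, and counted.
#'
#' @param tbl Long data.frame with columns `patient_id`, `eye`,
#'   `visit_time` and the value column.
#' @param value_col Name of the value column. Default `"npi_overall"`.
#' @param baseline_time Visit time treated as baseline. Default 0.
#' @return A list with `per_eye` (long data.frame of per-eye percentage
#'   changes), `mean_by_visit` (average across eyes per visit) and
#'   `n_undefined` (eyes dropped for zero/missing baseline).
#' @export
pct_change_from_baseline <- function(tbl, value_col = "npi_overall",
                                     baseline_time = 0) {
  stopifnot(all(c("patient_id", "eye", "visit_time", value_col) %in% names(tbl)))
  sp <- split(tbl, interaction(tbl$patient_id, tbl$eye, drop = TRUE))
  rows <- list(); n_undef <- 0L
  for (d in sp) {
    b <- d[[value_col]][d$visit_time == baseline_time]
    if (length(b) != 1L || is.na(b) || b == 0) { n_undef <- n_undef + 1L; next }
    post <- d[d$visit_time != baseline_time, , drop = FALSE]
    if (!nrow(post)) next
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = post$patient_id, eye = post$eye, visit_time = post$visit_time,
      pct_change = 100 * (post[[value_col]] - b) / b, stringsAsFactors = FALSE)
  }
  if (n_undef > 0L) {
    message(n_undef, " eye(s) excluded from percentage change (zero or missing baseline)")
  }
  per_eye <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), eye = character(),
               visit_time = numeric(), pct_change = numeric())
  mean_by_visit <- if (nrow(per_eye)) {
    agg <- aggregate(pct_change ~ visit_time, per_eye, mean)
    agg[order(agg$visit_time), , drop = FALSE]
  } else data.frame(visit_time = numeric(), pct_change = numeric())
  list(per_eye = per_eye, mean_by_visit = mean_by_visit, n_undefined = n_undef)
}

#' Functional-measure transforms
#'
#' `log_oct()` is the base-10 logarithm of OCT central subfield thickness
#' (CST, micrometers), used to normalize its skewed distribution.
#' `snellen_from_logmar()` converts logMAR acuity to the Snellen
#' denominator on the 20-foot scale (`20 * 10^logmar`), and
#' `logmar_from_snellen()` inverts it. `logmar_count_fingers()` returns the
#' conventional logMAR value (1.9) assigned to counting-fingers vision,
#' flagged as coming from a non-numeric acuity.
#'
#' @param cst CST in micrometers, strictly positive.
#' @param logmar logMAR acuity value(s).
#' @param numerator,denominator Snellen fraction parts (e.g. 20/25).
#' @return Numeric vector(s) of transformed values.
#' @examples
#' log_oct(270)                 # 2.431...
#' snellen_from_logmar(0.176)   # ~30: between 20/25 and 20/30
#' @export
log_oct <- function(cst) {
  if (any(!is.finite(cst) | cst <= 0)) {
    stop("domain error: CST must be positive (micrometers)")
  }
  log10(cst)
}

#' @rdname log_oct
#' @export
snellen_from_logmar <- function(logmar) 20 * 10^logmar

#' @rdname log_oct
#' @export
logmar_from_snellen <- function(denominator, numerator = 20) {
  log10(denominator / numerator)
}

#' @rdname log_oct
#' @export
logmar_count_fingers <- function() {
  structure(1.9, source = "non-numeric acuity (counting fingers)")
}

#' Intragrader reliability and zone-to-overall correlations
#'
#' Two descriptive statistic sets over a table of repeated per-eye NPI
#' gradings: (i) intragrader reliability as the Pearson correlation between
#' each eye's first and third measurement of the same visit, for the
#' overall index and each zone (visits pooled); (ii) the Spearman rank
#' correlation of each zone's NPI with the overall NPI, computed on
#' per-eye-visit averaged values.
#'
#' @param tbl Long data.frame with columns `patient_id`, `eye`,
#'   `visit_time`, `image_index` (1-3) and the NPI columns
#'   `npi_posterior`, `npi_mid`, `npi_far`, `npi_overall`.
#' @return A list with named vectors `pearson_first_third` and
#'   `spearman_zone_overall`. Constant series give `NA` with a warning.
#' @export
reliability_and_zone_correlations <- function(tbl) {
  need <- c("patient_id", "eye", "visit_time", "image_index",
            "npi_posterior", "npi_mid", "npi_far", "npi_overall")
  stopifnot(all(need %in% names(tbl)))
  zones <- c("npi_overall", "npi_posterior", "npi_mid", "npi_far")

  first <- tbl[tbl$image_index == 1L, , drop = FALSE]
  third <- tbl[tbl$image_index == 3L, , drop = FALSE]
  key <- function(d) paste(d$patient_id, d$eye, d$visit_time, sep = "|")
  mm <- match(key(first), key(third))
  ok <- !is.na(mm)
  if (sum(ok) < 3L) stop("need at least 3 paired first/third measurements")
  pearson <- vapply(zones, function(z) {
    .cor_or_na(first[[z]][ok], third[[z]][mm[ok]], method = "pearson")
  }, 0)

  agg <- aggregate(tbl[zones], tbl[c("patient_id", "eye", "visit_time")], mean)
  spearman <- vapply(setdiff(zones, "npi_overall"), function(z) {
    .cor_or_na(agg[[z]], agg$npi_overall, method = "spearman")
  }, 0)
  list(pearson_first_third = pearson, spearman_zone_overall = spearman)
}

.cor_or_na <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("undefined correlation: constant series")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}
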