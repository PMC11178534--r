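#' Spherical model eye for ultra-widefield imaging
#'
#' Builds the geometric model that links pixels of an ultra-widefield (UWF)
#' fundus image to points on a spherical retina. The retina is modeled as a
#' perfect sphere (Navarro-style posterior radius, 12 mm by default) with the
#' fovea at the pole of the imaged cap. The image is the projection of the
#' spherical cap of geodesic radius `field_geodesic_radius` (measured along
#' the retinal surface from the fovea) onto the image plane, either by
#' stereographic projection from the point antipodal to the fovea (the
#' default, echoing how UWF devices present the retina) or by an
#' azimuthal-equidistant projection.
#'
#' The default `field_geodesic_radius` of 19.14 mm is calibrated against the
#' closed-form spherical-cap area so that, at `retina_radius = 12`, the
#' posterior pole (geodesic distance < 10 mm from the fovea) covers 32% of
#' the imaged surface, and the mid (10-15 mm) and far (> 15 mm) periphery
#' cover approximately 35% and 33%. Both radii are configurable.
#'
#' @param retina_radius Radius of the retinal sphere in mm. Default 12.
#' @param field_geodesic_radius Maximum geodesic distance from the fovea
#'   covered by the image, in mm. Must not exceed `pi * retina_radius`
#'   (the antipode). Default 19.14 (calibrated, see Details).
#' @param image_size Integer vector `c(rows, cols)`, at least 16 x 16.
#' @param projection `"stereographic"` (default) or
#'   `"azimuthal_equidistant"`.
#' @param fovea_pixel Image coordinates `c(row, col)` of the foveal center.
#'   Defaults to the image center. May be fractional.
#' @return An object of class `eye_model`.
#' @examples
#' m <- eye_model()
#' m
#' @seealso [image_to_sphere()], [pixel_area_map()], [geodesic_distance()]
#' @export
eye_model <- function(retina_radius = 12,
                      field_geodesic_radius = 19.14,
                      image_size = c(512L, 512L),
                      projection = c("stereographic", "azimuthal_equidistant"),
                      fovea_pixel = NULL) {
  projection <- match.arg(projection)
  if (!is.numeric(retina_radius) || length(retina_radius) != 1L ||
      !is.finite(retina_radius) || retina_radius <= 0) {
    stop("invalid geometry: 'retina_radius' must be a positive length (mm)")
  }
  if (!is.numeric(field_geodesic_radius) || length(field_geodesic_radius) != 1L ||
      !is.finite(field_geodesic_radius) || field_geodesic_radius <= 0) {
    stop("invalid geometry: 'field_geodesic_radius' must be a positive length (mm)")
  }
  if (field_geodesic_radius > pi * retina_radius + 1e-9) {
    stop(sprintf(
      "invalid geometry: field_geodesic_radius (%.3f mm) exceeds the antipodal distance pi*R = %.3f mm",
      field_geodesic_radius, pi * retina_radius))
  }
  image_size <- as.integer(round(image_size))
  if (length(image_size) != 2L || any(!is.finite(image_size)) || any(image_size < 16L)) {
    stop("invalid geometry: 'image_size' must be c(rows, cols) with both >= 16")
  }
  if (is.null(fovea_pixel)) {
    fovea_pixel <- (image_size + 1) / 2
  }
  fovea_pixel <- as.numeric(fovea_pixel)
  if (length(fovea_pixel) != 2L ||
      fovea_pixel[1] < 0.5 || fovea_pixel[1] > image_size[1] + 0.5 ||
      fovea_pixel[2] < 0.5 || fovea_pixel[2] > image_size[2] + 0.5) {
    stop("invalid geometry: 'fovea_pixel' must lie inside the image")
  }
  disc_radius_px <- min(fovea_pixel[1] - 0.5, image_size[1] + 0.5 - fovea_pixel[1],
                        fovea_pixel[2] - 0.5, image_size[2] + 0.5 - fovea_pixel[2])
  if (disc_radius_px <= 1) {
    stop("invalid geometry: fovea_pixel too close to the image border for an imaged disc")
  }
  structure(
    list(retina_radius = retina_radius,
         field_geodesic_radius = field_geodesic_radius,
         image_size = image_size,
         projection = projection,
         fovea_pixel = fovea_pixel,
         disc_radius_px = disc_radius_px),
    class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat("Spherical model eye\n")
  cat(sprintf("  retina radius:        %.3f mm\n", x$retina_radius))
  cat(sprintf("  imaged field:         %.3f mm geodesic (colatitude %.3f rad)\n",
              x$field_geodesic_radius, .field_colatitude(x)))
  cat(sprintf("  image size:           %d x %d px (disc radius %.1f px)\n",
              x$image_size[1], x$image_size[2], x$disc_radius_px))
  cat(sprintf("  projection:           %s\n", x$projection))
  cat(sprintf("  fovea pixel:          (%.1f, %.1f)\n",
              x$fovea_pixel[1], x$fovea_pixel[2]))
  cat(sprintf("  imaged cap area:      %.2f mm^2 (closed form)\n", cap_area(x)))
  invisible(x)
}

# colatitude (rad) of the imaged-field boundary
.field_colatitude <- function(model) model$field_geodesic_radius / model$retina_radius

# planar radius of the imaged-disc boundary in the projection plane (mm)
.plane_max <- function(model) {
  theta_f <- .field_colatitude(model)
  switch(model$projection,
         stereographic = 2 * model$retina_radius * tan(theta_f / 2),
         azimuthal_equidistant = model$retina_radius * theta_f)
}

# mm of projection plane per image pixel
.px_scale <- function(model) .plane_max(model) / model$disc_radius_px

#' Closed-form area of the imaged spherical cap
#'
#' Area of the retinal cap of geodesic radius `d` about the fovea,
#' `2*pi*R^2*(1 - cos(d/R))`. With `d = NULL` the full imaged field is used.
#' This closed form is the oracle against which the numerical per-pixel
#' area summation of [pixel_area_map()] is validated.
#'
#' @param model An [eye_model()].
#' @param d Geodesic radius in mm, or `NULL` for the whole imaged field.
#' @return Area in mm^2.
#' @export
cap_area <- function(model, d = NULL) {
  if (is.null(d)) d <- model$field_geodesic_radius
  R <- model$retina_radius
  2 * pi * R^2 * (1 - cos(d / R))
}

#' Closed-form area of a geodesic annulus (cap band)
#'
#' Retinal surface area between geodesic distances `d0` and `d1` from the
#' fovea: `2*pi*R^2*(cos(d0/R) - cos(d1/R))`.
#'
#' @param model An [eye_model()].
#' @param d0,d1 Inner and outer geodesic radii in mm, `d0 <= d1`.
#' @return Area in mm^2.
#' @export
cap_band_area <- function(model, d0, d1) {
  stopifnot(d0 <= d1, d0 >= 0)
  R <- model$retina_radius
  2 * pi * R^2 * (cos(d0 / R) - cos(d1 / R))
}

#' Map image pixels onto the retinal sphere
#'
#' Inverts the projection: each pixel coordinate is mapped to a point on the
#' retinal sphere expressed as (colatitude, azimuth), with colatitude 0 at
#' the fovea. Pixels outside the imaged disc are flagged rather than raising
#' an error, so the result doubles as the inside-field indicator.
#'
#' Azimuth 0 points along +x (increasing column), increasing
#' counter-clockwise with the image viewed in conventional orientation
#' (rows increasing downward).
#'
#' @param model An [eye_model()].
#' @param pixels Numeric matrix (or 2-vector) of image coordinates, one
#'   `(row, col)` pair per row. Fractional coordinates are allowed.
#' @return A data.frame with columns `colatitude` (rad), `azimuth` (rad in
#'   `[0, 2*pi)`), `inside` (logical, pixel lies on the imaged cap).
#' @export
image_to_sphere <- function(model, pixels) {
  pixels <- .as_pixel_matrix(pixels)
  if (any(pixels[, 1] < 0.5 - 1e-9 | pixels[, 1] > model$image_size[1] + 0.5 + 1e-9 |
          pixels[, 2] < 0.5 - 1e-9 | pixels[, 2] > model$image_size[2] + 0.5 + 1e-9)) {
    stop("pixel outside the image")
  }
  dx <- pixels[, 2] - model$fovea_pixel[2]
  dy <- pixels[, 1] - model$fovea_pixel[1]
  rho_px <- sqrt(dx^2 + dy^2)
  rho_mm <- rho_px * .px_scale(model)
  R <- model$retina_radius
  theta <- switch(model$projection,
                  stereographic = 2 * atan(rho_mm / (2 * R)),
                  azimuthal_equidistant = rho_mm / R)
  phi <- atan2(-dy, dx) %% (2 * pi)
  phi[rho_px == 0] <- 0
  data.frame(colatitude = theta,
             azimuth = phi,
             inside = rho_px <= model$disc_radius_px + 1e-9)
}

#' Map sphere points back to image pixels
#'
#' Forward projection, the inverse of [image_to_sphere()]. Points beyond the
#' imaged field still project (up to the projection's domain) but fall
#' outside the imaged disc.
#'
#' @param model An [eye_model()].
#' @param points Data.frame or matrix with columns `colatitude`, `azimuth`
#'   (radians).
#' @return Numeric matrix of `(row, col)` image coordinates.
#' @export
sphere_to_image <- function(model, points) {
  points <- as.data.frame(points)
  theta <- points$colatitude
  phi <- points$azimuth
  R <- model$retina_radius
  rho_mm <- switch(model$projection,
                   stereographic = 2 * R * tan(theta / 2),
                   azimuthal_equidistant = R * theta)
  rho_px <- rho_mm / .px_scale(model)
  cbind(row = model$fovea_pixel[1] - rho_px * sin(phi),
        col = model$fovea_pixel[2] + rho_px * cos(phi))
}

#' Great-circle distance between retinal points
#'
#' Geodesic (great-circle) distance along the retinal sphere between two
#' sets of points given as (colatitude, azimuth) pairs, in mm. Uses the
#' numerically robust atan2 form of the central angle.
#'
#' @param model An [eye_model()].
#' @param a,b Data.frames or matrices with columns `colatitude`, `azimuth`
#'   (recycled to a common length).
#' @return Numeric vector of distances in mm.
#' @export
geodesic_distance <- function(model, a, b) {
  a <- as.data.frame(a)
  b <- as.data.frame(b)
  n <- max(nrow(a), nrow(b))
  t1 <- rep_len(a$colatitude, n); p1 <- rep_len(a$azimuth, n)
  t2 <- rep_len(b$colatitude, n); p2 <- rep_len(b$azimuth, n)
  dp <- p2 - p1
  # central angle via atan2: stable for both tiny and near-antipodal separations
  s1 <- sin(t1); c1 <- cos(t1); s2 <- sin(t2); c2 <- cos(t2)
  y <- sqrt((s2 * sin(dp))^2 + (s1 * c2 - c1 * s2 * cos(dp))^2)
  x <- c1 * c2 + s1 * s2 * cos(dp)
  model$retina_radius * atan2(y, x)
}

# per-pixel-center sphere coordinates for a whole image; cheap (no areas)
# returns list(geodesic [mm], colatitude, azimuth, inside) as matrices
pixel_sphere_coords <- function(model) {
  nr <- model$image_size[1]; nc <- model$image_size[2]
  dy <- matrix(seq_len(nr) - model$fovea_pixel[1], nr, nc)
  dx <- matrix(rep(seq_len(nc) - model$fovea_pixel[2], each = nr), nr, nc)
  rho_px <- sqrt(dx^2 + dy^2)
  rho_mm <- rho_px * .px_scale(model)
  R <- model$retina_radius
  theta <- switch(model$projection,
                  stereographic = 2 * atan(rho_mm / (2 * R)),
                  azimuthal_equidistant = pmin(rho_mm / R, pi))
  phi <- atan2(-dy, dx) %% (2 * pi)
  list(geodesic = R * theta,
       colatitude = theta,
       azimuth = phi,
       inside = rho_px <= model$disc_radius_px + 1e-9)
}

.as_pixel_matrix <- function(pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2, byrow = FALSE)
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L) stop("'pixels' must have two columns (row, col)")
  storage.mode(pixels) <- "double"
  pixels
}

#' Read or write an eye model as YAML
#'
#' Serializes the model with the flat key set
#' `retina_radius_mm`, `field_geodesic_radius_mm`, `image_rows`,
#' `image_cols`, `projection`, `fovea_row`, `fovea_col`; the reader rebuilds
#' (and re-validates) the model from those keys.
#'
#' @param model An [eye_model()].
#' @param path File path of the YAML document.
#' @return `read_eye_model()` returns an `eye_model`; `write_eye_model()`
#'   returns `path` invisibly.
#' @export
write_eye_model <- function(model, path) {
  stopifnot(inherits(model, "eye_model"))
  yaml::write_yaml(list(
    retina_radius_mm = model$retina_radius,
    field_geodesic_radius_mm = model$field_geodesic_radius,
    image_rows = model$image_size[1],
    image_cols = model$image_size[2],
    projection = model$projection,
    fovea_row = model$fovea_pixel[1],
    fovea_col = model$fovea_pixel[2]), path)
  invisible(path)
}

#' @rdname write_eye_model
#' @export
read_eye_model <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("retina_radius_mm", "field_geodesic_radius_mm", "image_rows",
            "image_cols", "projection", "fovea_row", "fovea_col")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("eye-model YAML missing keys: ", paste(miss, collapse = ", "))
  eye_model(retina_radius = y$retina_radius_mm,
            field_geodesic_radius = y$field_geodesic_radius_mm,
            image_size = c(y$image_rows, y$image_cols),
            projection = y$projection,
            fovea_pixel = c(y$fovea_row, y$fovea_col))
}
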