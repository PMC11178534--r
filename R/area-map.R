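#' Per-pixel retinal area map by spherical trigonometry
#'
#' Computes, for every image pixel, the retinal surface area (mm^2) of its
#' footprint on the spherical retina. The four pixel corners are mapped
#' through the inverse projection onto the sphere; the footprint is split
#' along one diagonal into two spherical triangles and each triangle's area
#' is obtained from its spherical excess via L'Huilier's theorem. Because
#' adjacent pixels share corner arcs, areas are exactly additive under grid
#' refinement, and the sum over the imaged cap converges to the closed-form
#' cap area `2*pi*R^2*(1 - cos(field/R))` (see [cap_area()]).
#'
#' A pixel belongs to the imaged field when its *center* lies on the imaged
#' disc; `pixel_area` is zero outside the field.
#'
#' @param model An [eye_model()].
#' @return An object of class `area_map`: a list with matrices `area`
#'   (mm^2, zero outside the field), `inside` (logical), `geodesic`
#'   (mm from the fovea at pixel centers), `azimuth` (rad), plus the
#'   generating `model`.
#' @examples
#' am <- pixel_area_map(eye_model(image_size = c(64, 64)))
#' sum(am$area) / cap_area(am$model)  # ~1
#' @export
pixel_area_map <- function(model) {
  stopifnot(inherits(model, "eye_model"))
  nr <- model$image_size[1]; nc <- model$image_size[2]
  R <- model$retina_radius

  # corner grid: (nr+1) x (nc+1) points at pixel boundaries
  rr <- matrix(seq(0.5, nr + 0.5), nr + 1L, nc + 1L)
  cc <- matrix(rep(seq(0.5, nc + 0.5), each = nr + 1L), nr + 1L, nc + 1L)
  dy <- rr - model$fovea_pixel[1]
  dx <- cc - model$fovea_pixel[2]
  rho_mm <- sqrt(dx^2 + dy^2) * .px_scale(model)
  theta <- switch(model$projection,
                  stereographic = 2 * atan(rho_mm / (2 * R)),
                  azimuthal_equidistant = pmin(rho_mm / R, pi))
  phi <- atan2(-dy, dx)

  # unit vectors of the corners
  st <- sin(theta)
  vx <- st * cos(phi); vy <- st * sin(phi); vz <- cos(theta)
  if (any(!is.finite(vx)) || any(!is.finite(vy)) || any(!is.finite(vz))) {
    stop("numerical geometry error: non-finite corner coordinates (degenerate projection)")
  }

  ir <- seq_len(nr); ic <- seq_len(nc)
  # arc lengths between corner pairs (angles on the unit sphere)
  top   <- .arc(vx[ir, ic], vy[ir, ic], vz[ir, ic],
                vx[ir, ic + 1L], vy[ir, ic + 1L], vz[ir, ic + 1L])
  bot   <- .arc(vx[ir + 1L, ic], vy[ir + 1L, ic], vz[ir + 1L, ic],
                vx[ir + 1L, ic + 1L], vy[ir + 1L, ic + 1L], vz[ir + 1L, ic + 1L])
  left  <- .arc(vx[ir, ic], vy[ir, ic], vz[ir, ic],
                vx[ir + 1L, ic], vy[ir + 1L, ic], vz[ir + 1L, ic])
  right <- .arc(vx[ir, ic + 1L], vy[ir, ic + 1L], vz[ir, ic + 1L],
                vx[ir + 1L, ic + 1L], vy[ir + 1L, ic + 1L], vz[ir + 1L, ic + 1L])
  diag  <- .arc(vx[ir, ic], vy[ir, ic], vz[ir, ic],
                vx[ir + 1L, ic + 1L], vy[ir + 1L, ic + 1L], vz[ir + 1L, ic + 1L])

  # split along the c00-c11 diagonal: (c00,c10,c11) and (c00,c11,c01)
  area <- R^2 * (.lhuilier(left, bot, diag) + .lhuilier(diag, right, top))

  ctr <- pixel_sphere_coords(model)
  area[!ctr$inside] <- 0
  structure(
    list(area = area,
         inside = ctr$inside,
         geodesic = ctr$geodesic,
         azimuth = ctr$azimuth,
         model = model),
    class = "area_map")
}

# angle between unit vectors, via atan2 (stable for small separations)
.arc <- function(ax, ay, az, bx, by, bz) {
  cx <- ay * bz - az * by
  cy <- az * bx - ax * bz
  cz <- ax * by - ay * bx
  atan2(sqrt(cx^2 + cy^2 + cz^2), ax * bx + ay * by + az * bz)
}

# spherical excess of a triangle with side arcs a, b, c (L'Huilier)
.lhuilier <- function(a, b, c) {
  s <- (a + b + c) / 2
  t <- tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) * tan((s - c) / 2)
  t[t < 0] <- 0  # guard tiny negative round-off for degenerate triangles
  4 * atan(sqrt(t))
}

#' @export
print.area_map <- function(x, ...) {
  cat("Per-pixel retinal area map\n")
  cat(sprintf("  image:        %d x %d px, %d px inside the field\n",
              nrow(x$area), ncol(x$area), sum(x$inside)))
  tot <- sum(x$area)
  cat(sprintf("  summed area:  %.2f mm^2 (closed-form cap %.2f mm^2, rel. err %.3g)\n",
              tot, cap_area(x$model), abs(tot - cap_area(x$model)) / cap_area(x$model)))
  invisible(x)
}

#' Export an area map as 32-bit float TIFF
#'
#' Writes the per-pixel areas (mm^2) as a single-channel 32-bit float TIFF.
#'
#' @param area_map An [pixel_area_map()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_area_map_tiff <- function(area_map, path) {
  stopifnot(inherits(area_map, "area_map"))
  tiff::writeTIFF(area_map$area, path, bits.per.sample = 32L)
  invisible(path)
}
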