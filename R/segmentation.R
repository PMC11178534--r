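# Per-pixel perfusion state coding shared across the package:
#   state:      0 ungradable, 1 perfused, 2 nonperfused
#   provenance: 0 automatic, 1 positive_correction, 2 negative_correction,
#               3 artifact
STATE_UNGRADABLE <- 0L
STATE_PERFUSED <- 1L
STATE_NONPERFUSED <- 2L
PROV_AUTOMATIC <- 0L
PROV_POSITIVE <- 1L
PROV_NEGATIVE <- 2L
PROV_ARTIFACT <- 3L

.new_perfusion_mask <- function(state, provenance, auto_state) {
  structure(list(state = state, provenance = provenance, auto_state = auto_state),
            class = "perfusion_mask")
}

#' Construct a perfusion mask from a coded state matrix
#'
#' Wraps a matrix of coded per-pixel perfusion states (0 ungradable,
#' 1 perfused, 2 nonperfused) into a `perfusion_mask`, e.g. for masks
#' produced by an external (manual) grader. Pixels outside the imaged field
#' of `model` are forced ungradable.
#'
#' @param state Integer matrix of codes in `{0, 1, 2}`.
#' @param model Optional [eye_model()]; if given, enforces the image size
#'   and marks pixels off the imaged disc ungradable.
#' @return A `perfusion_mask`.
#' @export
perfusion_mask <- function(state, model = NULL) {
  state <- matrix(as.integer(state), nrow(state), ncol(state))
  if (!all(state %in% c(STATE_UNGRADABLE, STATE_PERFUSED, STATE_NONPERFUSED))) {
    stop("perfusion states must be coded 0 (ungradable), 1 (perfused), 2 (nonperfused)")
  }
  if (!is.null(model)) {
    if (!identical(dim(state), as.integer(model$image_size))) {
      stop("state matrix does not match the model image size")
    }
    state[!pixel_sphere_coords(model)$inside] <- STATE_UNGRADABLE
  }
  .new_perfusion_mask(state, matrix(PROV_AUTOMATIC, nrow(state), ncol(state)), state)
}

#' @export
print.perfusion_mask <- function(x, ...) {
  n <- table(factor(x$state, levels = 0:2,
                    labels = c("ungradable", "perfused", "nonperfused")))
  cat("Perfusion mask", paste(dim(x$state), collapse = " x "), "px\n")
  print(n)
  invisible(x)
}

#' Guided automatic segmentation of perfused retina
#'
#' Deterministic stand-in for interactive level-set region delineation:
#' pixels whose intensity falls in `threshold_band` (closed interval) are
#' candidates, the connected components containing at least one seed are
#' kept, and the boundary is regularized by a morphological
#' closing-then-opening with a disc structuring element of radius
#' `smoothing` (in pixels; 0 disables smoothing). All other gradable pixels
#' are marked nonperfused; pixels off the imaged disc are ungradable.
#'
#' On angiogram-like images the perfused retina is the bright
#' fluorescein-filled region, so seeds are placed on well-perfused retina
#' (e.g. near the posterior pole) and the band brackets the perfused
#' intensity level.
#'
#' @param image Numeric matrix of grayscale intensities matching
#'   `model$image_size`.
#' @param model An [eye_model()] defining the imaged field.
#' @param seeds Matrix of `(row, col)` seed pixels; at least one must lie on
#'   the imaged field.
#' @param smoothing Non-negative disc radius (px) of the morphological
#'   regularizer. Default 2.
#' @param threshold_band Length-2 numeric `c(low, high)`, `low < high`;
#'   intensities in `[low, high]` (inclusive) are perfusion candidates.
#' @return A `perfusion_mask`.
#' @export
levelset_segment <- function(image, model, seeds,
                             smoothing = 2,
                             threshold_band = c(128, 255)) {
  stopifnot(inherits(model, "eye_model"))
  image <- as.matrix(image)
  if (!identical(dim(image), as.integer(model$image_size))) {
    stop("image does not match the model image size")
  }
  if (length(threshold_band) != 2L || threshold_band[1] >= threshold_band[2]) {
    stop("'threshold_band' must be c(low, high) with low < high")
  }
  if (smoothing < 0) stop("'smoothing' must be non-negative")
  seeds <- round(.as_pixel_matrix(seeds))
  inside <- pixel_sphere_coords(model)$inside
  seed_idx <- cbind(seeds[, 1], seeds[, 2])
  if (any(seeds[, 1] < 1 | seeds[, 1] > nrow(image) |
          seeds[, 2] < 1 | seeds[, 2] > ncol(image)) || !any(inside[seed_idx])) {
    stop("seed error: at least one seed must lie on the imaged field")
  }

  candidate <- image >= threshold_band[1] & image <= threshold_band[2]
  labels <- EBImage::imageData(EBImage::bwlabel(candidate))
  keep <- setdiff(unique(labels[seed_idx]), 0)
  region <- matrix(labels %in% keep, nrow(image), ncol(image))
  if (!any(region)) {
    warning("empty grown region: no candidate component contains a seed; all-nonperfused mask")
  } else if (smoothing > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(round(smoothing)) + 1L, shape = "disc")
    sm <- EBImage::opening(EBImage::closing(region * 1, brush), brush)
    region <- EBImage::imageData(sm) > 0.5
  }

  state <- matrix(STATE_UNGRADABLE, nrow(image), ncol(image))
  state[inside] <- ifelse(region[inside], STATE_PERFUSED, STATE_NONPERFUSED)
  .new_perfusion_mask(state,
                      matrix(PROV_AUTOMATIC, nrow(image), ncol(image)),
                      state)
}

# region spec -> logical matrix; accepts a logical matrix or (row, col) pairs
.region_matrix <- function(region, dims) {
  if (is.matrix(region) && is.logical(region)) {
    if (!identical(dim(region), as.integer(dims))) stop("region error: region mask size mismatch")
    return(region)
  }
  region <- round(.as_pixel_matrix(region))
  if (any(region[, 1] < 1 | region[, 1] > dims[1] |
          region[, 2] < 1 | region[, 2] > dims[2])) {
    stop("region error: region extends outside the image")
  }
  out <- matrix(FALSE, dims[1], dims[2])
  out[cbind(region[, 1], region[, 2])] <- TRUE
  out
}

#' Manual correction of an automatic segmentation
#'
#' Applies a grader's correction region to a mask. For `target =
#' "perfusion"`, a positive correction marks the region perfused (an area
#' the automatic step incorrectly excluded) and a negative correction marks
#' it nonperfused (an area incorrectly included). For `target =
#' "gradable_area"`, a negative correction removes the region from the
#' gradable area (ungradable), and a positive correction restores it to the
#' automatic segmentation state. Corrections only ever touch pixels inside
#' the imaged field; provenance is recorded per pixel.
#'
#' @param mask A `perfusion_mask`.
#' @param region Logical matrix or `(row, col)` coordinate matrix; must be
#'   non-empty and inside the image.
#' @param mode `"positive"` or `"negative"`.
#' @param target `"perfusion"` (default) or `"gradable_area"`.
#' @return The corrected `perfusion_mask`.
#' @export
apply_correction <- function(mask, region,
                             mode = c("positive", "negative"),
                             target = c("perfusion", "gradable_area")) {
  stopifnot(inherits(mask, "perfusion_mask"))
  mode <- match.arg(mode)
  target <- match.arg(target)
  reg <- .region_matrix(region, dim(mask$state))
  if (!any(reg)) stop("region error: empty correction region")
  # pixels the automatic step could grade: everything inside the imaged field
  in_field <- mask$auto_state != STATE_UNGRADABLE
  sel <- reg & in_field
  prov <- if (mode == "positive") PROV_POSITIVE else PROV_NEGATIVE
  if (target == "perfusion") {
    sel <- sel & mask$state != STATE_UNGRADABLE
    mask$state[sel] <- if (mode == "positive") STATE_PERFUSED else STATE_NONPERFUSED
  } else if (mode == "negative") {
    sel <- sel & mask$state != STATE_UNGRADABLE
    mask$state[sel] <- STATE_UNGRADABLE
  } else {
    sel <- sel & mask$state == STATE_UNGRADABLE
    mask$state[sel] <- mask$auto_state[sel]
  }
  mask$provenance[sel] <- prov
  mask
}

#' Exclude imaging artifacts from the gradable area
#'
#' Marks artifact regions (e.g. eyelash occlusions) ungradable so they drop
#' out of every area sum; provenance is recorded as `artifact`. An empty
#' list leaves the mask untouched.
#'
#' @param mask A `perfusion_mask`.
#' @param artifact_regions List of regions (logical matrices or coordinate
#'   matrices), or a single region.
#' @return The updated `perfusion_mask`.
#' @export
exclude_artifacts <- function(mask, artifact_regions) {
  stopifnot(inherits(mask, "perfusion_mask"))
  if (is.null(artifact_regions) || (is.list(artifact_regions) && !length(artifact_regions))) {
    return(mask)
  }
  if (!is.list(artifact_regions) || is.data.frame(artifact_regions)) {
    artifact_regions <- list(artifact_regions)
  }
  acc <- matrix(FALSE, nrow(mask$state), ncol(mask$state))
  for (r in artifact_regions) acc <- acc | .region_matrix(r, dim(mask$state))
  sel <- acc & mask$state != STATE_UNGRADABLE
  mask$state[sel] <- STATE_UNGRADABLE
  mask$provenance[acc] <- PROV_ARTIFACT
  mask
}

#' Read and write coded perfusion masks as 8-bit PNG
#'
#' Masks are stored with the byte codes 0 (ungradable), 1 (perfused),
#' 2 (nonperfused).
#'
#' @param mask A `perfusion_mask`.
#' @param path PNG file path.
#' @return `read_mask_png()` returns a `perfusion_mask`;
#'   `write_mask_png()` returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "perfusion_mask"))
  EBImage::writeImage(EBImage::Image(t(mask$state) / 255), path, type = "png")
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  perfusion_mask(t(round(img * 255)))
}

#' Read and write grayscale UWF-like images
#'
#' Images are exchanged as 8-bit grayscale PNG or TIFF with intensities on
#' the 0-255 scale; internally they are plain numeric matrices in
#' `(row, col)` orientation.
#'
#' @param image Numeric matrix of intensities in `[0, 255]`.
#' @param path Image file path (`.png` or `.tif`/`.tiff`).
#' @return `read_uwf_image()` returns the intensity matrix;
#'   `write_uwf_image()` returns `path` invisibly.
#' @export
write_uwf_image <- function(image, path) {
  type <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "png"
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(image, 0), 255)) / 255),
                      path, type = type)
  invisible(path)
}

#' @rdname write_uwf_image
#' @export
read_uwf_image <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  t(img * 255)
}
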