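#' Scalar image volume on a regular 3D grid
#'
#' A `voxel_grid` couples a numeric (or logical, for masks) 3D array with
#' its physical geometry: per-axis spacing and origin, both in mm. Arrays
#' are indexed `[x, y, z]`, x fastest; axial slices run along z.
#'
#' @param values 3D array of voxel values.
#' @param spacing numeric length-3, mm per voxel along (x, y, z); all > 0.
#' @param origin numeric length-3, mm offset of the first voxel centre.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing = c(1.5, 1.5, 1.5), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array")
  }
  if (any(dim(values) < 1L)) stop("grid needs at least 1 voxel per axis")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive numbers (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite numbers (mm)")
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing %s mm, %s\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              if (is.logical(x$values))
                sprintf("%d occupied", sum(x$values))
              else sprintf("range [%.3g, %.3g]",
                           min(x$values), max(x$values))))
  invisible(x)
}

#' Binary lesion mask paired with an image grid
#'
#' Coerces an array or `voxel_grid` to a logical-valued `voxel_grid`. A
#' voxel belongs to the region of interest iff its occupancy flag is true;
#' there is no partial-volume weighting.
#'
#' @param x array or `voxel_grid` with 0/1 or logical values.
#' @inheritParams voxel_grid
#' @return a `voxel_grid` whose values are logical.
#' @export
binary_mask <- function(x, spacing = c(1.5, 1.5, 1.5), origin = c(0, 0, 0)) {
  if (inherits(x, "voxel_grid")) {
    x$values <- array(as.logical(x$values), dim(x$values))
    return(x)
  }
  voxel_grid(array(as.logical(x), dim(x)), spacing, origin)
}

#' Check that a mask shares its image's geometry
#'
#' @param image,mask `voxel_grid` objects.
#' @param tol relative tolerance on spacing agreement.
#' @return invisibly `TRUE`; errors on mismatch listing both shapes.
#' @export
validate_geometry <- function(image, mask, tol = 1e-6) {
  stopifnot(inherits(image, "voxel_grid"), inherits(mask, "voxel_grid"))
  if (!identical(dim(image$values), dim(mask$values))) {
    stop(sprintf("geometry mismatch: image %s vs mask %s",
                 paste(dim(image$values), collapse = "x"),
                 paste(dim(mask$values), collapse = "x")))
  }
  if (any(abs(image$spacing - mask$spacing) > tol * image$spacing)) {
    stop(sprintf("spacing mismatch: image (%s) vs mask (%s)",
                 paste(image$spacing, collapse = ", "),
                 paste(mask$spacing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' One patient/timepoint observation: image, mask and dose label
#'
#' @param patient_id opaque identifier.
#' @param timepoint one of `TIMEPOINTS` (`"t0"`, `"t11"`, ..., `"t55"`),
#'   labelling the cumulative PTV1 dose in Gy.
#' @param image `voxel_grid` of MR intensities.
#' @param mask logical `voxel_grid` with geometry identical to `image`.
#' @return an object of class `lesion_obs`.
#' @export
lesion_observation <- function(patient_id, timepoint, image, mask) {
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  mask <- binary_mask(mask)
  validate_geometry(image, mask)
  structure(list(patient_id = as.character(patient_id),
                 timepoint = timepoint,
                 dose_gy = unname(TIMEPOINT_DOSES[timepoint]),
                 image = image, mask = mask),
            class = "lesion_obs")
}

#' @export
print.lesion_obs <- function(x, ...) {
  cat(sprintf("<lesion_obs> patient %s @ %s (%g Gy), %d ROI voxels\n",
              x$patient_id, x$timepoint, x$dose_gy, sum(x$mask$values)))
  invisible(x)
}

#' Extract the region-of-interest voxels
#'
#' Returns one row per occupied voxel, ordered deterministically by grid
#' index with x fastest (R column-major order).
#'
#' @param image `voxel_grid` of intensities.
#' @param mask logical `voxel_grid`, same geometry.
#' @return data.frame with columns `intensity`, `i`, `j`, `k` (1-based
#'   grid indices).
#' @export
roi_voxels <- function(image, mask) {
  validate_geometry(image, mask)
  occ <- which(mask$values)
  if (length(occ) == 0L) stop("empty ROI: mask contains no occupied voxel")
  idx <- arrayInd(occ, dim(mask$values))
  data.frame(intensity = as.numeric(image$values[occ]),
             i = idx[, 1], j = idx[, 2], k = idx[, 3])
}

#' Physical coordinates (mm) of occupied voxel centres
#' @noRd
roi_coords_mm <- function(mask) {
  occ <- which(mask$values)
  if (length(occ) == 0L) stop("empty ROI: mask contains no occupied voxel")
  idx <- arrayInd(occ, dim(mask$values))
  sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}
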