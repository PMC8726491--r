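#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of Hounsfield units together with its
#' geometry: voxel spacing (mm), the world coordinate of the centre of voxel
#' `(0, 0, 0)` (the origin), and a 3x3 matrix of direction cosines whose
#' columns give the world direction of each voxel axis. World coordinates use
#' the LPS (left-posterior-superior) convention in millimetres throughout the
#' package; NIfTI's RAS affine is converted at the I/O boundary. Voxel
#' indexing is 0-based and the coordinate is carried by the voxel centre.
#'
#' @param values Numeric 3D array of HU values; all values must lie in
#'   \[-1024, 3071\], the 12-bit CT range.
#' @param spacing Positive numeric length-3 vector of voxel spacing in mm.
#' @param origin Numeric length-3 vector, LPS mm of voxel (0,0,0) centre.
#' @param orientation 3x3 orthonormal matrix of direction cosines (columns =
#'   voxel axes in LPS world space). Defaults to identity (axis-aligned).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0),
                      orientation = diag(3)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stopf("`values` must be a 3D array")
  }
  storage.mode(values) <- "double"
  rng <- range(values, finite = TRUE)
  if (any(!is.finite(values))) stopf("HU values must be finite")
  if (rng[1] < -1024 || rng[2] > 3071) {
    stopf("HU values must lie within [-1024, 3071]; got range [%g, %g]",
          rng[1], rng[2])
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("`spacing` must be three positive numbers (mm)")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stopf("`origin` must be three finite numbers (mm)")
  }
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6) {
    stopf("`orientation` must be a 3x3 orthonormal matrix")
  }
  structure(
    list(values = values, spacing = spacing, origin = origin,
         orientation = orientation),
    class = "ct_volume"
  )
}

#' Binary mask aligned to a CT volume
#'
#' A `mask_volume` shares the geometry fields of its parent [ct_volume()] and
#' stores a logical 3D array.
#'
#' @param values Logical (or 0/1) 3D array.
#' @param geometry A `ct_volume` or `mask_volume` supplying spacing, origin
#'   and orientation; alternatively pass `spacing`, `origin`, `orientation`.
#' @param spacing,origin,orientation Geometry fields, used when `geometry` is
#'   missing; same semantics as in [ct_volume()].
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(values, geometry = NULL, spacing = NULL,
                        origin = c(0, 0, 0), orientation = diag(3)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stopf("mask `values` must be a 3D array")
  }
  if (is.numeric(values)) {
    if (any(!values %in% c(0, 1))) stopf("numeric mask values must be 0 or 1")
    values <- array(values != 0, dim = dim(values))
  }
  if (!is.logical(values)) stopf("mask `values` must be logical or 0/1")
  if (!is.null(geometry)) {
    if (!all(dim(values) == dim(geometry$values))) {
      stopf("mask shape %s does not match parent volume shape %s",
            paste(dim(values), collapse = "x"),
            paste(dim(geometry$values), collapse = "x"))
    }
    spacing <- geometry$spacing
    origin <- geometry$origin
    orientation <- geometry$orientation
  }
  if (is.null(spacing)) stopf("supply `geometry` or `spacing`")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), orientation = as.matrix(orientation)),
    class = "mask_volume"
  )
}

#' Convert between voxel indices and world coordinates
#'
#' `voxel_to_world()` maps 0-based (possibly fractional) voxel indices to LPS
#' mm; `world_to_voxel()` is its exact inverse.
#'
#' @param vol A `ct_volume` or `mask_volume`.
#' @param idx Numeric matrix (n x 3) or length-3 vector of 0-based indices.
#' @param xyz Numeric matrix (n x 3) or length-3 vector of LPS mm points.
#' @return An n x 3 matrix.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind3(idx)
  t(vol$orientation %*% (t(idx) * vol$spacing) + vol$origin)
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind3(xyz)
  t((crossprod(vol$orientation, t(xyz) - vol$origin)) / vol$spacing)
}

rbind3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3L)
  if (ncol(x) != 3L) stopf("coordinates must have 3 columns")
  x
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s voxels, %d foreground\n",
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

# Shared geometry check used by measurement / segmentation code.
same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$values) == dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

# Voxel volume in millilitres (1 ml = 1000 mm^3).
voxel_ml <- function(vol) prod(vol$spacing) / 1000
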