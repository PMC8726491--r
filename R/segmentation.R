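# Proximal-femur VOI extraction: HU-bounded 3D region growing, interior
# (marrow cavity) filling, and exclusion of everything inferior to the
# lesser-trochanter plane.

#' Region-growing configuration
#'
#' @param seed_point 0-based voxel index triple inside the grid; the voxel's
#'   HU must lie within `[hu_low, hu_high]`.
#' @param hu_low,hu_high HU bounds of the growing band. The default band
#'   `[126, 3071]` captures cortical and trabecular bone (the bone-band lower
#'   edge of the HU-histogram analysis); marrow is added afterwards by
#'   [fill_interior()].
#' @param connectivity 6 or 26 (default) neighbour connectivity.
#' @return A list of class `region_grow_config`.
#' @export
region_grow_config <- function(seed_point, hu_low = 126, hu_high = 3071,
                               connectivity = 26) {
  if (length(seed_point) != 3L || any(seed_point != round(seed_point))) {
    stopf("`seed_point` must be three integer voxel indices (0-based)")
  }
  if (hu_low > hu_high) stopf("`hu_low` must be <= `hu_high`")
  if (!connectivity %in% c(6, 26)) stopf("`connectivity` must be 6 or 26")
  structure(list(seed_point = as.integer(seed_point), hu_low = hu_low,
                 hu_high = hu_high, connectivity = as.integer(connectivity)),
            class = "region_grow_config")
}

#' Seeded 3D region growing
#'
#' Returns the maximal connected set of voxels containing the seed whose HU
#' lies within the configured band, under 6- or 26-connectivity. The result
#' is deterministic (breadth-first growth order does not affect the set).
#'
#' @param volume A [ct_volume()].
#' @param config A [region_grow_config()].
#' @return A [mask_volume()] aligned to `volume`.
#' @export
region_grow <- function(volume, config) {
  if (!inherits(volume, "ct_volume")) stopf("`volume` must be a ct_volume")
  if (!inherits(config, "region_grow_config")) {
    stopf("`config` must be a region_grow_config")
  }
  dims <- dim(volume$values)
  sp <- config$seed_point
  if (any(sp < 0) || any(sp >= dims)) stopf("seed point outside the grid")
  seed_hu <- volume$values[sp[1] + 1L, sp[2] + 1L, sp[3] + 1L]
  if (seed_hu < config$hu_low || seed_hu > config$hu_high) {
    stopf("seed voxel HU %.1f outside growing band [%g, %g]",
          seed_hu, config$hu_low, config$hu_high)
  }
  grown <- .region_grow_cpp(as.numeric(volume$values), dims, sp,
                            config$hu_low, config$hu_high,
                            config$connectivity)
  mask_volume(array(grown, dims), geometry = volume)
}

#' Fill enclosed cavities of a binary mask
#'
#' Adds to the mask every background component not 6-connected to the grid
#' boundary (3D hole filling), so that a region-grown cortical shell becomes
#' a solid bone including the marrow space. Idempotent; output is a superset
#' of the input.
#'
#' @param cortex_mask A nonempty [mask_volume()].
#' @return A [mask_volume()].
#' @export
fill_interior <- function(cortex_mask) {
  if (!inherits(cortex_mask, "mask_volume")) stopf("`cortex_mask` must be a mask_volume")
  if (!any(cortex_mask$values)) stopf("`cortex_mask` is empty")
  dims <- dim(cortex_mask$values)
  filled <- .fill_interior_cpp(cortex_mask$values, dims)
  out <- cortex_mask
  out$values <- array(filled, dims)
  out
}

#' Locate the inferior lesser-trochanter plane
#'
#' Scans axial slices from inferior to superior and returns the most inferior
#' slice (0-based index) at which the in-plane left-right width of the bone
#' cross-section exceeds the shaft baseline width by `prominence` mm — the
#' level where the lesser-trochanter boss first protrudes from the shaft.
#' Supplying `override` bypasses detection.
#'
#' @param mask A nonempty [mask_volume()] of the (filled) femur.
#' @param axis Slice axis (3 = axial, the default and only supported value).
#' @param prominence Width excess over baseline, mm.
#' @param baseline_slices Number of most-inferior nonempty slices defining the
#'   shaft baseline width.
#' @param override Optional 0-based slice index returned verbatim.
#' @return 0-based slice index.
#' @export
detect_cut_plane <- function(mask, axis = 3, prominence = 2,
                             baseline_slices = 5, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  if (!inherits(mask, "mask_volume")) stopf("`mask` must be a mask_volume")
  if (axis != 3) stopf("only axial (axis = 3) cut planes are supported")
  if (!any(mask$values)) stopf("`mask` is empty")
  dims <- dim(mask$values)
  width <- rep(NA_real_, dims[3])
  for (k in seq_len(dims[3])) {
    sl <- mask$values[, , k]
    if (!any(sl)) next
    xs <- which(rowSums(sl) > 0)
    width[k] <- (max(xs) - min(xs)) * mask$spacing[1]
  }
  nonempty <- which(!is.na(width))
  if (length(nonempty) < baseline_slices + 2L) {
    stopf("mask has too few nonempty slices to establish a shaft baseline")
  }
  base <- stats::median(width[nonempty[seq_len(baseline_slices)]])
  hit <- nonempty[width[nonempty] >= base + prominence]
  if (!length(hit)) {
    stopf("no lesser-trochanter prominence found (baseline width %.1f mm); supply `override` with a manual cut plane",
          base)
  }
  as.integer(min(hit) - 1L)
}

#' Crop a femur mask to the proximal VOI
#'
#' Removes every voxel inferior to the cut plane (the plane itself is kept)
#' and recomputes counts and volume.
#'
#' @param mask A [mask_volume()].
#' @param cut_plane_z 0-based slice index within the grid.
#' @return An object of class `proximal_femur_voi`: list with `mask`,
#'   `cut_plane_z`, `voxel_count`, `volume_ml`.
#' @export
crop_to_voi <- function(mask, cut_plane_z) {
  if (!inherits(mask, "mask_volume")) stopf("`mask` must be a mask_volume")
  dims <- dim(mask$values)
  cut_plane_z <- as.integer(cut_plane_z)
  if (cut_plane_z < 0 || cut_plane_z >= dims[3]) {
    stopf("`cut_plane_z` = %d outside grid (0..%d)", cut_plane_z, dims[3] - 1L)
  }
  out <- mask
  if (cut_plane_z > 0) out$values[, , seq_len(cut_plane_z)] <- FALSE
  n <- sum(out$values)
  if (n == 0L) stopf("VOI is empty after cropping at slice %d", cut_plane_z)
  structure(list(mask = out, cut_plane_z = cut_plane_z, voxel_count = n,
                 volume_ml = n * voxel_ml(mask)),
            class = "proximal_femur_voi")
}

#' @export
print.proximal_femur_voi <- function(x, ...) {
  cat(sprintf("<proximal_femur_voi> %d voxels (%.1f ml), cut plane z=%d\n",
              x$voxel_count, x$volume_ml, x$cut_plane_z))
  invisible(x)
}

#' Segment the proximal femur from a CT volume
#'
#' Convenience wrapper chaining [region_grow()] (bone band), [fill_interior()]
#' (marrow), [detect_cut_plane()] and [crop_to_voi()].
#'
#' @param volume A [ct_volume()].
#' @param config A [region_grow_config()].
#' @param cut_plane Optional manual 0-based cut-plane index.
#' @param prominence Passed to [detect_cut_plane()].
#' @return A `proximal_femur_voi`.
#' @export
segment_proximal_femur <- function(volume, config, cut_plane = NULL,
                                   prominence = 2) {
  filled <- fill_interior(region_grow(volume, config))
  cut <- detect_cut_plane(filled, prominence = prominence, override = cut_plane)
  crop_to_voi(filled, cut)
}
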