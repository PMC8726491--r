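# HU-histogram analysis (HUHA) and ROI/VOI measurement. The histogram bands
# are fixed at the published edges: fat < 0 HU, bone >= 126 HU; everything in
# between is the mid band. Percentages are retained at full precision
# internally and rounded to one decimal only in written reports.

#' HU histogram summary of a set of attenuation values
#'
#' @param values Nonempty numeric vector of finite HU values.
#' @return An object of class `huha_result`: `huha_fat` (% of values
#'   < 0 HU), `huha_bone` (% of values >= 126 HU, edge inclusive),
#'   `huha_mid` (remainder, so the three always sum to exactly 100),
#'   `mean_hu`, and `n`.
#' @export
huha_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stopf("`values` must be nonempty")
  if (any(!is.finite(values))) stopf("`values` must be finite HU")
  n <- length(values)
  fat <- 100 * sum(values < 0) / n
  bone <- 100 * sum(values >= 126) / n
  structure(list(huha_fat = fat, huha_bone = bone,
                 huha_mid = 100 - fat - bone,
                 mean_hu = mean(values), n = n),
            class = "huha_result")
}

#' @export
print.huha_result <- function(x, ...) {
  cat(sprintf("HUHA: fat %.1f%%, mid %.1f%%, bone %.1f%%; mean %.1f HU (n=%d)\n",
              x$huha_fat, x$huha_mid, x$huha_bone, x$mean_hu, x$n))
  invisible(x)
}

#' Largest circular ROI inscribed in the bone cross-section
#'
#' Draws the largest circle around a given centre that touches, without
#' crossing, the outer cortical boundary: the radius is the distance from the
#' centre to the nearest non-femur pixel centre on the plane, and ROI pixels
#' are those whose centres lie strictly within that radius (so cortex up to
#' the outer boundary is included, the touched background pixel is not).
#'
#' @param plane A [reformat_plane()] result with a `bone_mask`.
#' @param center mm offset pair `(u, v)` on the plane; defaults to `(0, 0)`,
#'   the neck centre. Must lie inside the bone mask.
#' @return An object of class `circular_roi`: `center` (mm offsets), `radius`
#'   (mm), `pixel_index` (indices into the plane), `pixel_count`, `area_mm2`.
#' @export
largest_inscribed_circle <- function(plane, center = c(0, 0)) {
  if (!inherits(plane, "reformatted_plane")) stopf("`plane` must be a reformatted_plane")
  if (is.null(plane$bone_mask)) stopf("plane has no bone mask; reformat with `mask =`")
  U <- matrix(plane$u_offsets, length(plane$u_offsets), length(plane$v_offsets))
  V <- matrix(plane$v_offsets, length(plane$u_offsets), length(plane$v_offsets),
              byrow = TRUE)
  d2 <- (U - center[1])^2 + (V - center[2])^2
  ctr_px <- which.min(d2)
  if (!plane$bone_mask[ctr_px]) {
    stopf("ROI centre (%.1f, %.1f) mm is not inside the bone cross-section",
          center[1], center[2])
  }
  bg <- !plane$bone_mask | is.na(plane$values)
  if (!any(bg)) stopf("no background on plane: circle radius is unbounded")
  radius <- sqrt(min(d2[bg]))
  inside <- which(d2 < radius^2 - 1e-9)
  if (!length(inside)) stopf("degenerate ROI: centre lies on the bone boundary")
  structure(list(center = as.numeric(center), radius = radius,
                 pixel_index = inside, pixel_count = length(inside),
                 area_mm2 = length(inside) * prod(plane$pixel_spacing)),
            class = "circular_roi")
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf("<circular_roi> r=%.2f mm, %d px, %.1f mm^2\n",
              x$radius, x$pixel_count, x$area_mm2))
  invisible(x)
}

#' Measure the 3D femur VOI
#'
#' HU histogram analysis over every voxel inside the VOI mask; the record
#' carries the `3D_Femur` prefix and the VOI volume in ml.
#'
#' @param volume A [ct_volume()].
#' @param voi A [crop_to_voi()] result (or a [mask_volume()]).
#' @param subject_id Identifier stored in the record.
#' @return A one-row data.frame (`measurement_record`): `subject_id`,
#'   `prefix`, `huha_fat`, `huha_bone`, `huha_mid`, `mean_hu`, `n`, `size`
#'   (ml for VOIs, mm^2 for ROIs).
#' @export
measure_voi <- function(volume, voi, subject_id = "subject") {
  mask <- if (inherits(voi, "proximal_femur_voi")) voi$mask else voi
  if (!inherits(mask, "mask_volume")) stopf("`voi` must be a proximal_femur_voi or mask_volume")
  if (!same_geometry(volume, mask)) stopf("VOI is not aligned to the volume")
  vals <- volume$values[mask$values]
  if (!length(vals)) stopf("VOI is empty")
  h <- huha_summary(vals)
  measurement_record(subject_id, "3D_Femur", h,
                     size = length(vals) * voxel_ml(volume))
}

#' Measure a circular ROI on a reformatted plane
#'
#' @param plane A [reformat_plane()] result.
#' @param roi A [largest_inscribed_circle()] result.
#' @param subject_id Identifier stored in the record.
#' @return A one-row `measurement_record` data.frame with prefix
#'   `2D_coronal`.
#' @export
measure_roi <- function(plane, roi, subject_id = "subject") {
  if (!inherits(plane, "reformatted_plane")) stopf("`plane` must be a reformatted_plane")
  if (!inherits(roi, "circular_roi")) stopf("`roi` must be a circular_roi")
  vals <- plane$values[roi$pixel_index]
  if (any(is.na(vals))) {
    stopf("ROI overlaps %d invalid (out-of-volume) samples", sum(is.na(vals)))
  }
  h <- huha_summary(vals)
  measurement_record(subject_id, "2D_coronal", h, size = roi$area_mm2)
}

measurement_record <- function(subject_id, prefix, h, size) {
  structure(
    data.frame(subject_id = subject_id, prefix = prefix,
               huha_fat = h$huha_fat, huha_bone = h$huha_bone,
               huha_mid = h$huha_mid, mean_hu = h$mean_hu, n = h$n,
               size = size, stringsAsFactors = FALSE),
    class = c("measurement_record", "data.frame"))
}
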