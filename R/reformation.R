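# Femoral-neck frame estimation and true-coronal multiplanar reformation.
# The "true coronal" plane is the oblique plane containing the neck axis
# (not the scanner coronal); HU is resampled with trilinear interpolation,
# masks with nearest-neighbour.

#' Trilinear / nearest-neighbour sampling of a volume at world points
#'
#' @param vol A [ct_volume()] or [mask_volume()].
#' @param pts n x 3 matrix of LPS mm points.
#' @param method "trilinear" or "nearest".
#' @return Numeric (or logical) vector of length n; `NA` outside the volume.
#' @keywords internal
#' @noRd
sample_volume <- function(vol, pts, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  dims <- dim(vol$values)
  idx <- world_to_voxel(vol, pts)
  ok <- idx[, 1] >= 0 & idx[, 1] <= dims[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= dims[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= dims[3] - 1
  out <- rep(NA_real_, nrow(idx))
  if (!any(ok)) return(out)
  ix <- idx[ok, , drop = FALSE]
  if (method == "nearest") {
    r <- round(ix)
    out[ok] <- vol$values[cbind(r[, 1] + 1, r[, 2] + 1, r[, 3] + 1)]
    return(out)
  }
  i0 <- pmin(floor(ix), rep(dims - 2, each = nrow(ix)))
  i0 <- pmax(i0, 0)
  f <- ix - i0
  g <- function(dx, dy, dz) {
    vol$values[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  }
  w <- function(fi, d) if (d == 1) fi else 1 - fi
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    acc <- acc + g(dx, dy, dz) *
      w(f[, 1], dx) * w(f[, 2], dy) * w(f[, 3], dz)
  }
  out[ok] <- acc
  out
}

#' Estimate the femoral-head centre
#'
#' Centre of the maximal inscribed sphere: the argmax of the interior chamfer
#' distance transform, restricted (when the mask has several connected
#' components) to the most superior component, with a warning.
#'
#' @param mask A nonempty [mask_volume()].
#' @return LPS mm point with attribute `"radius"` (the inscribed-sphere
#'   radius, mm).
#' @export
estimate_head_center <- function(mask) {
  if (!inherits(mask, "mask_volume")) stopf("`mask` must be a mask_volume")
  dims <- dim(mask$values)
  if (!any(mask$values)) stopf("`mask` is empty")
  dt <- .chamfer_dt_cpp(mask$values, dims, mask$spacing)
  lab <- .label_components_cpp(mask$values, dims, 26L)
  ncomp <- max(lab)
  use <- mask$values
  if (ncomp > 1L) {
    warning(sprintf("mask has %d connected components; using the most superior one", ncomp))
    topz <- vapply(seq_len(ncomp), function(l) {
      max(which(apply(lab == l, 3, any)))
    }, numeric(1))
    use <- lab == which.max(topz)
  }
  dtm <- ifelse(use, dt, -Inf)
  i <- which.max(dtm)
  vox <- arrayInd(i, dims) - 1L
  ctr <- drop(voxel_to_world(mask, vox))
  structure(ctr, radius = dt[i])
}

#' Estimate the femoral-neck frame
#'
#' The neck axis starts at the direction from the head centre toward the
#' centroid of the remaining bone (trochanters and shaft) and is refined so
#' that the bone cross-sectional area perpendicular to the axis is minimal at
#' the neck; the neck centre (the "3D central point") is the centroid of that
#' minimal cross-section. The returned frame spans the true-coronal plane:
#' `in_plane_u` is the neck axis, `in_plane_v` completes the plane, and
#' `plane_normal` (as close to the AP direction as the axis allows) completes
#' the right-handed orthonormal triple.
#'
#' @param mask A [mask_volume()] containing head, neck and trochanter.
#' @param head_center Optional head centre (mm); estimated when missing.
#' @param scan_extent In-plane half-extent (mm) of the area-evaluation grid.
#' @param scan_step In-plane sampling step (mm) for area evaluation.
#' @return An object of class `neck_frame`.
#' @export
estimate_neck_frame <- function(mask, head_center = NULL, scan_extent = 32,
                                scan_step = 1.6) {
  if (!inherits(mask, "mask_volume")) stopf("`mask` must be a mask_volume")
  if (is.null(head_center)) head_center <- estimate_head_center(mask)
  r_head <- attr(head_center, "radius")
  if (is.null(r_head)) {
    dt <- .chamfer_dt_cpp(mask$values, dim(mask$values), mask$spacing)
    vox <- round(world_to_voxel(mask, head_center)) + 1
    r_head <- dt[vox[1], vox[2], vox[3]]
  }
  head_center <- as.numeric(head_center)
  vox_idx <- which(mask$values)
  coords <- voxel_to_world(mask, arrayInd(vox_idx, dim(mask$values)) - 1L)
  dist_head <- sqrt(colSums((t(coords) - head_center)^2))
  rest <- coords[dist_head > 1.5 * r_head, , drop = FALSE]
  if (nrow(rest) < 50L) {
    stopf("no bone beyond the head component: cannot estimate a neck axis")
  }
  centroid <- colMeans(rest)
  axis0 <- centroid - head_center
  s_max <- sqrt(sum(axis0^2))
  axis0 <- axis0 / s_max

  off <- seq(-scan_extent, scan_extent, by = scan_step)
  grid <- as.matrix(expand.grid(u = off, v = off))
  px_area <- scan_step^2
  area_at <- function(center, axis) {
    b <- orthobasis(axis)
    pts <- matrix(center, nrow(grid), 3, byrow = TRUE) +
      grid[, 1] %o% b$u + grid[, 2] %o% b$v
    m <- sample_volume(mask, pts, method = "nearest")
    sum(m, na.rm = TRUE) * px_area
  }
  profile_min <- function(axis, s_lo, s_hi, n = 25L) {
    ss <- seq(s_lo, s_hi, length.out = n)
    a <- vapply(ss, function(s) area_at(head_center + s * axis, axis),
                numeric(1))
    list(ss = ss, a = a, i = which.min(a))
  }
  s_lo <- 0.55 * r_head
  s_hi <- min(s_max, s_lo + 4.5 * r_head)
  pr <- profile_min(axis0, s_lo, s_hi)
  i <- pr$i
  flat <- (max(pr$a) - min(pr$a)) <= 0.02 * max(pr$a)
  if (flat) i <- ceiling(length(pr$ss) / 2)  # e.g. a straight cylinder
  if (pr$a[i] <= 0 ||
      (!flat && (i <= 1L || i >= length(pr$ss) ||
                 pr$a[i] > min(pr$a[1], pr$a[length(pr$a)])))) {
    stopf("no interior cross-section area minimum along the head-trochanter direction (no neck found)")
  }
  s_best <- pr$ss[i]
  axis <- axis0
  # refine the axis as the line from the head centre (a reliable on-axis
  # landmark) through the centroid of the waist cross-section, re-locating
  # the waist after each update; the in-plane cutoff keeps distant structures
  # (trochanters, shaft) out of the centroid
  centroid_at <- function(center, axis, r_cut) {
    b <- orthobasis(axis)
    pts <- matrix(center, nrow(grid), 3, byrow = TRUE) +
      grid[, 1] %o% b$u + grid[, 2] %o% b$v
    m <- sample_volume(mask, pts, method = "nearest")
    keep <- which(!is.na(m) & m > 0 & grid[, 1]^2 + grid[, 2]^2 < r_cut^2)
    if (length(keep) < 5) return(NULL)
    center + mean(grid[keep, 1]) * b$u + mean(grid[keep, 2]) * b$v
  }
  for (iter in 1:4) {
    loc <- profile_min(axis, max(s_lo, s_best - 6), min(s_hi, s_best + 6),
                       n = 13L)
    if (loc$a[loc$i] <= 0) break
    s_best <- loc$ss[loc$i]
    r_cut <- 1.4 * sqrt(loc$a[loc$i] / pi)
    cw <- centroid_at(head_center + s_best * axis, axis, r_cut)
    if (is.null(cw)) break
    new_axis <- cw - head_center
    nn <- sqrt(sum(new_axis^2))
    if (nn < 1e-6) break
    axis <- new_axis / nn
  }
  # fine waist localisation: denser in-plane sampling reduces the area
  # quantisation that otherwise blurs the shallow frustum-side ramp
  fine_step <- scan_step / 2
  off_f <- seq(-scan_extent, scan_extent, by = fine_step)
  grid_f <- as.matrix(expand.grid(u = off_f, v = off_f))
  area_fine <- function(center, axis) {
    b <- orthobasis(axis)
    pts <- matrix(center, nrow(grid_f), 3, byrow = TRUE) +
      grid_f[, 1] %o% b$u + grid_f[, 2] %o% b$v
    m <- sample_volume(mask, pts, method = "nearest")
    sum(m, na.rm = TRUE) * fine_step^2
  }
  ss_f <- seq(s_best - 3, s_best + 3, by = 0.5)
  a_f <- vapply(ss_f, function(s) area_fine(head_center + s * axis, axis),
                numeric(1))
  s_best <- ss_f[which.min(a_f)]
  center0 <- head_center + s_best * axis
  b <- orthobasis(axis)
  pts <- matrix(center0, nrow(grid_f), 3, byrow = TRUE) +
    grid_f[, 1] %o% b$u + grid_f[, 2] %o% b$v
  m <- sample_volume(mask, pts, method = "nearest")
  r_cut <- 1.4 * sqrt(max(min(a_f), fine_step^2) / pi)
  inplane <- which(!is.na(m) & m > 0 &
                     grid_f[, 1]^2 + grid_f[, 2]^2 < r_cut^2)
  if (!length(inplane)) stopf("empty cross-section at the detected neck waist")
  neck_center <- center0 + mean(grid_f[inplane, 1]) * b$u +
    mean(grid_f[inplane, 2]) * b$v
  neck_frame(neck_center, axis)
}

# Orthonormal in-plane basis perpendicular to `axis`.
orthobasis <- function(axis) {
  ref <- if (abs(axis[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  u <- cross3(ref, axis); u <- u / sqrt(sum(u^2))
  v <- cross3(axis, u)
  list(u = u, v = v)
}

#' Construct a femoral-neck frame
#'
#' @param neck_center LPS mm point on the neck axis (the 3D central point).
#' @param neck_axis Unit vector along the neck (head toward trochanter).
#' @return A `neck_frame`: `neck_center`, `neck_axis`, `in_plane_u` (the
#'   axis), `in_plane_v`, `plane_normal`; `{in_plane_u, in_plane_v,
#'   plane_normal}` are orthonormal and the plane contains the neck axis.
#' @export
neck_frame <- function(neck_center, neck_axis) {
  neck_axis <- as.numeric(neck_axis)
  n2 <- sqrt(sum(neck_axis^2))
  if (n2 < 1e-12) stopf("`neck_axis` must be nonzero")
  u <- neck_axis / n2
  ap <- c(0, 1, 0)
  nrm <- ap - sum(ap * u) * u
  if (sqrt(sum(nrm^2)) < 1e-6) nrm <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
  nrm <- nrm / sqrt(sum(nrm^2))
  v <- cross3(nrm, u)
  structure(list(neck_center = as.numeric(neck_center), neck_axis = u,
                 in_plane_u = u, in_plane_v = v, plane_normal = nrm),
            class = "neck_frame")
}

#' @export
print.neck_frame <- function(x, ...) {
  cat(sprintf("<neck_frame> center (%.1f, %.1f, %.1f) mm, axis (%.3f, %.3f, %.3f)\n",
              x$neck_center[1], x$neck_center[2], x$neck_center[3],
              x$neck_axis[1], x$neck_axis[2], x$neck_axis[3]))
  invisible(x)
}

#' Resample the true-coronal plane of the neck
#'
#' Each output pixel is sampled at `neck_center + u * in_plane_u + v *
#' in_plane_v` by trilinear interpolation (HU) and nearest-neighbour (bone
#' mask); samples outside the volume are `NA` and excluded from downstream
#' statistics. Offsets are centred so the neck centre lies mid-plane.
#'
#' @param volume A [ct_volume()].
#' @param frame A [neck_frame()].
#' @param extent mm pair, plane size (default 80 x 80 mm).
#' @param pixel_spacing mm pair (default 0.67 x 0.67, the in-plane acquisition
#'   resolution).
#' @param mask Optional [mask_volume()] giving the femur; sampled into
#'   `bone_mask`.
#' @return An object of class `reformatted_plane`: `values` (2D HU grid, NA
#'   outside the volume), `pixel_spacing`, `frame`, `bone_mask`, and the
#'   pixel offset vectors `u_offsets`, `v_offsets` (mm).
#' @export
reformat_plane <- function(volume, frame, extent = c(80, 80),
                           pixel_spacing = c(0.67, 0.67), mask = NULL) {
  if (!inherits(volume, "ct_volume")) stopf("`volume` must be a ct_volume")
  if (!inherits(frame, "neck_frame")) stopf("`frame` must be a neck_frame")
  nu <- max(2L, round(extent[1] / pixel_spacing[1]))
  nv <- max(2L, round(extent[2] / pixel_spacing[2]))
  u_off <- (seq_len(nu) - (nu + 1) / 2) * pixel_spacing[1]
  v_off <- (seq_len(nv) - (nv + 1) / 2) * pixel_spacing[2]
  grid <- as.matrix(expand.grid(u = u_off, v = v_off))
  pts <- matrix(frame$neck_center, nrow(grid), 3, byrow = TRUE) +
    grid[, 1] %o% frame$in_plane_u + grid[, 2] %o% frame$in_plane_v
  hu <- sample_volume(volume, pts, method = "trilinear")
  if (all(is.na(hu))) stopf("reformation plane lies wholly outside the volume")
  bone <- NULL
  if (!is.null(mask)) {
    bm <- sample_volume(mask, pts, method = "nearest")
    bone <- matrix(!is.na(bm) & bm > 0, nu, nv)
  }
  structure(list(values = matrix(hu, nu, nv),
                 pixel_spacing = as.numeric(pixel_spacing),
                 frame = frame, bone_mask = bone,
                 u_offsets = u_off, v_offsets = v_off),
            class = "reformatted_plane")
}

#' @export
print.reformatted_plane <- function(x, ...) {
  cat(sprintf("<reformatted_plane> %dx%d px at %.2fx%.2f mm\n",
              nrow(x$values), ncol(x$values),
              x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}
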