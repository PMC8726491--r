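# Head-centre and neck-frame estimation, and oblique-plane resampling.

test_that("head centre of a digital ball is its centre", {
  m <- ball_mask(c(25, 25, 25), c(12, 12, 12), 8)
  ctr <- estimate_head_center(m)
  expect_lt(sqrt(sum((as.numeric(ctr) - c(12, 12, 12))^2)), 1.01)
  expect_gt(attr(ctr, "radius"), 6)
})

test_that("with two disjoint balls the superior one is used, with a warning", {
  two <- ball_mask(c(20, 20, 40), c(9, 9, 8), 5)$values |
    ball_mask(c(20, 20, 40), c(9, 9, 30), 6)$values
  m <- mask_volume(two, spacing = c(1, 1, 1))
  expect_warning(ctr <- estimate_head_center(m), "components")
  expect_lt(sqrt(sum((as.numeric(ctr) - c(9, 9, 30))^2)), 1.5)
})

test_that("phantom head centre is recovered within 2 mm", {
  ph <- test_phantom()
  ctr <- estimate_head_center(ph$truth$femur_mask)
  expect_lt(sqrt(sum((as.numeric(ctr) - ph$truth$head_center)^2)), 2)
})

test_that("neck frame recovery on the phantom meets the geometric tolerances", {
  ph <- test_phantom()
  voi <- segment_proximal_femur(ph$volume,
    region_grow_config(femhu:::auto_seed_point(ph$volume)))
  fr <- estimate_neck_frame(voi$mask)
  ang <- acos(min(1, abs(sum(fr$neck_axis * ph$truth$neck_axis)))) * 180 / pi
  expect_lt(ang, 5)
  expect_lt(sqrt(sum((fr$neck_center - ph$truth$neck_center)^2)), 3)
})

test_that("a straight cylinder's axis is recovered within a degree", {
  dims <- c(30, 30, 60)
  cyl <- array(FALSE, dims)
  x <- (seq_len(30) - 1); y <- x
  for (k in 1:60) cyl[, , k] <- outer((x - 14.5)^2, (y - 14.5)^2, "+") <= 8^2
  m <- mask_volume(cyl, spacing = c(1, 1, 1))
  hc <- structure(c(14.5, 14.5, 5), radius = 8)
  fr <- estimate_neck_frame(m, head_center = hc)
  ang <- acos(min(1, abs(fr$neck_axis[3]))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("a bare sphere has no neck and raises an error", {
  m <- ball_mask(c(30, 30, 30), c(14, 14, 14), 9)
  expect_error(estimate_neck_frame(m), "neck")
})

test_that("returned frames are orthonormal and contain the neck axis", {
  fr <- neck_frame(c(1, 2, 3), c(2, 0, 1))
  B <- cbind(fr$in_plane_u, fr$in_plane_v, fr$plane_normal)
  expect_lt(max(abs(crossprod(B) - diag(3))), 1e-9)
  expect_equal(fr$in_plane_u, fr$neck_axis)
})

test_that("reformation reproduces constant and affine fields exactly", {
  vol <- ct_volume(array(77, c(20, 20, 20)), spacing = c(1, 1, 1))
  fr <- neck_frame(c(9, 9, 9), c(1, 1, 0.5))
  pl <- reformat_plane(vol, fr, extent = c(10, 10), pixel_spacing = c(1, 1))
  expect_true(all(abs(pl$values[!is.na(pl$values)] - 77) < 1e-9))
  # trilinear interpolation is exact on affine fields
  dims <- c(20, 20, 20)
  lin <- array(0, dims)
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    lin[i, j, k] <- 2 * (i - 1) + 3 * (j - 1) - 1.5 * (k - 1) + 10
  }
  vol2 <- ct_volume(lin, spacing = c(1, 1, 1))
  pl2 <- reformat_plane(vol2, fr, extent = c(8, 8), pixel_spacing = c(0.5, 0.5))
  U <- matrix(pl2$u_offsets, length(pl2$u_offsets), length(pl2$v_offsets))
  V <- matrix(pl2$v_offsets, length(pl2$u_offsets), length(pl2$v_offsets),
              byrow = TRUE)
  px <- fr$neck_center[1] + U * fr$in_plane_u[1] + V * fr$in_plane_v[1]
  py <- fr$neck_center[2] + U * fr$in_plane_u[2] + V * fr$in_plane_v[2]
  pz <- fr$neck_center[3] + U * fr$in_plane_u[3] + V * fr$in_plane_v[3]
  want <- 2 * px + 3 * py - 1.5 * pz + 10
  expect_equal(pl2$values, want, tolerance = 1e-10)
})

test_that("an axis-aligned frame reproduces the native slice", {
  set.seed(4)
  vals <- array(round(runif(16^3, -100, 900)), c(16, 16, 16))
  vol <- ct_volume(vals, spacing = c(1, 1, 1))
  fr <- neck_frame(c(7.5, 8, 7.5), c(0, 0, 1))  # axis = z, plane = x-z
  pl <- reformat_plane(vol, fr, extent = c(16, 16), pixel_spacing = c(1, 1))
  # in_plane_u = z axis, in_plane_v completes: sample points have integer
  # coordinates, so trilinear equals the stored voxels of the y = 8 plane
  expect_true(all(!is.na(pl$values)))
  expect_true(all(pl$values %in% vals[, 9, ]))
})

test_that("resampling is invariant under a rigid motion of volume and points", {
  set.seed(5)
  vals <- array(runif(18^3, 0, 1000), c(18, 18, 18))
  vol <- ct_volume(vals, spacing = c(1, 1, 1))
  pts <- cbind(runif(60, 2, 15), runif(60, 2, 15), runif(60, 2, 15))
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(5, -2, 3)
  vol_r <- ct_volume(vals, spacing = c(1, 1, 1), origin = shift,
                     orientation = R)
  pts_r <- t(R %*% t(pts)) + matrix(shift, nrow(pts), 3, byrow = TRUE)
  a <- femhu:::sample_volume(vol, pts, method = "trilinear")
  b <- femhu:::sample_volume(vol_r, pts_r, method = "trilinear")
  expect_equal(a, b, tolerance = 1e-10)
})
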