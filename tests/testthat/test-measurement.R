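# HU histogram analysis and ROI/VOI measurement.

test_that("huha_summary matches hand-enumerated band fractions", {
  h <- huha_summary(c(-50, -1, 0, 126, 200))
  expect_equal(h$huha_fat, 40)
  expect_equal(h$huha_bone, 40)
  expect_equal(h$huha_mid, 20)
  expect_equal(h$mean_hu, 55)
  expect_equal(h$n, 5)
})

test_that("huha band edges are half-open at 0 and closed at 126", {
  z <- huha_summary(rep(0, 10))
  expect_equal(z$huha_fat, 0)   # 0 is not < 0
  expect_equal(z$huha_bone, 0)  # 0 < 126
  expect_equal(z$mean_hu, 0)
  b <- huha_summary(rep(126, 7))
  expect_equal(b$huha_bone, 100)  # 126 is included in the bone band
  expect_error(huha_summary(numeric(0)), "nonempty")
  expect_error(huha_summary(c(1, NA)), "finite")
})

test_that("huha percentages always sum to exactly 100 and are permutation-invariant", {
  set.seed(6)
  for (rep in 1:25) {
    v <- runif(sample(1:200, 1), -1000, 2000)
    h <- huha_summary(v)
    expect_identical(h$huha_fat + h$huha_mid + h$huha_bone, 100)
    hp <- huha_summary(sample(v))
    expect_equal(hp[c("huha_fat", "huha_bone", "mean_hu")],
                 h[c("huha_fat", "huha_bone", "mean_hu")])
  }
  # monotone response: a large positive shift drives everything into the bone band
  v <- rnorm(50, 0, 30)
  expect_equal(huha_summary(v + 1500)$huha_bone, 100)
})

test_that("largest inscribed circle matches the geometry of simple masks", {
  n <- 41
  U <- matrix(seq_len(n) - 21, n, n)
  V <- t(U)
  disk <- U^2 + V^2 <= 15^2
  pl <- make_plane(matrix(200, n, n), disk)
  roi <- largest_inscribed_circle(pl, c(0, 0))
  expect_lt(abs(roi$radius - 15), 1.01)
  expect_equal(roi$area_mm2, roi$pixel_count * 1)
  # annulus: the ROI reaches the outer ring and includes it
  ring <- disk & !(U^2 + V^2 <= 10^2)
  vals <- matrix(-100, n, n); vals[ring] <- 1500
  pl2 <- make_plane(vals, disk)
  roi2 <- largest_inscribed_circle(pl2, c(0, 0))
  expect_gt(roi2$radius, 14)
  expect_gt(huha_summary(vals[roi2$pixel_index])$huha_bone, 0)
  # centre one pixel from background
  roi3 <- largest_inscribed_circle(pl, c(14, 0))
  expect_lt(roi3$radius, 2.5)
  # centre outside the bone is an error
  expect_error(largest_inscribed_circle(pl, c(20, 0)), "not inside")
})

test_that("largest inscribed circle agrees with an exhaustive radius oracle", {
  set.seed(7)
  for (rep in 1:30) {
    n <- 25
    m <- matrix(FALSE, n, n)
    # random blob: union of a few disks
    for (b in 1:3) {
      cx <- runif(1, 8, 18); cy <- runif(1, 8, 18); r <- runif(1, 3, 7)
      U <- matrix(seq_len(n) - 13, n, n); V <- t(U)
      m <- m | ((U - (cx - 13))^2 + (V - (cy - 13))^2 <= r^2)
    }
    m[1, ] <- m[n, ] <- m[, 1] <- m[, n] <- FALSE
    pl <- make_plane(matrix(0, n, n), m)
    ctr_idx <- which(m, arr.ind = TRUE)[1, ]
    ctr <- c(ctr_idx[1] - 13, ctr_idx[2] - 13)
    roi <- largest_inscribed_circle(pl, ctr)
    # oracle: brute-force distance to every background pixel centre
    bg <- which(!m, arr.ind = TRUE)
    d <- sqrt((bg[, 1] - 13 - ctr[1])^2 + (bg[, 2] - 13 - ctr[2])^2)
    expect_equal(roi$radius, min(d), tolerance = 1e-12)
  }
})

test_that("VOI measurement on a noise-free phantom equals planted fractions", {
  ph <- test_phantom(noise_sd = 0)
  truth_voi <- ph$truth$femur_mask
  truth_voi$values[, , seq_len(ph$truth$cut_plane_z)] <- FALSE
  rec <- measure_voi(ph$volume, truth_voi, subject_id = "t")
  labs <- ph$truth$labels
  labs[, , seq_len(ph$truth$cut_plane_z)] <- -1L
  n_tot <- sum(labs > 0L)
  expect_identical(rec$huha_fat, 100 * sum(labs == 4L) / n_tot)
  expect_identical(rec$huha_bone, 100 * sum(labs %in% c(1L, 2L)) / n_tot)
  expect_equal(rec$n, n_tot)
})

test_that("single-voxel VOI and determinism of repeated measurement", {
  vals <- array(100, c(4, 4, 4)); vals[2, 2, 2] <- -10
  vol <- ct_volume(vals, spacing = c(1, 1, 1))
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  rec <- measure_voi(vol, mask_volume(m, geometry = vol))
  expect_equal(rec$huha_fat, 100)
  expect_equal(rec$mean_hu, -10)
  ph <- test_phantom()
  r1 <- measure_subject(ph$volume, "d")
  r2 <- measure_subject(ph$volume, "d")
  expect_identical(r1, r2)
})

test_that("ROI measurement handles constant, mixed and invalid planes", {
  n <- 31
  U <- matrix(seq_len(n) - 16, n, n); V <- t(U)
  disk <- U^2 + V^2 <= 12^2
  pl <- make_plane(matrix(200, n, n), disk)
  roi <- largest_inscribed_circle(pl, c(0, 0))
  rec <- measure_roi(pl, roi)
  expect_equal(rec$huha_bone, 100)
  expect_equal(rec$mean_hu, 200)
  expect_equal(rec$prefix, "2D_coronal")
  # half-disk -100 / half 300 (even grid, so no pixels on the split line):
  # fat and bone each cover half within one pixel-count quantum
  ne <- 30
  Ue <- matrix(seq_len(ne) - 15.5, ne, ne); Ve <- t(Ue)
  diske <- Ue^2 + Ve^2 <= 12^2
  vals <- matrix(-100, ne, ne); vals[Ue > 0] <- 300
  pl2 <- make_plane(vals, diske)
  rec2 <- measure_roi(pl2, largest_inscribed_circle(pl2, c(0, 0)))
  quantum <- 100 / rec2$n
  expect_lt(abs(rec2$huha_fat - 50), quantum + 1e-9)
  expect_lt(abs(rec2$huha_bone - 50), quantum + 1e-9)
  # NA samples under the ROI are an error
  vals3 <- matrix(150, n, n); vals3[16, 16] <- NA
  pl3 <- make_plane(vals3, disk)
  expect_error(measure_roi(pl3, roi), "invalid")
})
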