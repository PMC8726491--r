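# Region growing, hole filling and the lesser-trochanter cut.

test_that("region growing handles degenerate neighbourhoods", {
  vals <- array(-500, c(5, 5, 5))
  vals[3, 3, 3] <- 500
  vol <- ct_volume(vals, spacing = c(1, 1, 1))
  m <- region_grow(vol, region_grow_config(c(2, 2, 2), 126, 3071))
  expect_equal(sum(m$values), 1)
  expect_true(m$values[3, 3, 3])
  # uniform in-range volume grows to the full grid
  uni <- ct_volume(array(200, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_true(all(region_grow(uni, region_grow_config(c(0, 0, 0)))$values))
  # seed outside the band is an explicit error, not an empty mask
  expect_error(region_grow(vol, region_grow_config(c(0, 0, 0))),
               "outside growing band")
  expect_error(region_grow(vol, region_grow_config(c(9, 9, 9))),
               "outside the grid")
})

test_that("region growing equals the breadth-first flood-fill oracle", {
  set.seed(11)
  for (rep in 1:20) {
    conn <- if (rep %% 2) 26 else 6
    vals <- array(sample(c(-200, 400), 20^3, replace = TRUE,
                         prob = c(0.45, 0.55)), c(20, 20, 20))
    seeds <- which(vals >= 126, arr.ind = TRUE)
    s <- seeds[sample(nrow(seeds), 1), ] - 1L
    vol <- ct_volume(vals, spacing = c(1, 1, 1))
    got <- region_grow(vol, region_grow_config(s, connectivity = conn))
    want <- bfs_flood_fill(vals, s, 126, 3071, connectivity = conn)
    expect_identical(got$values, want)
  }
})

test_that("fill_interior fills cavities, is idempotent and monotone", {
  shell <- ball_mask(c(21, 21, 21), c(10, 10, 10), 8)$values &
    !ball_mask(c(21, 21, 21), c(10, 10, 10), 5.5)$values
  m <- mask_volume(shell, spacing = c(1, 1, 1))
  filled <- fill_interior(m)
  expect_identical(filled$values, ball_mask(c(21, 21, 21), c(10, 10, 10), 8)$values)
  # idempotent
  expect_identical(fill_interior(filled)$values, filled$values)
  # already-solid mask unchanged
  solid <- ball_mask(c(15, 15, 15), c(7, 7, 7), 5)
  expect_identical(fill_interior(solid)$values, solid$values)
  # monotone (superset) on random masks
  set.seed(3)
  for (rep in 1:10) {
    r <- mask_volume(array(runif(12^3) < 0.35, c(12, 12, 12)),
                     spacing = c(1, 1, 1))
    if (!any(r$values)) next
    f <- fill_interior(r)
    expect_true(all(f$values[r$values]))
  }
})

test_that("a perforated shell fills only if the hole is sealed", {
  shell <- ball_mask(c(21, 21, 21), c(10, 10, 10), 8)$values &
    !ball_mask(c(21, 21, 21), c(10, 10, 10), 5.5)$values
  hole <- shell
  hole[11, 11, 17:21] <- FALSE   # bore a channel to the boundary
  perforated <- mask_volume(hole, spacing = c(1, 1, 1))
  f <- fill_interior(perforated)
  expect_false(f$values[11, 11, 11])   # cavity connected to outside: unfilled
})

test_that("the cut plane is found near the true lesser-trochanter margin", {
  ph <- test_phantom()
  voi_mask <- fill_interior(region_grow(ph$volume,
    region_grow_config(femhu:::auto_seed_point(ph$volume))))
  z <- detect_cut_plane(voi_mask)
  expect_lte(abs(z - ph$truth$cut_plane_z), 2)
  # override returned verbatim
  expect_identical(detect_cut_plane(voi_mask, override = 17L), 17L)
  # a featureless cylinder has no prominence
  cyl <- array(FALSE, c(20, 20, 40))
  cyl[6:14, 6:14, ] <- TRUE
  expect_error(detect_cut_plane(mask_volume(cyl, spacing = c(1, 1, 1))),
               "prominence")
})

test_that("crop_to_voi removes inferior slices and recomputes volume", {
  m <- array(FALSE, c(8, 8, 10))
  m[3:5, 3:5, ] <- TRUE                 # 9 voxels on each of 10 slices
  mv <- mask_volume(m, spacing = c(1, 1, 2))
  voi <- crop_to_voi(mv, 5)
  expect_equal(voi$voxel_count, 9 * 5)
  expect_equal(voi$volume_ml, 9 * 5 * 2 / 1000)
  expect_true(all(which(apply(voi$mask$values, 3, any)) >= 6))
  # cut below the whole mask leaves it unchanged
  expect_equal(crop_to_voi(mv, 0)$voxel_count, 90)
  # cut above the whole mask empties the VOI
  m2 <- array(FALSE, c(8, 8, 10)); m2[3, 3, 1:3] <- TRUE
  expect_error(crop_to_voi(mask_volume(m2, spacing = c(1, 1, 1)), 8), "empty")
  expect_error(crop_to_voi(mv, 99), "outside grid")
})

test_that("segmentation recovers the phantom femur almost exactly", {
  ph <- test_phantom(noise_sd = 12)
  voi <- segment_proximal_femur(ph$volume,
    region_grow_config(femhu:::auto_seed_point(ph$volume)))
  truth_voi <- ph$truth$femur_mask$values
  truth_voi[, , seq_len(ph$truth$cut_plane_z)] <- FALSE
  got <- voi$mask$values
  recovered <- sum(got & truth_voi) / sum(truth_voi)
  false_frac <- sum(got & !truth_voi) / sum(got)
  expect_gte(recovered, 0.99)
  expect_lte(false_frac, 0.01)
})
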