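# Digital proximal-femur phantom. The femur is a union of analytic solids
# (spherical head, tapering frustum neck at a configurable neck-shaft angle,
# cylindrical shaft, ellipsoidal greater/lesser trochanter bosses) with a
# cortical shell and a marrow-space interior rendered as a per-voxel
# categorical mixture of trabecular bone, red marrow and fat. All landmarks
# have closed-form ground truth.

#' Phantom geometry and tissue specification
#'
#' Lengths in mm, attenuation in HU. The default voxel grid (0.67 x 0.67 x
#' 1 mm) matches thin-slice abdominal-pelvic CT reconstructions. HU bands
#' must satisfy `hu_fat < 0 <= hu_red_marrow < 126 <= hu_cortical`, the band
#' edges used by the HU-histogram analysis. The geometry must fit strictly
#' inside the grid.
#'
#' @param voxel_spacing mm triple.
#' @param grid_shape Voxel triple.
#' @param head_radius,neck_radius,neck_length,shaft_radius,cortical_thickness
#'   Femur geometry, mm. `neck_radius` is the frustum radius at the head end;
#'   the base radius equals `shaft_radius`.
#' @param neck_shaft_angle Degrees between shaft axis and neck axis.
#' @param lesser_trochanter_offset mm from the neck-shaft junction down the
#'   shaft to the lesser-trochanter centre.
#' @param trochanter_semiaxes Semi-axes (medial, AP, SI) of the
#'   lesser-trochanter ellipsoid, mm.
#' @param hu_cortical,hu_trabecular_ref,hu_red_marrow,hu_fat,hu_soft_tissue
#'   Tissue attenuations, HU.
#' @param noise_sd Additive Gaussian noise SD, HU (>= 0).
#' @param side `"left"` (default; the study side) or `"right"`.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_spacing = c(0.67, 0.67, 1.0),
                         grid_shape = c(120L, 80L, 96L),
                         head_radius = 20, neck_radius = 12,
                         neck_length = 33, shaft_radius = 13.5,
                         cortical_thickness = 2, neck_shaft_angle = 130,
                         lesser_trochanter_offset = 15,
                         trochanter_semiaxes = c(9, 7, 8),
                         hu_cortical = 1200, hu_trabecular_ref = 300,
                         hu_red_marrow = 50, hu_fat = -80,
                         hu_soft_tissue = 30, noise_sd = 12,
                         side = c("left", "right")) {
  side <- match.arg(side)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0)) {
    stopf("`voxel_spacing` must be three positive numbers")
  }
  if (length(grid_shape) != 3L || any(grid_shape < 8)) {
    stopf("`grid_shape` must be three voxel counts >= 8")
  }
  if (!(hu_fat < 0 && hu_red_marrow >= 0 && hu_red_marrow < 126 &&
        hu_cortical >= 126)) {
    stopf("invalid HU ordering: need hu_fat < 0 <= hu_red_marrow < 126 <= hu_cortical")
  }
  if (hu_trabecular_ref < 126) stopf("`hu_trabecular_ref` must be >= 126 (bone band)")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (cortical_thickness <= 0 || cortical_thickness >= neck_radius) {
    stopf("`cortical_thickness` must be in (0, neck_radius)")
  }
  if (neck_shaft_angle <= 90 || neck_shaft_angle >= 180) {
    stopf("`neck_shaft_angle` must be in (90, 180) degrees")
  }
  spec <- structure(
    list(voxel_spacing = as.numeric(voxel_spacing),
         grid_shape = as.integer(grid_shape),
         head_radius = head_radius, neck_radius = neck_radius,
         neck_length = neck_length, shaft_radius = shaft_radius,
         cortical_thickness = cortical_thickness,
         neck_shaft_angle = neck_shaft_angle,
         lesser_trochanter_offset = lesser_trochanter_offset,
         trochanter_semiaxes = as.numeric(trochanter_semiaxes),
         hu_cortical = hu_cortical, hu_trabecular_ref = hu_trabecular_ref,
         hu_red_marrow = hu_red_marrow, hu_fat = hu_fat,
         hu_soft_tissue = hu_soft_tissue, noise_sd = noise_sd, side = side),
    class = "phantom_spec")
  geo <- phantom_geometry(spec)
  ext <- spec$voxel_spacing * (spec$grid_shape - 1)
  reach <- geo$reach
  if (any(reach$lo <= 0.5) || any(reach$hi >= ext - 0.5)) {
    stopf("femur geometry does not fit strictly inside the grid (extent %s mm, needs [%s] to [%s])",
          paste(round(ext, 1), collapse = " x "),
          paste(round(reach$lo, 1), collapse = ", "),
          paste(round(reach$hi, 1), collapse = ", "))
  }
  spec
}

# Closed-form landmark geometry shared by the renderer and ground truth.
phantom_geometry <- function(spec) {
  ext <- spec$voxel_spacing * (spec$grid_shape - 1)
  m <- if (spec$side == "left") c(-1, 0, 0) else c(1, 0, 0)  # medial
  theta <- (180 - spec$neck_shaft_angle) * pi / 180           # from vertical
  d <- m * sin(theta) + c(0, 0, cos(theta))                   # neck direction
  shaft_bottom <- 6
  # head top needs head_radius + margin above the junction
  z_junction <- ext[3] - (spec$neck_length * cos(theta) + spec$head_radius + 4)
  shaft_x <- ext[1] / 2 - m[1] * 14
  yc <- ext[2] / 2
  J <- c(shaft_x, yc, z_junction)
  H <- J + spec$neck_length * d
  lt_center <- J + m * spec$shaft_radius -
    c(0, 0, spec$lesser_trochanter_offset)
  gt_center <- J - m * spec$shaft_radius + c(0, 0, 6)
  gt_semi <- spec$trochanter_semiaxes * c(0.9, 1.15, 1.3)
  # neck waist: radius of the frustum/head union perpendicular to the axis
  runion <- function(s) {
    rf <- spec$shaft_radius +
      (spec$neck_radius - spec$shaft_radius) * s / spec$neck_length
    ds <- spec$neck_length - s
    rs <- if (abs(ds) < spec$head_radius) sqrt(spec$head_radius^2 - ds^2) else 0
    max(rf, rs)
  }
  ss <- seq(2, spec$neck_length - 2, by = 0.05)
  waist_s <- ss[which.min(vapply(ss, runion, numeric(1)))]
  neck_center <- J + waist_s * d
  lo <- pmin(H - spec$head_radius,
             c(shaft_x - spec$shaft_radius, yc - spec$shaft_radius, shaft_bottom),
             lt_center - spec$trochanter_semiaxes,
             gt_center - gt_semi)
  hi <- pmax(H + spec$head_radius,
             c(shaft_x + spec$shaft_radius, yc + spec$shaft_radius, z_junction),
             lt_center + spec$trochanter_semiaxes,
             gt_center + gt_semi)
  list(medial = m, neck_dir = d, J = J, H = H, shaft_x = shaft_x, yc = yc,
       shaft_bottom = shaft_bottom, z_junction = z_junction,
       lt_center = lt_center, gt_center = gt_center, gt_semi = gt_semi,
       waist_s = waist_s, neck_center = neck_center,
       reach = list(lo = lo, hi = hi))
}

#' Render a proximal-femur CT phantom
#'
#' Produces a [ct_volume()] containing a soft-tissue background, a cortical
#' shell and a marrow-space interior whose per-voxel tissue category
#' (trabecular bone / red marrow / fat) is drawn with probabilities set by
#' the subject's `marrow_fat_fraction` and `trabecular_hu_mean` (the
#' trabecular-bone probability is solved so the expected interior mean equals
#' `trabecular_hu_mean`, clipped to the achievable range). Additive Gaussian
#' noise with `spec$noise_sd` is applied everywhere. The same
#' `(profile, spec, seed)` triple reproduces the volume bit-identically.
#'
#' @param profile One row of a [sample_cohort()] data.frame (or a list with
#'   `marrow_fat_fraction` and `trabecular_hu_mean`).
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return A list of class `femur_phantom` with elements `volume`
#'   ([ct_volume()]) and `truth`: `femur_mask` ([mask_volume()]), `labels`
#'   (integer array: 0 background, 1 cortical, 2 trabecular, 3 red marrow,
#'   4 fat), `cut_plane_z` (0-based slice index of the inferior
#'   lesser-trochanter margin), `head_center`, `neck_center` (mm, LPS),
#'   `neck_axis` (unit vector pointing from the head toward the trochanter).
#' @export
render_phantom <- function(profile, spec = phantom_spec(), seed = 1L) {
  if (!inherits(spec, "phantom_spec")) stopf("`spec` must be phantom_spec()")
  p_fat <- profile$marrow_fat_fraction
  hu_target <- profile$trabecular_hu_mean
  if (is.null(p_fat) || is.null(hu_target) || !is.finite(p_fat) ||
      p_fat < 0 || p_fat > 1) {
    stopf("`profile` must carry marrow_fat_fraction in [0,1] and trabecular_hu_mean")
  }
  geo <- phantom_geometry(spec)
  gs <- spec$grid_shape
  sp <- spec$voxel_spacing
  x <- (seq_len(gs[1]) - 1) * sp[1]
  y <- (seq_len(gs[2]) - 1) * sp[2]
  z <- (seq_len(gs[3]) - 1) * sp[3]
  X <- array(rep(x, times = gs[2] * gs[3]), dim = gs)
  Y <- array(rep(rep(y, each = gs[1]), times = gs[3]), dim = gs)
  Z <- array(rep(z, each = gs[1] * gs[2]), dim = gs)

  sphere <- function(center, r) {
    (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= r^2
  }
  ellipsoid <- function(center, semi) {
    ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
      ((Z - center[3]) / semi[3])^2 <= 1
  }
  cylinder <- function(r, z0, z1) {
    (X - geo$shaft_x)^2 + (Y - geo$yc)^2 <= r^2 & Z >= z0 & Z <= z1
  }
  frustum <- function(shrink, t_min = 0) {
    dx <- X - geo$J[1]; dy <- Y - geo$J[2]; dz <- Z - geo$J[3]
    t <- dx * geo$neck_dir[1] + dy * geo$neck_dir[2] + dz * geo$neck_dir[3]
    r_at <- spec$shaft_radius +
      (spec$neck_radius - spec$shaft_radius) * t / spec$neck_length - shrink
    rho2 <- pmax(dx^2 + dy^2 + dz^2 - t^2, 0)
    t >= t_min & t <= spec$neck_length & rho2 <= r_at^2
  }

  tc <- spec$cortical_thickness
  lt_outer <- ellipsoid(geo$lt_center, spec$trochanter_semiaxes)
  shaft_outer <- cylinder(spec$shaft_radius, geo$shaft_bottom, geo$z_junction)
  outer <- sphere(geo$H, spec$head_radius) | frustum(0) | shaft_outer |
    lt_outer | ellipsoid(geo$gt_center, geo$gt_semi)
  # the inner cylinder is capped at both ends so the marrow canal is sealed
  # by cortex except where another interior solid (neck, trochanter) opens it
  inner <- sphere(geo$H, spec$head_radius - tc) | frustum(tc, t_min = tc) |
    cylinder(spec$shaft_radius - tc, geo$shaft_bottom + tc,
             geo$z_junction - tc) |
    ellipsoid(geo$lt_center, spec$trochanter_semiaxes - tc) |
    ellipsoid(geo$gt_center, geo$gt_semi - tc)
  inner <- inner & outer
  cortex <- outer & !inner

  # trabecular probability solving the interior mean, clipped to feasibility
  hu <- c(spec$hu_fat, spec$hu_trabecular_ref, spec$hu_red_marrow)
  p_trab <- (hu_target - p_fat * hu[1] - (1 - p_fat) * hu[3]) /
    (hu[2] - hu[3])
  p_trab <- min(max(p_trab, 0), 1 - p_fat)

  labels <- array(0L, dim = gs)
  labels[cortex] <- 1L
  idx_in <- which(inner)
  values <- array(spec$hu_soft_tissue, dim = gs)
  values[cortex] <- spec$hu_cortical
  with_seed(seed, {
    u <- stats::runif(length(idx_in))
    cat_in <- ifelse(u < p_fat, 4L, ifelse(u < p_fat + p_trab, 2L, 3L))
    labels[idx_in] <- cat_in
    values[idx_in] <- c(spec$hu_fat, spec$hu_trabecular_ref,
                        spec$hu_red_marrow)[match(cat_in, c(4L, 2L, 3L))]
    if (spec$noise_sd > 0) {
      values <- values + stats::rnorm(length(values), 0, spec$noise_sd)
    }
  })
  values <- pmin(pmax(values, -1024), 3071)
  values <- array(values, dim = gs)

  vol <- ct_volume(values, spacing = sp)
  femur_mask <- mask_volume(outer, geometry = vol)
  # inferior lesser-trochanter margin: most inferior slice in which the boss
  # protrudes beyond the shaft
  boss <- lt_outer & !shaft_outer
  boss_z <- which(apply(boss, 3, any))
  cut_plane_z <- if (length(boss_z)) min(boss_z) - 1L else NA_integer_
  truth <- list(
    femur_mask = femur_mask,
    labels = labels,
    cut_plane_z = cut_plane_z,
    head_center = geo$H,
    neck_center = geo$neck_center,
    neck_axis = -geo$neck_dir,
    composition = c(p_fat = p_fat, p_trab = p_trab,
                    p_marrow = 1 - p_fat - p_trab)
  )
  structure(list(volume = vol, truth = truth, spec = spec), class = "femur_phantom")
}

#' @export
print.femur_phantom <- function(x, ...) {
  cat(sprintf("<femur_phantom> grid %s, cut plane z=%d, %d femur voxels\n",
              paste(dim(x$volume$values), collapse = "x"),
              x$truth$cut_plane_z, sum(x$truth$femur_mask$values)))
  invisible(x)
}
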