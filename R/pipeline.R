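# End-to-end orchestration: simulate -> segment -> reformat -> measure ->
# report, plus the two-observer reliability experiment. All randomness flows
# from one root seed through per-subject / per-stage derived streams, so a
# run is reproducible bit-for-bit from its configuration.

#' Pipeline run configuration
#'
#' @param n_osteo,n_non Cohort sizes (defaults: the emulated study, 96 / 334).
#' @param cohort A [cohort_params()].
#' @param coupling A [tissue_coupling()].
#' @param spec A [phantom_spec()] (base geometry before per-subject scaling).
#' @param anatomy_sd SD of the per-subject anatomical scale factor applied to
#'   the phantom geometry (0 disables anatomical variation).
#' @param seed_jitter Observer seed-point jitter, voxels (integer, per axis).
#' @param roi_jitter Observer ROI-centre jitter, mm (in-plane, per axis).
#' @param cut_jitter Observer cut-plane jitter, slices.
#' @param plane_extent,plane_spacing Reformation plane size / pixel size, mm.
#' @param prominence Lesser-trochanter detection prominence, mm.
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_osteo = 96, n_non = 334, cohort = cohort_params(),
                       coupling = tissue_coupling(), spec = phantom_spec(),
                       anatomy_sd = 0.04, seed_jitter = 2, roi_jitter = 2,
                       cut_jitter = 1, plane_extent = c(80, 80),
                       plane_spacing = c(0.67, 0.67), prominence = 2,
                       seed = 1L) {
  if (anatomy_sd < 0 || seed_jitter < 0 || roi_jitter < 0 || cut_jitter < 0) {
    stopf("jitter magnitudes and `anatomy_sd` must be >= 0")
  }
  structure(list(n_osteo = n_osteo, n_non = n_non, cohort = cohort,
                 coupling = coupling, spec = spec, anatomy_sd = anatomy_sd,
                 seed_jitter = seed_jitter, roi_jitter = roi_jitter,
                 cut_jitter = cut_jitter, plane_extent = plane_extent,
                 plane_spacing = plane_spacing, prominence = prominence,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Scale the phantom geometry by a per-subject anatomical factor.
scale_phantom_spec <- function(spec, factor) {
  phantom_spec(
    voxel_spacing = spec$voxel_spacing, grid_shape = spec$grid_shape,
    head_radius = spec$head_radius * factor,
    neck_radius = spec$neck_radius * factor,
    neck_length = spec$neck_length * factor,
    shaft_radius = spec$shaft_radius * factor,
    cortical_thickness = spec$cortical_thickness,
    neck_shaft_angle = spec$neck_shaft_angle,
    lesser_trochanter_offset = spec$lesser_trochanter_offset * factor,
    trochanter_semiaxes = spec$trochanter_semiaxes * factor,
    hu_cortical = spec$hu_cortical,
    hu_trabecular_ref = spec$hu_trabecular_ref,
    hu_red_marrow = spec$hu_red_marrow, hu_fat = spec$hu_fat,
    hu_soft_tissue = spec$hu_soft_tissue, noise_sd = spec$noise_sd,
    side = spec$side)
}

# Default automatic seed point: the brightest voxel (deep cortical bone).
auto_seed_point <- function(volume) {
  arrayInd(which.max(volume$values), dim(volume$values)) - 1L
}

#' Measure one CT volume with both the 3D VOI and the 2D coronal ROI
#'
#' Runs the full measurement chain on a volume: bone-band region growing from
#' `seed_point` (default: the brightest voxel), interior filling,
#' lesser-trochanter cut, 3D VOI measurement; then neck-frame estimation,
#' true-coronal reformation, largest inscribed circle at the neck centre
#' (plus `roi_offset`), 2D ROI measurement.
#'
#' @param volume A [ct_volume()].
#' @param subject_id Identifier for the records.
#' @param seed_point Optional region-growing seed voxel (0-based).
#' @param roi_offset mm pair added to the ROI centre on the plane.
#' @param cut_offset Slices added to the detected cut plane.
#' @param config A [run_config()] supplying plane and detection settings.
#' @return Two-row data.frame of measurement records (3D_Femur, 2D_coronal).
#' @export
measure_subject <- function(volume, subject_id = "subject", seed_point = NULL,
                            roi_offset = c(0, 0), cut_offset = 0,
                            config = run_config()) {
  sp <- seed_point %||% auto_seed_point(volume)
  cfg <- region_grow_config(sp)
  dims <- dim(volume$values)
  hu <- volume$values[sp[1] + 1L, sp[2] + 1L, sp[3] + 1L]
  if (hu < cfg$hu_low || hu > cfg$hu_high) {
    # jittered observer seed fell off the cortex: recover at the brightest voxel
    cfg <- region_grow_config(auto_seed_point(volume))
  }
  filled <- fill_interior(region_grow(volume, cfg))
  cut <- detect_cut_plane(filled, prominence = config$prominence)
  cut <- min(max(cut + as.integer(cut_offset), 0L), dims[3] - 1L)
  voi <- crop_to_voi(filled, cut)
  rec3 <- measure_voi(volume, voi, subject_id = subject_id)
  frame <- estimate_neck_frame(voi$mask)
  plane <- reformat_plane(volume, frame, extent = config$plane_extent,
                          pixel_spacing = config$plane_spacing,
                          mask = voi$mask)
  roi <- largest_inscribed_circle(plane, center = roi_offset)
  rec2 <- measure_roi(plane, roi, subject_id = subject_id)
  rbind(rec3, rec2)
}

subject_scale <- function(config, i) {
  if (config$anatomy_sd == 0) return(1)
  with_seed(derive_seed(config$seed, i, 7L),
            max(0.90, min(1.10, stats::rnorm(1, 1, config$anatomy_sd))))
}

render_subject <- function(config, cohort, i) {
  spec_i <- scale_phantom_spec(config$spec, subject_scale(config, i))
  render_phantom(cohort[i, ], spec_i, seed = derive_seed(config$seed, i, 1L))
}

index_directions <- c(huha_fat = "positive_if_high",
                      huha_bone = "positive_if_low",
                      mean_hu = "positive_if_low")

#' Run the full screening-analysis pipeline
#'
#' Samples the cohort, renders each subject's phantom, measures both the 3D
#' femur VOI and the 2D coronal neck ROI, and computes the diagnostic report:
#' group comparison, Spearman correlations of each index with T-score and
#' BMD, ROC analysis (AUC with DeLong CI, Youden cutoff, sensitivity,
#' specificity, PPV, NPV), paired DeLong comparisons of the 2D vs 3D AUC per
#' index, and five-number box-plot summaries per group. Identical
#' configuration and seed reproduce the report exactly.
#'
#' @param config A [run_config()].
#' @param progress Print per-subject progress to stderr.
#' @return An object of class `diagnostic_report`.
#' @export
run_pipeline <- function(config = run_config(), progress = FALSE) {
  if (!inherits(config, "run_config")) stopf("`config` must be a run_config")
  cohort <- sample_cohort(config$n_osteo, config$n_non, config$cohort,
                          seed = derive_seed(config$seed, 0L, 0L),
                          coupling = config$coupling)
  n <- nrow(cohort)
  if (n < 4L) stopf("cohort too small for a diagnostic report")
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- render_subject(config, cohort, i)
    recs[[i]] <- tryCatch(
      measure_subject(ph$volume, subject_id = cohort$subject_id[i],
                      config = config),
      error = function(e) stopf("subject %s failed at measurement: %s",
                                cohort$subject_id[i], conditionMessage(e)))
    if (progress) message(sprintf("[femhu] measured %s (%d/%d)",
                                  cohort$subject_id[i], i, n))
  }
  measurements <- do.call(rbind, recs)
  build_report(cohort, measurements, config)
}

build_report <- function(cohort, measurements, config) {
  labels <- cohort$group
  n_pos <- sum(labels == "osteoporosis")
  n_neg <- sum(labels == "non-osteoporosis")
  indexes <- c("huha_fat", "huha_bone", "mean_hu")
  prefixes <- c("2D_coronal", "3D_Femur")

  # Table-1 analogue
  table1 <- do.call(rbind, lapply(c("age", "bmd", "t_score"), function(v) {
    x <- cohort[[v]]
    data.frame(
      variable = v,
      mean_osteo = mean(x[labels == "osteoporosis"]),
      sd_osteo = stats::sd(x[labels == "osteoporosis"]),
      mean_non = mean(x[labels == "non-osteoporosis"]),
      sd_non = stats::sd(x[labels == "non-osteoporosis"]),
      p_value = group_difference_test(x, labels))
  }))

  wide <- function(prefix, index) {
    m <- measurements[measurements$prefix == prefix, ]
    m[match(cohort$subject_id, m$subject_id), index]
  }

  table2 <- NULL
  table3 <- NULL
  fig4 <- NULL
  for (prefix in prefixes) {
    for (index in indexes) {
      x <- wide(prefix, index)
      ct <- spearman_with_ci(x, cohort$t_score)
      cb <- spearman_with_ci(x, cohort$bmd)
      table2 <- rbind(table2, data.frame(
        prefix = prefix, index = index,
        rho_tscore = ct$rho, rho_tscore_lo = ct$ci95[1],
        rho_tscore_hi = ct$ci95[2], cat_tscore = ct$category,
        rho_bmd = cb$rho, rho_bmd_lo = cb$ci95[1], rho_bmd_hi = cb$ci95[2],
        cat_bmd = cb$category))
      dir <- index_directions[[index]]
      roc <- auc_mann_whitney(x, labels, direction = dir)
      yd <- youden_cutoff(x, labels, direction = dir)
      cf <- confusion_from_rates(n_pos, n_neg, yd$sens, yd$spec)
      table3 <- rbind(table3, data.frame(
        prefix = prefix, index = index, auc = roc$auc,
        auc_lo = roc$ci95[1], auc_hi = roc$ci95[2], direction = dir,
        cutoff = yd$cutoff, sens = yd$sens, spec = yd$spec,
        ppv = cf$ppv, npv = cf$npv))
      for (g in c("osteoporosis", "non-osteoporosis")) {
        s <- boxplot_summary(x[labels == g])
        fig4 <- rbind(fig4, data.frame(prefix = prefix, index = index,
                                       group = g, t(s)))
      }
    }
  }

  delong <- do.call(rbind, lapply(indexes, function(index) {
    a <- wide("2D_coronal", index)
    b <- wide("3D_Femur", index)
    dt <- delong_test(a, b, labels,
                      direction_a = index_directions[[index]],
                      direction_b = index_directions[[index]])
    data.frame(index = index, auc_2d = dt$auc_a, auc_3d = dt$auc_b,
               z = dt$z, p = dt$p)
  }))

  structure(list(
    n_pos = n_pos, n_neg = n_neg, prevalence = 100 * n_pos / (n_pos + n_neg),
    table1 = table1, table2 = table2, table3 = table3, delong = delong,
    fig4 = fig4, measurements = measurements, cohort = cohort,
    config = config), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report> %d subjects (%d osteoporosis, prevalence %.1f%%)\n",
              x$n_pos + x$n_neg, x$n_pos, x$prevalence))
  cat("Diagnostic accuracy (Youden cutoffs):\n")
  t3 <- x$table3
  t3[c("auc", "sens", "spec", "ppv", "npv")] <-
    lapply(t3[c("auc", "sens", "spec", "ppv", "npv")], round_half_up, 1)
  t3$auc <- round_half_up(x$table3$auc, 3)
  print(t3[c("prefix", "index", "auc", "cutoff", "sens", "spec", "ppv", "npv")],
        row.names = FALSE)
  invisible(x)
}

#' Two-observer reliability experiment
#'
#' Renders `n_subjects` phantoms once each and measures every scan twice
#' under independently jittered region-growing seed points, ROI centres and
#' cut planes (simulating two blinded observers), then computes the
#' single-measure absolute-agreement ICC per variable for both the 2D ROI
#' and the 3D VOI.
#'
#' @param config A [run_config()]; jitter magnitudes come from
#'   `seed_jitter`, `roi_jitter`, `cut_jitter`.
#' @param n_subjects Number of scans measured by both observers (>= 2).
#' @return A data.frame with one row per prefix x variable (size, mean HU,
#'   HUHA fat, HUHA bone): `icc`, `ci_lo`, `ci_hi`, `category`.
#' @export
run_reliability <- function(config = run_config(), n_subjects = 50) {
  if (n_subjects < 2) stopf("`n_subjects` must be >= 2")
  n_o <- max(1L, round(n_subjects * config$n_osteo /
                         (config$n_osteo + config$n_non)))
  cohort <- sample_cohort(n_o, n_subjects - n_o, config$cohort,
                          seed = derive_seed(config$seed, 0L, 99L),
                          coupling = config$coupling)
  jitter_draw <- function(seed) {
    with_seed(seed, list(
      seed_vox = as.integer(round(stats::runif(3, -config$seed_jitter,
                                               config$seed_jitter))),
      roi = stats::runif(2, -config$roi_jitter, config$roi_jitter),
      cut = as.integer(round(stats::runif(1, -config$cut_jitter,
                                          config$cut_jitter)))))
  }
  obs <- list()
  for (i in seq_len(n_subjects)) {
    ph <- render_subject(config, cohort, i)
    for (o in 1:2) {
      j <- jitter_draw(derive_seed(config$seed, i, 100L + o))
      sp <- auto_seed_point(ph$volume) + j$seed_vox
      sp <- pmin(pmax(sp, 0L), dim(ph$volume$values) - 1L)
      rec <- measure_subject(ph$volume, subject_id = cohort$subject_id[i],
                             seed_point = sp, roi_offset = j$roi,
                             cut_offset = j$cut, config = config)
      rec$observer <- o
      obs[[length(obs) + 1L]] <- rec
    }
  }
  obs <- do.call(rbind, obs)
  vars <- c("size", "mean_hu", "huha_fat", "huha_bone")
  out <- NULL
  for (prefix in c("2D_coronal", "3D_Femur")) {
    for (v in vars) {
      d <- obs[obs$prefix == prefix, ]
      tab <- cbind(d[[v]][d$observer == 1][match(cohort$subject_id,
                                                 d$subject_id[d$observer == 1])],
                   d[[v]][d$observer == 2][match(cohort$subject_id,
                                                 d$subject_id[d$observer == 2])])
      icc <- icc_two_way_mixed_absolute(tab)
      out <- rbind(out, data.frame(prefix = prefix, variable = v,
                                   icc = icc$icc, ci_lo = icc$ci95[1],
                                   ci_hi = icc$ci95[2],
                                   category = icc$category))
    }
  }
  out
}

#' Write phantom outputs to disk
#'
#' Writes the CT volume and femur mask as NIfTI and the ground-truth
#' landmarks (mm, LPS) as a sidecar JSON.
#'
#' @param phantom A [render_phantom()] result.
#' @param dir Output directory.
#' @param subject_id File-name stem.
#' @return The directory, invisibly.
#' @export
save_phantom <- function(phantom, dir, subject_id = "subject") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, paste0(subject_id, ".nii.gz")))
  write_volume(phantom$truth$femur_mask,
               file.path(dir, paste0(subject_id, "_femur_mask.nii.gz")))
  truth <- phantom$truth
  jsonlite::write_json(
    list(cut_plane_z = truth$cut_plane_z, head_center = truth$head_center,
         neck_center = truth$neck_center, neck_axis = truth$neck_axis,
         composition = as.list(truth$composition), convention = "LPS mm"),
    file.path(dir, paste0(subject_id, "_truth.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a diagnostic report to disk
#'
#' Emits CSV tables (group comparison, correlations, diagnostic accuracy,
#' ICCs when supplied, box-plot summaries, per-subject measurements) and one
#' JSON document containing everything; percentages in the CSVs are rounded
#' half-up to one decimal, full precision is kept in the JSON.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory.
#' @param reliability Optional [run_reliability()] table.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir, reliability = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  t3 <- report$table3
  for (col in c("sens", "spec", "ppv", "npv")) {
    t3[[col]] <- round_half_up(t3[[col]], 1)
  }
  w(report$table1, "group_comparison.csv")
  w(report$table2, "correlations.csv")
  w(t3, "diagnostic_accuracy.csv")
  w(report$delong, "delong_2d_vs_3d.csv")
  w(report$fig4, "boxplot_summaries.csv")
  w(report$measurements, "measurements.csv")
  w(report$cohort, "cohort.csv")
  if (!is.null(reliability)) w(reliability, "reliability_icc.csv")
  payload <- report[c("n_pos", "n_neg", "prevalence", "table1", "table2",
                      "table3", "delong", "fig4")]
  payload$reliability <- reliability
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
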