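# Synthetic study cohort: subject-level bone mineral density, derived
# T-scores and the BMD-coupled tissue-composition parameters that drive the
# femur phantom renderer.

#' T-score from bone mineral density
#'
#' Standard densitometric definition: `(bmd - ref_mean) / ref_sd`, where the
#' reference constants describe a young-adult reference population.
#'
#' @param bmd Bone mineral density, g/cm^2.
#' @param ref_mean,ref_sd Reference-population mean and SD (g/cm^2);
#'   `ref_sd` must be positive.
#' @return T-score (dimensionless), vectorised over `bmd`.
#' @export
t_score_from_bmd <- function(bmd, ref_mean, ref_sd) {
  assert_scalar_num(ref_mean, "ref_mean")
  assert_scalar_num(ref_sd, "ref_sd")
  if (ref_sd <= 0) stopf("`ref_sd` must be > 0")
  (bmd - ref_mean) / ref_sd
}

#' Default cohort distribution parameters
#'
#' Group-wise age and BMD moments of the emulated screening cohort (430
#' women, 96 osteoporotic), together with the T-score reference constants.
#' The reference constants default to `ref_mean = 1.13`, `ref_sd = 0.18`
#' g/cm^2, chosen so the two configured group BMD means map onto the
#' corresponding group T-score means (-3.1 and -1.6).
#'
#' @param age_osteo,age_non Mean/SD of age (years) per group.
#' @param bmd_osteo,bmd_non Mean/SD of BMD (g/cm^2) per group.
#' @param ref_mean,ref_sd T-score reference constants (g/cm^2).
#' @param age_min Lower truncation bound for age (years).
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(age_osteo = c(78.5, 8.7), age_non = c(61.7, 10.2),
                          bmd_osteo = c(0.57, 0.06), bmd_non = c(0.84, 0.12),
                          ref_mean = 1.13, ref_sd = 0.18, age_min = 50) {
  for (nm in c("age_osteo", "age_non", "bmd_osteo", "bmd_non")) {
    v <- get(nm)
    if (length(v) != 2L || any(!is.finite(v)) || v[2] < 0) {
      stopf("`%s` must be c(mean, sd) with sd >= 0", nm)
    }
  }
  if (ref_sd <= 0) stopf("`ref_sd` must be > 0")
  structure(list(age_osteo = age_osteo, age_non = age_non,
                 bmd_osteo = bmd_osteo, bmd_non = bmd_non,
                 ref_mean = ref_mean, ref_sd = ref_sd, age_min = age_min),
            class = "cohort_params")
}

# Mean of N(mu, sd) truncated to [lo, hi].
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location parameter mu* such that the [lo, hi]-truncated N(mu*, sd) has mean
# `target`; keeps configured group means intact despite truncation.
truncnorm_corrected_mu <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  f <- function(mu) truncnorm_mean(mu, sd, lo, hi) - target
  stats::uniroot(f, lower = target - 8 * sd, upper = target + 8 * sd,
                 extendInt = "yes", tol = 1e-10)$root
}

# Truncated-Gaussian draws by resampling out-of-range values.
rtrunc_norm <- function(n, mu, sd, lo = -Inf, hi = Inf) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mu < lo || mu > hi) stopf("degenerate distribution outside truncation bounds")
    return(rep(mu, n))
  }
  x <- stats::rnorm(n, mu, sd)
  for (iter in 1:1000) {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) return(x)
    x[bad] <- stats::rnorm(length(bad), mu, sd)
  }
  stopf("truncated sampling failed to converge (mass in [%g, %g] too small)",
        lo, hi)
}

#' Sample a synthetic screening cohort
#'
#' Draws subject profiles for the osteoporosis (`t_score <= -2.5`) and
#' non-osteoporosis (`t_score > -2.5`) groups. BMD is drawn from a group-wise
#' Gaussian truncated to the group's BMD region (the boundary is
#' `ref_mean - 2.5 * ref_sd`), with the location parameter mean-corrected so
#' the truncated mean equals the configured group mean; the T-score is then
#' derived with [t_score_from_bmd()], which guarantees that labels and
#' T-scores never contradict. Tissue-composition parameters are attached via
#' [bmd_to_tissue_params()].
#'
#' @param n_osteo,n_non Non-negative subject counts per group.
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param coupling A [tissue_coupling()] configuration.
#' @return A data.frame with columns `subject_id`, `age`, `bmd`, `t_score`,
#'   `group`, `marrow_fat_fraction`, `trabecular_hu_mean`.
#' @export
sample_cohort <- function(n_osteo, n_non, params = cohort_params(), seed = 1L,
                          coupling = tissue_coupling()) {
  if (!is.numeric(n_osteo) || !is.numeric(n_non) || n_osteo < 0 || n_non < 0 ||
      n_osteo != round(n_osteo) || n_non != round(n_non)) {
    stopf("`n_osteo` and `n_non` must be non-negative integers")
  }
  if (!inherits(params, "cohort_params")) stopf("`params` must be cohort_params()")
  n_osteo <- as.integer(n_osteo); n_non <- as.integer(n_non)
  bmd_cut <- params$ref_mean - 2.5 * params$ref_sd
  with_seed(seed, {
    draw_group <- function(n, age_p, bmd_p, lo, hi) {
      age_mu <- truncnorm_corrected_mu(age_p[1], age_p[2], params$age_min, Inf)
      bmd_mu <- truncnorm_corrected_mu(bmd_p[1], bmd_p[2], lo, hi)
      list(age = rtrunc_norm(n, age_mu, age_p[2], lo = params$age_min),
           bmd = rtrunc_norm(n, bmd_mu, bmd_p[2], lo = lo, hi = hi))
    }
    # osteoporosis: bmd <= cut (t <= -2.5); non-osteoporosis: bmd > cut
    eps <- 1e-9
    g1 <- draw_group(n_osteo, params$age_osteo, params$bmd_osteo,
                     lo = 0.05, hi = bmd_cut)
    g2 <- draw_group(n_non, params$age_non, params$bmd_non,
                     lo = bmd_cut + eps, hi = Inf)
    age <- c(g1$age, g2$age)
    bmd <- c(g1$bmd, g2$bmd)
    group <- c(rep("osteoporosis", n_osteo), rep("non-osteoporosis", n_non))
    t_score <- t_score_from_bmd(bmd, params$ref_mean, params$ref_sd)
    tissue <- bmd_to_tissue_params(bmd, coupling)
    n <- n_osteo + n_non
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, bmd = bmd, t_score = t_score, group = group,
      marrow_fat_fraction = tissue$marrow_fat_fraction,
      trabecular_hu_mean = tissue$trabecular_hu_mean,
      stringsAsFactors = FALSE
    )
  })
}

#' BMD-to-tissue coupling configuration
#'
#' Linear monotone maps from BMD to (a) the marrow fat fraction (strictly
#' decreasing) and (b) the target mean attenuation of the marrow-space
#' interior compartment (strictly increasing), clipped outside `bmd_range`.
#' The strength of this coupling is a modelling choice, not an observed
#' quantity.
#'
#' @param bmd_range BMD interval (g/cm^2) over which the maps are linear.
#' @param fat_range Fat fraction at `bmd_range[1]` and `bmd_range[2]`; must
#'   be decreasing and within \[0, 1\].
#' @param hu_range Interior mean HU at `bmd_range[1]` and `bmd_range[2]`;
#'   must be increasing.
#' @return A list of class `tissue_coupling`.
#' @export
tissue_coupling <- function(bmd_range = c(0.40, 1.20),
                            fat_range = c(0.75, 0.10),
                            hu_range = c(-20, 180)) {
  if (diff(bmd_range) <= 0) stopf("`bmd_range` must be increasing")
  if (diff(fat_range) >= 0) stopf("non-monotone coupling: `fat_range` must be strictly decreasing in BMD")
  if (diff(hu_range) <= 0) stopf("non-monotone coupling: `hu_range` must be strictly increasing in BMD")
  if (any(fat_range < 0 | fat_range > 1)) stopf("`fat_range` must lie in [0, 1]")
  structure(list(bmd_range = bmd_range, fat_range = fat_range,
                 hu_range = hu_range), class = "tissue_coupling")
}

#' Map BMD to phantom tissue-composition parameters
#'
#' @param bmd BMD values (g/cm^2), all positive.
#' @param coupling A [tissue_coupling()].
#' @return A data.frame with `marrow_fat_fraction` (strictly decreasing in
#'   BMD over `bmd_range`) and `trabecular_hu_mean` (strictly increasing).
#' @export
bmd_to_tissue_params <- function(bmd, coupling = tissue_coupling()) {
  if (!inherits(coupling, "tissue_coupling")) stopf("`coupling` must be tissue_coupling()")
  if (any(!is.finite(bmd)) || any(bmd <= 0)) stopf("`bmd` must be positive and finite")
  f <- (bmd - coupling$bmd_range[1]) / diff(coupling$bmd_range)
  f <- pmin(1, pmax(0, f))
  data.frame(
    marrow_fat_fraction = coupling$fat_range[1] + f * diff(coupling$fat_range),
    trabecular_hu_mean = coupling$hu_range[1] + f * diff(coupling$hu_range)
  )
}
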