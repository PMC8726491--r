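# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately implemented differently from the package
# internals (pure-R breadth-first search, ANOVA via aov(), exhaustive scans).

# Pure-R breadth-first flood fill over an HU grid: the oracle for
# region_grow(). Frontier-at-a-time matrix expansion, entirely in R.
bfs_flood_fill <- function(values, seed, hu_low, hu_high, connectivity = 26) {
  dims <- dim(values)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[if (connectivity == 6) m == 1 else m > 0, , drop = FALSE]
  inband <- values >= hu_low & values <= hu_high
  out <- array(FALSE, dims)
  s <- rbind(seed + 1L)
  if (!inband[s]) stop("oracle: seed out of band")
  out[s] <- TRUE
  frontier <- s
  while (nrow(frontier)) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                     drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), , drop = FALSE]
    keep <- cand[, 1] >= 1 & cand[, 2] >= 1 & cand[, 3] >= 1 &
      cand[, 1] <= dims[1] & cand[, 2] <= dims[2] & cand[, 3] <= dims[3]
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[!duplicated(cand), , drop = FALSE]
    keep <- inband[cand] & !out[cand]
    cand <- cand[keep, , drop = FALSE]
    out[cand] <- TRUE
    frontier <- cand
  }
  out
}

# Trapezoidal area under the empirical ROC curve: the second, independent
# AUC computation.
trapezoid_auc <- function(scores, labels, direction = "positive_if_high") {
  x <- if (direction == "positive_if_low") -scores else scores
  thr <- c(-Inf, sort(unique(x)), Inf)
  sens <- vapply(thr, function(t) mean(x[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(x[!labels] >= t), numeric(1))
  ord <- order(fpr, sens)
  sum(diff(fpr[ord]) * (head(sens[ord], -1) + tail(sens[ord], -1)) / 2)
}

# Two-way ANOVA mean squares via aov(): the ICC oracle.
icc_a1_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  d <- data.frame(y = as.vector(tab),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Exact Mann-Whitney p by enumeration of all label assignments.
mann_whitney_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(a, b)
  combs <- combn(length(pooled), n)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  eu <- n * (length(pooled) - n) / 2
  mean(abs(us - eu) >= abs(obs - eu) - 1e-12)
}

# A small, fast phantom shared across tests (default geometry, one subject).
test_phantom <- local({
  cache <- new.env()
  function(noise_sd = 12, seed = 7, fat = NULL, hu_mean = NULL) {
    key <- paste(noise_sd, seed, fat, hu_mean, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    co <- sample_cohort(1, 1, seed = 5)
    prof <- co[1, ]
    if (!is.null(fat)) prof$marrow_fat_fraction <- fat
    if (!is.null(hu_mean)) prof$trabecular_hu_mean <- hu_mean
    spec <- phantom_spec(noise_sd = noise_sd)
    cache[[key]] <- render_phantom(prof, spec, seed = seed)
    cache[[key]]
  }
})

# Digital ball mask in an axis-aligned grid.
ball_mask <- function(dims, center, radius, spacing = c(1, 1, 1)) {
  x <- (seq_len(dims[1]) - 1) * spacing[1]
  y <- (seq_len(dims[2]) - 1) * spacing[2]
  z <- (seq_len(dims[3]) - 1) * spacing[3]
  X <- array(rep(x, times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(y, each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dim = dims)
  m <- (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= radius^2
  mask_volume(m, spacing = spacing)
}

# Assemble a reformatted_plane object directly (for ROI unit tests).
make_plane <- function(values, bone_mask, pixel_spacing = c(1, 1)) {
  nu <- nrow(values); nv <- ncol(values)
  structure(list(
    values = values, pixel_spacing = pixel_spacing,
    frame = neck_frame(c(0, 0, 0), c(1, 0, 0)),
    bone_mask = bone_mask,
    u_offsets = (seq_len(nu) - (nu + 1) / 2) * pixel_spacing[1],
    v_offsets = (seq_len(nv) - (nv + 1) / 2) * pixel_spacing[2]),
    class = "reformatted_plane")
}
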