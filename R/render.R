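# ---- geometry helpers -------------------------------------------------------

# logical in-plane ellipse, axis-aligned
ellipse_voxels <- function(shape_xy, center, semi_axes) {
  x <- matrix(seq_len(shape_xy[1]), shape_xy[1], shape_xy[2])
  y <- matrix(seq_len(shape_xy[2]), shape_xy[1], shape_xy[2], byrow = TRUE)
  ((x - center[1]) / semi_axes[1])^2 + ((y - center[2]) / semi_axes[2])^2 <= 1
}

# bilateral SN template: two ellipses per slice over three slices.
# Returns the mask, per-voxel posterolateral score (higher = more
# posterolateral), and the slice indices.
sn_template <- function(shape, slices, hemi_offset, semi_axes) {
  mid <- (shape[1] + 1) / 2
  cy <- round(shape[2] * 0.46)
  plane <- array(FALSE, dim = shape[1:2])
  score <- array(NA_real_, dim = shape[1:2])
  for (side in c(-1, 1)) {
    cx <- mid + side * hemi_offset
    nq_assert(cx - semi_axes[1] >= 1 && cx + semi_axes[1] <= shape[1] &&
                cy - semi_axes[2] >= 1 && cy + semi_axes[2] <= shape[2],
              "volume shape too small for the SN template",
              class = "nigraquant_template_too_small")
    e <- ellipse_voxels(shape[1:2], c(cx, cy), semi_axes)
    plane <- plane | e
    idx <- which(e, arr.ind = TRUE)
    # lateral distance from midline plus posterior (+y) displacement
    score[e] <- abs(idx[, 1] - mid) / semi_axes[1] +
      (idx[, 2] - cy) / semi_axes[2]
  }
  mask <- array(FALSE, dim = shape)
  sc <- array(NA_real_, dim = shape)
  for (z in slices) { mask[, , z] <- plane; sc[, , z] <- score }
  sc[!mask] <- NA
  list(mask = mask, score = sc, slices = slices)
}

# rectangular background ROI on the analysis slices, anterior to the SN
background_template <- function(shape, slices) {
  bg <- array(FALSE, dim = shape)
  xr <- seq(round(shape[1] * 0.40), round(shape[1] * 0.60))
  yr <- seq(round(shape[2] * 0.08), round(shape[2] * 0.20))
  for (z in slices) bg[xr, yr, z] <- TRUE
  bg
}

# zero-mean alternating +/-1 texture, used to give background regions a
# deterministic, reproducible standard deviation
bg_texture <- function(n, amplitude) {
  p <- amplitude * rep_len(c(-1, 1), n)
  p - mean(p)
}

# ---- in-mask intensity profiles --------------------------------------------

# linear-in-rank profile with given mean and P90/P10 contrast ratio; exact
# under type-7 quantiles because the values are equally spaced
linear_profile <- function(n, mean, contrast) {
  nq_assert(contrast >= 1 && contrast < 9,
            "contrast ratio must lie in [1, 9) for a linear profile")
  a <- mean / (1 + (contrast - 1) / (2 * (0.9 - 0.1 * contrast)))
  b <- a * (contrast - 1) / (0.9 - 0.1 * contrast)
  a + b * (seq_len(n) - 1) / (n - 1)
}

# symmetric linear ramp of `len` values with exact mean `mu` and halfwidth `h`
ramp_seg <- function(mu, h, len) {
  if (len <= 0) return(numeric(0))
  if (len == 1) return(mu)
  seq(mu - h, mu + h, length.out = len)
}

# sorted value profile with exact mean whose k smallest values fall strictly
# below `cutoff` and the remaining n-k strictly above; used for the fixed
# 70 ppb susceptibility rule. Two symmetric ramps, one per side of the
# cutoff, with the side means solved so the overall mean is exact.
profile_with_cutoff_count <- function(n, mean, cutoff, k, lower_gap = 30) {
  k <- max(0L, min(n, as.integer(k)))
  eps <- 1e-6 * max(1, abs(cutoff))
  one_side <- function(side) {
    # all values on one side of the cutoff; exact mean when feasible
    h <- side * (mean - cutoff) - eps
    if (h > 0) return(sort(ramp_seg(mean, min(h, 45), n)))
    rep(cutoff + side * eps, n)   # infeasible mean/count combination
  }
  if (k == 0L) return(one_side(+1))
  if (k == n) return(one_side(-1))
  t_star <- k / n
  mu_low <- cutoff - lower_gap / 2
  mu_up <- (mean - t_star * mu_low) / (1 - t_star)
  if (mu_up <= cutoff + 2 * eps) {
    # requested mean sits low for the split: anchor the upper side just
    # above the cutoff and push the lower-side mean down instead
    mu_up <- cutoff + 5
    mu_low <- (mean - (1 - t_star) * mu_up) / t_star
    if (mu_low >= cutoff - 2 * eps) mu_low <- cutoff - 1
  }
  low <- ramp_seg(mu_low, cutoff - eps - mu_low, k)
  up <- ramp_seg(mu_up, min(mu_up - cutoff - eps, 60), n - k)
  c(low, up)
}

# assign a sorted value profile to mask voxels along the posterolateral ->
# anteromedial axis. `ascending_with_pl = TRUE` puts the smallest values at
# the most posterolateral voxels (NM depigmentation, low-susceptibility
# nigrosome loss start there). gradient_strength in [0,1] mixes strict
# anatomical ordering with a deterministic shuffle; features are invariant
# to in-mask ordering, so this only changes geometry, never statistics.
assign_profile <- function(values, score, ascending_with_pl, gradient_strength) {
  ord <- order(score, decreasing = ascending_with_pl)
  g <- min(1, max(0, gradient_strength))
  if (g < 1) {
    n <- length(ord)
    n_mix <- floor((1 - g) * n)
    if (n_mix > 1) {
      ix <- seq_len(n_mix)
      ord[ix] <- ord[ix[(seq_along(ix) * 7L) %% n_mix + 1L]]
    }
  }
  out <- numeric(length(values))
  out[ord] <- sort(values)
  out
}

# ---- subject rendering ------------------------------------------------------

#' Render synthetic midbrain volumes and masks for one subject
#'
#' Paints NM-sensitive, QSM and SWI-magnitude volumes containing a bilateral
#' two-ellipse SN template on three analysis slices, plus a rectangular
#' background ROI. The in-mask intensity profiles are constructed so that the
#' quantitative extraction pipeline reproduces the subject's target features:
#' NM values follow a linear posterolateral-to-anteromedial ramp with the
#' target mean and P90/P10 contrast ratio, and the background level is set so
#' the high-signal cutoff (background mean + k SD) isolates exactly the
#' target number of suprathreshold voxels; QSM values ramp through the fixed
#' 70 ppb cutoff at the target low-susceptibility count; the magnitude volume
#' is chosen so the synthesised SMWI image hits the target mean and
#' low-signal count. Mask ellipses are scaled per subject to the target mask
#' areas. The returned `truth_features` are re-measured from the painted
#' volumes (sizes quantised to whole voxels), so zero-noise extraction
#' reproduces them to float precision; Gaussian noise of SD `config$noise_sd`
#' is then added to the returned volumes.
#'
#' @param record one-row subject data frame (a [generate_cohort] record).
#' @param config a [phantom_config].
#' @param truth_features one-row data frame of target features; defaults to a
#'   fresh draw from the configured marginals.
#' @param policy the [threshold_policy] the downstream extraction will use.
#' @param shape_nm,shape_qsm grid dimensions of the NM and QSM volumes.
#' @param noise_seed seed for the additive noise stream.
#' @return List with `volumes` (named list `nm`, `qsm`, `mag`), `masks`
#'   (named list of [mask_set]s `nm`, `qsm`) and the re-measured
#'   `truth_features`.
#' @export
render_subject_volumes <- function(record, config,
                                   truth_features = NULL,
                                   policy = threshold_policy(),
                                   shape_nm = c(96, 96, 13),
                                   shape_qsm = c(96, 96, 32),
                                   noise_seed = config$seed) {
  nq_assert(inherits(config, "phantom_config"), "need a phantom_config")
  if (is.null(truth_features)) {
    grp <- if (is_patient(record$group)) "patient" else "control"
    fm <- config$feature_marginals
    means <- if (grp == "patient") fm$mean_patient else fm$mean_control
    truth_features <- as.data.frame(as.list(stats::setNames(means, fm$feature)))
  }
  tf <- truth_features
  vd_nm <- config$voxel_dims_nm; vd_q <- config$voxel_dims_qsm
  va_nm <- vd_nm[1] * vd_nm[2]; va_q <- vd_q[1] * vd_q[2]
  g <- config$gradient_strength

  ## ---- NM grid -------------------------------------------------------------
  # template ellipse sized for the control-mean mask area, rescaled per
  # subject to the target area
  base_nm <- c(a = 14.0, b = 8.44)        # ~371 voxels/hemisphere/slice
  scale_nm <- sqrt(tf$nm_size / 556.8)
  nm_slices <- round(shape_nm[3] / 2) + (-1:1)
  tmpl_nm <- sn_template(shape_nm, nm_slices, hemi_offset = round(shape_nm[1] * 0.19),
                         semi_axes = base_nm * scale_nm)
  n_nm <- sum(tmpl_nm$mask)
  k_high <- max(0L, min(n_nm, round(tf$nm_size_high / va_nm)))
  if (tf$nm_contrast_range <= 1 + 1e-9 && k_high > 0L) {
    # contrast ratio at its floor of 1 with a nonzero suprathreshold area:
    # a two-level profile keeps P10 = P90 while a small bright fraction
    # carries the thresholded size (feasible only below the 10th percentile)
    if (k_high > floor(0.095 * (n_nm - 1))) k_high <- floor(0.095 * (n_nm - 1))
    x <- tf$nm_signal * n_nm / (n_nm - k_high + 1.25 * k_high)
    nm_vals <- c(rep(x, n_nm - k_high), rep(1.25 * x, k_high))
  } else {
    nm_vals <- linear_profile(n_nm, tf$nm_signal, tf$nm_contrast_range)
  }
  sorted <- nm_vals                        # already ascending
  cut_nm <- if (k_high == 0L) sorted[n_nm] + 1 else
    if (k_high == n_nm) sorted[1] - 1 else
      (sorted[n_nm - k_high] + sorted[n_nm - k_high + 1]) / 2

  bg_nm_mask <- background_template(shape_nm, nm_slices)
  tex_nm <- bg_texture(sum(bg_nm_mask), amplitude = 8)
  # invert the background-statistics threshold rule: place the background
  # level so that mean(bg) + nm_k * sd(bg) equals the required cutoff
  bg_level_nm <- cut_nm - policy$nm_k * stats::sd(tex_nm)

  nm <- array(bg_level_nm, dim = shape_nm)
  nm[bg_nm_mask] <- bg_level_nm + tex_nm
  nm[tmpl_nm$mask] <- assign_profile(nm_vals, tmpl_nm$score[tmpl_nm$mask],
                                     ascending_with_pl = TRUE,
                                     gradient_strength = g)

  ## ---- QSM grid ------------------------------------------------------------
  base_q <- c(a = 10.3, b = 5.72)          # ~185 voxels/hemisphere/slice
  scale_q <- sqrt(tf$qsm_size / 277.7)
  q_slices <- round(shape_qsm[3] / 2) + (-1:1)
  tmpl_q <- sn_template(shape_qsm, q_slices, hemi_offset = round(shape_qsm[1] * 0.19),
                        semi_axes = base_q * scale_q)
  n_q <- sum(tmpl_q$mask)
  k_low <- round(tf$qsm_size_low / va_q)
  chi_vals <- sort(profile_with_cutoff_count(n_q, tf$qsm_chi_mean,
                                             policy$qsm_chi_cutoff, k_low))

  qsm <- array(0, dim = shape_qsm)
  bg_q_mask <- background_template(shape_qsm, q_slices)
  qsm[tmpl_q$mask] <- assign_profile(chi_vals, tmpl_q$score[tmpl_q$mask],
                                     ascending_with_pl = TRUE,
                                     gradient_strength = g)

  ## ---- SMWI / magnitude ----------------------------------------------------
  # voxels whose susceptibility reaches the weighting ceiling have zero SMWI
  # signal whatever the magnitude; they are painted as exact zeros and the
  # remaining voxels carry the target mean and low-signal count
  k_slow <- max(0L, min(n_q, round(tf$smwi_size_low / va_q)))
  n0 <- sum(chi_vals >= policy$smwi_chi_high)
  n_pos <- n_q - n0
  mu_pos <- tf$smwi_signal * n_q / max(1, n_pos)
  pos_vals <- ramp_seg(mu_pos, min(0.25 * mu_pos, mu_pos - 1), n_pos)
  k_eff <- max(0L, min(n_pos, k_slow - n0))
  cut_s <- if (n_pos == 0L) 1 else
    if (k_eff == 0L) pos_vals[1] / 2 else
      if (k_eff == n_pos) pos_vals[n_pos] + 1 else
        (pos_vals[k_eff] + pos_vals[k_eff + 1]) / 2
  amp_s <- min(10, cut_s / 2)
  bg_level_s <- cut_s + amp_s    # q10 of a symmetric two-level texture
  tex_s <- amp_s * rep_len(c(-1, 1), sum(bg_q_mask))

  # low SMWI signal sits where susceptibility is high (anteromedial first):
  # in-mask SMWI values descend as chi ascends, zeros at the ceiling
  smwi_in_mask <- rev(c(rep(0, n0), pos_vals))[order(order(qsm[tmpl_q$mask]))]
  smwi_target <- array(bg_level_s, dim = shape_qsm)
  smwi_target[bg_q_mask] <- bg_level_s + tex_s
  smwi_target[tmpl_q$mask] <- smwi_in_mask

  w <- pmin(1, pmax(0, (policy$smwi_chi_high - qsm) /
                      (policy$smwi_chi_high - policy$smwi_chi_low)))^policy$smwi_power
  mag <- array(bg_level_s, dim = shape_qsm)
  ok_w <- w > 0
  mag[ok_w] <- smwi_target[ok_w] / w[ok_w]
  mag[bg_q_mask] <- smwi_target[bg_q_mask]   # background chi is zero: w = 1

  volumes <- list(
    nm = volume_image(nm, vd_nm, "NM"),
    qsm = volume_image(qsm, vd_q, "QSM"),
    mag = volume_image(mag, vd_q, "SWI_MAG")
  )
  masks <- list(
    nm = mask_set(tmpl_nm$mask, bg_nm_mask, nm_slices, vd_nm),
    qsm = mask_set(tmpl_q$mask, bg_q_mask, q_slices, vd_q)
  )

  # ground truth is what was actually painted: re-measure it with the same
  # operations the downstream extraction applies
  truth <- extract_feature_vector(volumes, masks, policy)
  truth$composite <- NULL

  if (config$noise_sd > 0) {
    with_seed(noise_seed, {
      for (v in names(volumes)) {
        arr <- unclass(volumes[[v]])
        arr <- arr + stats::rnorm(length(arr), 0, config$noise_sd)
        volumes[[v]] <- volume_image(array(arr, dim = dim(arr)),
                                     voxel_dims(volumes[[v]]),
                                     attr(volumes[[v]], "modality"))
      }
    })
  }
  list(volumes = volumes, masks = masks, truth_features = truth)
}
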