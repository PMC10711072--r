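test_that("mask areas follow the in-plane voxel-area convention and add over disjoint masks", {
  m <- array(0, c(10, 10, 1)); m[1:10, 1:10, 1] <- 1
  expect_equal(mask_area(m, c(0.5, 0.5, 3)), 25)

  left <- array(0, c(10, 10, 2)); left[1:3, 1:3, 1] <- 1
  right <- array(0, c(10, 10, 2)); right[7:9, 7:9, 2] <- 1
  expect_equal(mask_area(left | right, c(0.5, 0.5, 1)),
               mask_area(left, c(0.5, 0.5, 1)) + mask_area(right, c(0.5, 0.5, 1)))

  expect_error(mask_area(array(0, c(4, 4, 1)), c(0.5, 0.5, 1)),
               class = "nigraquant_degenerate_mask")
})

test_that("the default SN templates reproduce the published control mask areas", {
  cfg <- phantom_config(seed = 3)
  rec <- data.frame(subject_id = "S001", group = "control")
  r <- render_subject_volumes(rec, cfg)  # control-mean targets by default
  expect_equal(mask_area(r$masks$nm, cfg$voxel_dims_nm), 556.8,
               tolerance = 0.01)
  expect_equal(mask_area(r$masks$qsm, cfg$voxel_dims_qsm), 277.7,
               tolerance = 0.01)
})

test_that("in-mask mean intensity is the plain arithmetic mean", {
  mask <- array(0, c(6, 6, 3)); mask[1:3, 1, 1] <- 1
  expect_equal(mean_intensity_in_mask(toy_volume(c(7, 7, 7)), mask), 7)
  expect_equal(mean_intensity_in_mask(toy_volume(c(1, 2, 3)), mask), 2)
  expect_error(mean_intensity_in_mask(toy_volume(1:3), array(0, c(6, 6, 3))),
               class = "nigraquant_degenerate_mask")
})

test_that("contrast range matches a sort-based order-statistic oracle and is scale invariant", {
  mask <- array(0, c(10, 10, 2)); mask[, , 1] <- 1
  v <- array(0, c(10, 10, 2)); v[, , 1] <- 1:100
  vol <- volume_image(v, c(0.5, 0.5, 1), "NM")
  # independent oracle: linear interpolation between closest order statistics
  interp_q <- function(x, p) {
    x <- sort(x); h <- 1 + p * (length(x) - 1)
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  expect_equal(contrast_range(vol, mask),
               interp_q(1:100, 0.9) / interp_q(1:100, 0.1))

  set.seed(11)
  x <- rlnorm(57)
  mask2 <- array(0, c(8, 8, 2)); mask2[seq_along(x)] <- 1
  v2 <- array(0, c(8, 8, 2)); v2[seq_along(x)] <- x
  vol2 <- volume_image(v2, c(0.5, 0.5, 1), "NM")
  expect_equal(contrast_range(vol2, mask2),
               interp_q(x, 0.9) / interp_q(x, 0.1))
  vol3 <- volume_image(v2 * 37.5, c(0.5, 0.5, 1), "NM")
  expect_equal(contrast_range(vol3, mask2), contrast_range(vol2, mask2))

  # constant signal has unit contrast; non-positive P10 is rejected
  expect_equal(contrast_range(toy_volume(rep(5, 12)),
                              array(c(rep(1, 12), rep(0, 96)), c(6, 6, 3))), 1)
  neg <- toy_volume(c(rep(-1, 3), rep(2, 9)))
  expect_error(contrast_range(neg, array(c(rep(1, 12), rep(0, 96)), c(6, 6, 3))),
               class = "nigraquant_undefined_statistic")
})

test_that("NM high-signal cutoff follows the background-statistics rule", {
  dims <- c(8, 8, 3)
  sn <- array(0, dims); sn[1:4, 1, 2] <- 1
  bg <- array(0, dims); bg[5:8, 8, 2] <- 1
  bg_vals <- c(90, 95, 105, 110)
  v <- array(0, dims); v[sn == 1] <- 200; v[bg == 1] <- bg_vals
  vol <- volume_image(v, c(0.5, 0.5, 3), "NM")
  ms <- mask_set(sn, bg, 2)
  expect_equal(nm_high_signal_threshold(vol, ms, threshold_policy(nm_k = 3)),
               mean(bg_vals) + 3 * sd(bg_vals))
  expect_equal(nm_high_signal_threshold(vol, ms, threshold_policy(nm_k = 0)),
               mean(bg_vals))
  # zero background variance falls back to the mean with a warning
  v[bg == 1] <- 100
  volc <- volume_image(v, c(0.5, 0.5, 3), "NM")
  expect_warning(cut <- nm_high_signal_threshold(volc, ms, threshold_policy()),
                 "zero variance")
  expect_equal(cut, 100)
})

test_that("auc_sweep picks the grid cutoff with maximal group separation", {
  set.seed(21)
  n <- 40
  lab <- rep(c("control", "patient"), each = n / 2)
  vals <- lapply(seq_len(n), function(i)
    rnorm(60, mean = if (lab[i] == "patient") 170 else 200, sd = 25))
  areas_fun <- function(cut) vapply(vals, function(v) 0.25 * sum(v > cut),
                                    numeric(1))
  grid <- seq(150, 230, by = 10)
  cut <- nm_high_signal_threshold(NULL, NULL,
                                  threshold_policy(optimization_mode = "auc_sweep"),
                                  calibration = list(areas_fun = areas_fun,
                                                     labels = lab, grid = grid))
  aucs <- vapply(grid, function(g)
    empirical_auc_ci(areas_fun(g), lab, direction = "low")$auc, numeric(1))
  expect_equal(cut, grid[which.max(aucs)])
  expect_true(all(aucs[grid == cut] >= aucs))
})

test_that("thresholded areas count strict-predicate voxels and partition the mask", {
  dims <- c(4, 4, 1)
  mask <- array(0, dims); mask[1:4, 1, 1] <- 1
  v <- array(0, dims); v[1:4, 1, 1] <- c(60, 65, 75, 80)
  vol <- volume_image(v, c(0.5, 0.5, 1), "QSM")
  expect_equal(thresholded_area(vol, mask, 70, "<", c(0.5, 0.5, 1)), 0.5)
  expect_equal(thresholded_area(vol, mask, 50, "<", c(0.5, 0.5, 1)), 0)

  set.seed(31)
  for (i in 1:10) {
    dims <- c(10, 10, 3)
    mask <- array(runif(prod(dims)) < 0.4, dims)
    if (!any(mask)) next
    v <- volume_image(array(rnorm(prod(dims)), dims), c(0.5, 0.5, 1), "QSM")
    cut <- rnorm(1)
    lo <- thresholded_area(v, mask, cut, "<", c(0.5, 0.5, 1))
    hi <- thresholded_area(v, mask, cut, ">", c(0.5, 0.5, 1))
    tot <- mask_area(mask, c(0.5, 0.5, 1))
    expect_equal(lo + hi, tot)  # continuous values: ties have measure zero
    expect_true(lo >= 0 && hi >= 0 && lo <= tot && hi <= tot)
  }
})

test_that("SMWI weighting is the clipped linear ramp raised to a power", {
  dims <- c(5, 5, 2)
  mag <- volume_image(array(120, dims), c(0.5, 0.5, 1), "SWI_MAG")
  lowchi <- volume_image(array(70, dims), c(0.5, 0.5, 1), "QSM")
  hichi <- volume_image(array(200, dims), c(0.5, 0.5, 1), "QSM")
  midchi <- volume_image(array(120, dims), c(0.5, 0.5, 1), "QSM")
  expect_equal(as.numeric(compute_smwi(lowchi, mag)[1]), 120)
  expect_equal(max(abs(compute_smwi(hichi, mag))), 0)
  expect_equal(as.numeric(compute_smwi(midchi, mag, 70, 170, 4)[1]),
               120 * 0.5^4)
  # voxel-wise monotone non-increasing in susceptibility
  chis <- seq(0, 250, by = 10)
  w <- vapply(chis, function(ch)
    as.numeric(compute_smwi(volume_image(array(ch, dims), c(0.5, 0.5, 1), "QSM"),
                            mag)[1]), numeric(1))
  expect_true(all(diff(w) <= 1e-12))
  bad <- volume_image(array(1, c(4, 4, 2)), c(0.5, 0.5, 1), "SWI_MAG")
  expect_error(compute_smwi(lowchi, bad), class = "nigraquant_geometry_mismatch")
})

test_that("feature extraction is invariant to in-mask voxel order and translation", {
  cfg <- calibrated_config()
  r <- render_subject_volumes(data.frame(subject_id = "S1", group = "patient"),
                              cfg)
  base <- extract_feature_vector(r$volumes, r$masks)

  # one permutation per region per grid, applied to every co-registered
  # volume on that grid (SMWI is a voxel-wise product of QSM and magnitude)
  set.seed(5)
  perm <- r$volumes
  perms <- lapply(list(nm_sn = r$masks$nm$sn_mask,
                       nm_bg = r$masks$nm$background_mask,
                       q_sn = r$masks$qsm$sn_mask,
                       q_bg = r$masks$qsm$background_mask),
                  function(m) list(from = which(m), to = sample(which(m))))
  for (v in c("nm", "qsm", "mag")) {
    keys <- if (v == "nm") c("nm_sn", "nm_bg") else c("q_sn", "q_bg")
    arr <- unclass(perm[[v]])
    for (k in keys) arr[perms[[k]]$from] <- arr[perms[[k]]$to]
    perm[[v]] <- volume_image(arr, voxel_dims(perm[[v]]),
                              attr(perm[[v]], "modality"))
  }
  expect_equal(extract_feature_vector(perm, r$masks), base)

  # rigid translation of volume + masks together
  shift <- function(a, by) {
    out <- array(0, dim(a)); n <- dim(a)[1]
    out[(1 + by):n, , ] <- a[1:(n - by), , ]
    out
  }
  tr_vol <- lapply(r$volumes, function(v)
    volume_image(shift(unclass(v), 2), voxel_dims(v), attr(v, "modality")))
  tr_masks <- lapply(r$masks, function(m)
    mask_set(shift(m$sn_mask, 2), shift(m$background_mask, 2),
             m$analysis_slices, m$voxel_dims))
  expect_equal(extract_feature_vector(tr_vol, tr_masks), base)
})
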