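#' Thresholding policy for SN mask post-processing
#'
#' Controls the three thresholding rules applied to SN masks: the
#' high-signal cutoff on neuromelanin-sensitive images (background mean plus
#' `nm_k` background standard deviations, or an AUC-optimised sweep), the
#' fixed low-susceptibility cutoff on QSM (default 70 ppb), and the
#' low-signal cutoff on SMWI (a background quantile, default the 10th
#' percentile).
#'
#' @param qsm_chi_cutoff susceptibility cutoff in ppb; SN voxels with
#'   susceptibility strictly below it count toward `qsm_size_low`.
#' @param nm_k background-SD multiplier for the NM high-signal cutoff.
#' @param smwi_low_quantile background quantile in (0,1) defining the SMWI
#'   low-signal cutoff.
#' @param optimization_mode `"fixed"` uses the background-statistics rule;
#'   `"auc_sweep"` picks the NM cutoff maximising group-separation AUC of the
#'   thresholded area on a labelled calibration cohort.
#' @param smwi_chi_low,smwi_chi_high,smwi_power SMWI weighting constants
#'   passed to [compute_smwi] when SMWI must be synthesised.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(qsm_chi_cutoff = 70, nm_k = 3,
                             smwi_low_quantile = 0.1,
                             optimization_mode = c("fixed", "auc_sweep"),
                             smwi_chi_low = 70, smwi_chi_high = 170,
                             smwi_power = 4L) {
  nq_assert(qsm_chi_cutoff > 0, "`qsm_chi_cutoff` must be positive")
  nq_assert(nm_k >= 0, "`nm_k` must be non-negative")
  nq_assert(smwi_low_quantile > 0 && smwi_low_quantile < 1,
            "`smwi_low_quantile` must lie in (0,1)")
  structure(list(qsm_chi_cutoff = qsm_chi_cutoff, nm_k = nm_k,
                 smwi_low_quantile = smwi_low_quantile,
                 optimization_mode = match.arg(optimization_mode),
                 smwi_chi_low = smwi_chi_low, smwi_chi_high = smwi_chi_high,
                 smwi_power = as.integer(smwi_power)),
            class = "threshold_policy")
}

mask_array <- function(mask) {
  if (inherits(mask, "mask_set")) mask$sn_mask else mask != 0
}

#' Area of an SN mask in mm^2
#'
#' The area convention pools both hemispheres and the three analysis slices:
#' (number of in-mask voxels) x (in-plane voxel area). This reproduces the
#' scale of published SN mask sizes (roughly 560 mm^2 for NM-sensitive and
#' 280 mm^2 for QSM masks in controls).
#'
#' @param mask a [mask_set] or binary 3D array.
#' @param voxel_dims voxel dimensions in mm; only the in-plane (first two)
#'   dimensions enter the area.
#' @return Area in mm^2.
#' @examples
#' m <- array(0, c(10, 10, 1)); m[1:10, 1:10, 1] <- 1
#' mask_area(m, c(0.5, 0.5, 3))  # 100 voxels x 0.25 mm^2 = 25
#' @export
mask_area <- function(mask, voxel_dims) {
  m <- mask_array(mask)
  n <- sum(m)
  if (n == 0) nq_stop("mask is empty", "nigraquant_degenerate_mask")
  n * voxel_dims[1] * voxel_dims[2]
}

#' Mean voxel value within a mask
#'
#' @param volume a [volume_image] (or plain 3D array).
#' @param mask a [mask_set] or binary array on the same grid.
#' @return Arithmetic mean of the in-mask voxel values (a.u. or ppb).
#' @export
mean_intensity_in_mask <- function(volume, mask) {
  m <- mask_array(mask)
  nq_assert(identical(dim(unclass(volume)), dim(m)),
            "mask and volume grids differ")
  if (!any(m)) nq_stop("mask is empty", "nigraquant_degenerate_mask")
  mean(volume[m])
}

#' Percentile contrast range of in-mask signal
#'
#' Ratio of the 90th to the 10th percentile of in-mask voxel values,
#' percentiles computed by linear interpolation between the closest order
#' statistics (R quantile type 7). In the SN this captures the dynamic range
#' between retained (hyperintense) and depigmented neuromelanin signal and is
#' invariant to positive rescaling of the image.
#'
#' @inheritParams mean_intensity_in_mask
#' @return Unitless ratio P90/P10 (>= 1 for any sample).
#' @export
contrast_range <- function(volume, mask) {
  m <- mask_array(mask)
  if (sum(m) < 10)
    nq_stop("fewer than 10 in-mask voxels", "nigraquant_degenerate_mask")
  q <- stats::quantile(volume[m], c(0.1, 0.9), names = FALSE, type = 7)
  if (q[1] <= 0)
    nq_stop("10th percentile is non-positive; contrast range undefined",
            "nigraquant_undefined_statistic")
  q[2] / q[1]
}

#' High-signal cutoff for neuromelanin-sensitive images
#'
#' In `"fixed"` mode the cutoff is mean(background) + `nm_k` x sd(background),
#' the standard background-statistics rule in NM-MRI. In `"auc_sweep"` mode
#' the cutoff is chosen over a grid to maximise the group-separation AUC of
#' the resulting thresholded areas on a labelled calibration cohort.
#'
#' @param volume NM-sensitive [volume_image].
#' @param masks a [mask_set] providing the background region.
#' @param policy a [threshold_policy].
#' @param calibration for `"auc_sweep"` mode: a list with `areas_fun`, a
#'   function(cutoff) returning per-subject thresholded areas, and `labels`,
#'   the group factor; plus optional `grid` of candidate cutoffs.
#' @return Cutoff in a.u.
#' @export
nm_high_signal_threshold <- function(volume, masks, policy = threshold_policy(),
                                     calibration = NULL) {
  if (policy$optimization_mode == "auc_sweep") {
    nq_assert(!is.null(calibration),
              "auc_sweep mode needs a labelled calibration cohort")
    grid <- calibration$grid
    nq_assert(length(grid) >= 2, "auc_sweep needs a cutoff grid")
    aucs <- vapply(grid, function(cut) {
      a <- calibration$areas_fun(cut)
      empirical_auc_ci(a, calibration$labels, direction = "low")$auc
    }, numeric(1))
    return(grid[which.max(aucs)])
  }
  bg <- volume[mask_array_bg(masks)]
  if (length(bg) < 2 || stats::sd(bg) == 0) {
    warning("background has zero variance; cutoff falls back to its mean")
    return(mean(bg))
  }
  mean(bg) + policy$nm_k * stats::sd(bg)
}

mask_array_bg <- function(masks) {
  nq_assert(inherits(masks, "mask_set"), "need a mask_set with background")
  masks$background_mask
}

#' Mask area after thresholding
#'
#' Area (same convention as [mask_area]) of the in-mask voxels satisfying a
#' one-sided predicate: strictly above the cutoff (`">"`; NM high-signal) or
#' strictly below it (`"<"`; QSM low susceptibility, SMWI low signal).
#'
#' @inheritParams mean_intensity_in_mask
#' @param cutoff threshold value in the volume's units.
#' @param predicate `">"` or `"<"`.
#' @param voxel_dims voxel dimensions in mm.
#' @return Area in mm^2; zero when no voxel satisfies the predicate, and
#'   never larger than `mask_area(mask)`.
#' @export
thresholded_area <- function(volume, mask, cutoff, predicate = c(">", "<"),
                             voxel_dims) {
  predicate <- match.arg(predicate)
  m <- mask_array(mask)
  if (!any(m)) nq_stop("mask is empty", "nigraquant_degenerate_mask")
  v <- volume[m]
  n <- if (predicate == ">") sum(v > cutoff) else sum(v < cutoff)
  n * voxel_dims[1] * voxel_dims[2]
}

#' Synthesize susceptibility map-weighted images (SMWI)
#'
#' SMWI multiplies the SWI magnitude image by a susceptibility-derived weight
#' that suppresses high-susceptibility (iron-rich) tissue, sharpening the SN
#' margins and the nigrosome-1 substructure. The weight is a clipped linear
#' ramp: w = 1 for susceptibility <= `chi_low`, 0 for >= `chi_high`, linear
#' in between, raised to an integer `power`.
#'
#' @param qsm QSM [volume_image] in ppb.
#' @param magnitude SWI-magnitude [volume_image] on the same grid.
#' @param chi_low,chi_high ramp endpoints in ppb (`chi_low < chi_high`).
#' @param power positive integer exponent applied to the weight.
#' @return A `SMWI` [volume_image]; voxel-wise no larger than `magnitude`
#'   wherever the magnitude is non-negative.
#' @export
compute_smwi <- function(qsm, magnitude, chi_low = 70, chi_high = 170,
                         power = 4L) {
  nq_assert(chi_low < chi_high, "`chi_low` must be below `chi_high`")
  nq_assert(power >= 1, "`power` must be >= 1")
  if (!identical(dim(unclass(qsm)), dim(unclass(magnitude))))
    nq_stop("QSM and magnitude grids differ", "nigraquant_geometry_mismatch")
  w <- pmin(1, pmax(0, (chi_high - unclass(qsm)) / (chi_high - chi_low)))
  volume_image(array(unclass(magnitude) * w^as.integer(power), dim = dim(qsm)),
               voxel_dims(magnitude), "SMWI")
}

#' Extract the full SN-mask parameter vector for one subject
#'
#' Applies the whole quantitative protocol to one subject's volumes: mean
#' signal / susceptibility, NM percentile contrast range, mask areas, and the
#' three thresholded areas (NM high-signal, QSM low-susceptibility, SMWI
#' low-signal). Each modality is analysed on its own grid; the SMWI volume is
#' synthesised from QSM + magnitude via [compute_smwi] when not supplied.
#' The composite marker column is left `NA`; it is computed downstream by
#' [composite_marker].
#'
#' @param volumes named list with elements `nm`, `qsm` and either `smwi` or
#'   `mag` (SWI magnitude), each a [volume_image].
#' @param masks named list with [mask_set] elements `nm` (NM grid) and `qsm`
#'   (QSM/SMWI grid).
#' @param policy a [threshold_policy].
#' @return One-row data frame with the ten feature columns (see
#'   [reference_feature_marginals] for definitions) plus `composite = NA`.
#' @export
extract_feature_vector <- function(volumes, masks, policy = threshold_policy()) {
  nq_assert(!is.null(volumes$nm) && !is.null(volumes$qsm),
            "NM and QSM volumes are required")
  nq_assert(inherits(masks$nm, "mask_set") && inherits(masks$qsm, "mask_set"),
            "masks$nm and masks$qsm must be mask_set objects")
  vd_nm <- voxel_dims(volumes$nm)
  vd_q <- voxel_dims(volumes$qsm)

  smwi <- volumes$smwi
  if (is.null(smwi)) {
    nq_assert(!is.null(volumes$mag),
              "either an SMWI volume or a SWI magnitude volume is required")
    smwi <- compute_smwi(volumes$qsm, volumes$mag, policy$smwi_chi_low,
                         policy$smwi_chi_high, policy$smwi_power)
  }

  with_modality <- function(tag, expr) {
    tryCatch(expr, nigraquant_degenerate_mask = function(e) {
      nq_stop(paste0(tag, ": ", conditionMessage(e)),
              "nigraquant_degenerate_mask")
    })
  }

  nm_cut <- nm_high_signal_threshold(volumes$nm, masks$nm, policy)
  smwi_bg <- smwi[masks$qsm$background_mask]
  smwi_cut <- stats::quantile(smwi_bg, policy$smwi_low_quantile, names = FALSE,
                              type = 7)

  data.frame(
    nm_signal = with_modality("NM", mean_intensity_in_mask(volumes$nm, masks$nm)),
    nm_contrast_range = with_modality("NM", contrast_range(volumes$nm, masks$nm)),
    nm_size = with_modality("NM", mask_area(masks$nm, vd_nm)),
    nm_size_high = with_modality(
      "NM", thresholded_area(volumes$nm, masks$nm, nm_cut, ">", vd_nm)),
    qsm_chi_mean = with_modality("QSM", mean_intensity_in_mask(volumes$qsm, masks$qsm)),
    qsm_size = with_modality("QSM", mask_area(masks$qsm, vd_q)),
    qsm_size_low = with_modality(
      "QSM", thresholded_area(volumes$qsm, masks$qsm, policy$qsm_chi_cutoff,
                              "<", vd_q)),
    smwi_signal = with_modality("SMWI", mean_intensity_in_mask(smwi, masks$qsm)),
    smwi_size = with_modality("SMWI", mask_area(masks$qsm, vd_q)),
    smwi_size_low = with_modality(
      "SMWI", thresholded_area(smwi, masks$qsm, smwi_cut, "<", vd_q)),
    composite = NA_real_
  )
}
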