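#' Published case-control reference summaries for SN MRI parameters
#'
#' Group-level summary statistics from a large prospective case-control
#' Parkinson's disease (PD) cohort (111 healthy controls, 80 PD patients)
#' that this package uses as the default calibration of its synthetic
#' phantom and as fixed inputs for summary-level statistics (effect sizes,
#' printed-contrast arithmetic). Features follow the standard SN-mask
#' parameter set:
#'
#' * `nm_signal` — mean neuromelanin-sensitive signal intensity in the SN
#'   mask (a.u.);
#' * `nm_contrast_range` — ratio of the 90th to the 10th percentile of
#'   in-mask NM signal (unitless);
#' * `nm_size` — NM SN mask area (mm^2, three slices, both hemispheres);
#' * `nm_size_high` — NM mask area after thresholding for high-signal
#'   voxels (mm^2);
#' * `qsm_chi_mean` — mean susceptibility in the QSM SN mask (ppb);
#' * `qsm_size` — QSM SN mask area (mm^2);
#' * `qsm_size_low` — QSM mask area after thresholding for voxels with
#'   susceptibility below 70 ppb (mm^2);
#' * `smwi_signal` — mean SMWI signal intensity in the SN mask (a.u.);
#' * `smwi_size` — SMWI SN mask area (mm^2; the SMWI mask is the QSM mask);
#' * `smwi_size_low` — SMWI mask area after thresholding for low-signal
#'   voxels (mm^2).
#'
#' @return `reference_feature_marginals()`: data frame with columns
#'   `feature`, `mean_control`, `sd_control`, `mean_patient`, `sd_patient`,
#'   `censored` (whether the marginal is modelled as a normal left-censored
#'   at `floor`: the thresholded-size features, whose printed SD approaches
#'   or exceeds their mean, floored at 0, and the contrast range floored at
#'   its definitional minimum of 1), `floor`.
#' @export
reference_feature_marginals <- function() {
  data.frame(
    feature = c("nm_signal", "nm_contrast_range", "nm_size", "nm_size_high",
                "qsm_chi_mean", "qsm_size", "qsm_size_low",
                "smwi_signal", "smwi_size", "smwi_size_low"),
    mean_control = c(226.8, 1.18, 556.8, 92.3, 84.5, 277.7, 102.3,
                     171.2, 277.7, 46.2),
    sd_control   = c(36.6, 0.12, 108.1, 65.6, 27.5, 45.9, 55.9,
                     49.7, 45.9, 70.4),
    mean_patient = c(211.2, 1.10, 580.34, 29.1, 119.2, 240.6, 40.1,
                     145.9, 240.6, 83.2),
    sd_patient   = c(54.2, 0.25, 184.4, 30.6, 33.5, 56.7, 42.1,
                     35.7, 56.7, 76.6),
    censored = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
                 FALSE, FALSE, TRUE),
    floor = c(-Inf, 1, -Inf, 0, -Inf, -Inf, 0, -Inf, -Inf, 0),
    stringsAsFactors = FALSE
  )
}

#' @rdname reference_feature_marginals
#' @return `reference_clinical_marginals()`: data frame of per-group clinical
#'   score summaries (age in years; UPDRS parts I-III; MMSE 0-30; Hoehn &
#'   Yahr stage; levodopa-equivalent daily dose in mg/day, patients only).
#'   `censored` marks scores modelled as zero-censored normals.
#' @export
reference_clinical_marginals <- function() {
  data.frame(
    variable = c("age", "mmse", "updrs1", "updrs2", "updrs3", "hy", "ledd"),
    mean_control = c(65.6, 27.3, 1.6, 0.5, 3.4, 0, NA),
    sd_control   = c(6.5, 2.1, 2.9, 1.7, 4.4, 0, NA),
    mean_patient = c(65.0, 25.9, 5.6, 7.8, 29.4, 2.0, 452.9),
    sd_patient   = c(9.3, 3.0, 5.8, 6.2, 13.3, 0.5, 280.5),
    censored = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' @rdname reference_feature_marginals
#' @return `reference_spearman_targets()`: numeric matrix of full-cohort
#'   Spearman correlations between the four highly discriminant SN parameters
#'   (rows) and clinical variables (columns: age, MMSE, UPDRS-I/II/III), used
#'   as the dependence targets for the phantom's copula calibration.
#' @export
reference_spearman_targets <- function() {
  m <- rbind(
    nm_contrast_range = c(-0.051,  0.196, -0.274, -0.466, -0.532),
    nm_size_high      = c(-0.220,  0.126, -0.173, -0.372, -0.417),
    qsm_chi_mean      = c( 0.027, -0.273,  0.298,  0.453,  0.443),
    qsm_size_low      = c( 0.012,  0.272, -0.360, -0.479, -0.445)
  )
  colnames(m) <- c("age", "mmse", "updrs1", "updrs2", "updrs3")
  m
}

#' @rdname reference_feature_marginals
#' @return `reference_group_sizes()`: named vector `c(control = 111,
#'   patient = 80)`.
#' @export
reference_group_sizes <- function() c(control = 111L, patient = 80L)

#' @rdname reference_feature_marginals
#' @return `reference_sex_male_fraction()`: named vector of the per-group
#'   male fraction.
#' @export
reference_sex_male_fraction <- function() {
  c(control = 52 / 111, patient = 55 / 80)
}

#' @rdname reference_feature_marginals
#' @return `reference_reader_performance()`: data frame with the visual-rating
#'   sensitivity/specificity of four radiological readers on SMWI and
#'   NM-sensitive MRI, used as defaults for simulated reader ratings.
#' @export
reference_reader_performance <- function() {
  data.frame(
    reader = rep(1:4, 2),
    modality = rep(c("SMWI", "NM"), each = 4),
    sensitivity = c(1.00, 0.99, 0.94, 0.74, 0.81, 0.68, 1.00, 0.58),
    specificity = c(0.98, 0.96, 0.89, 0.80, 0.93, 0.93, 0.63, 0.59),
    stringsAsFactors = FALSE
  )
}

# canonical feature order used for CSV output and reports
feature_names <- function() reference_feature_marginals()$feature
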