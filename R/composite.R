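#' Composite neuromelanin-iron marker
#'
#' The composite marker is the plain product of the three best-discriminating
#' SN mask parameters: the NM percentile contrast range, the NM mask area
#' after high-signal thresholding, and the QSM mask area after thresholding
#' for susceptibility below 70 ppb,
#'
#' \deqn{\mathrm{composite} = \frac{NM_{90}}{NM_{10}} \times
#'   \mathrm{Size}_{NM,high} \times \mathrm{Size}_{QSM,low}.}
#'
#' All three factors are reduced in Parkinson's disease (narrower NM dynamic
#' range, loss of high-NM-signal voxels, loss of low-susceptibility voxels),
#' so lower values indicate the patient side. Factors enter raw, without
#' rescaling; the product is therefore strictly increasing in each argument
#' while the others are positive.
#'
#' @param nm_contrast_range unitless NM P90/P10 ratio (or a feature data
#'   frame; see Details).
#' @param nm_size_high NM high-signal thresholded area, mm^2.
#' @param qsm_size_low QSM low-susceptibility thresholded area, mm^2.
#' @details When the first argument is a data frame holding the three feature
#'   columns, the product is computed row-wise and returned as the data frame
#'   with its `composite` column filled.
#' @return Unitless composite value(s), or the augmented data frame.
#' @examples
#' composite_marker(1.18, 92.3, 102.3)  # control-mean product, about 1.11e4
#' @export
composite_marker <- function(nm_contrast_range, nm_size_high, qsm_size_low) {
  if (is.data.frame(nm_contrast_range)) {
    df <- nm_contrast_range
    df$composite <- composite_marker(df$nm_contrast_range, df$nm_size_high,
                                     df$qsm_size_low)
    return(df)
  }
  vals <- cbind(nm_contrast_range, nm_size_high, qsm_size_low)
  nq_assert(all(is.finite(vals)), "composite factors must be finite")
  if (any(vals < 0))
    nq_stop("composite factors must be non-negative",
            "nigraquant_invalid_feature")
  as.numeric(nm_contrast_range * nm_size_high * qsm_size_low)
}

#' Classify subjects by a marker cutoff
#'
#' Deterministic cutoff classification of a continuous marker. With
#' `direction = "low"` (the default, appropriate for the composite marker and
#' the individual NM/QSM factors, which are all lower in PD) values at or
#' below the cutoff are labelled `"patient"`; ties at the cutoff go to the
#' patient side, favouring sensitivity. `direction = "high"` mirrors the
#' rule.
#'
#' @param values numeric marker values, one per subject.
#' @param cutoff decision threshold.
#' @param direction which side of the cutoff is the patient side.
#' @return Factor with levels `control`, `patient`.
#' @export
classify_by_cutoff <- function(values, cutoff, direction = c("low", "high")) {
  direction <- match.arg(direction)
  patient <- if (direction == "low") values <= cutoff else values >= cutoff
  factor(ifelse(patient, "patient", "control"),
         levels = c("control", "patient"))
}
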