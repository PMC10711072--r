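# ---- group labels -----------------------------------------------------------

# normalise group labels to a logical "is patient" vector
is_patient <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- tolower(as.character(labels))
  nq_assert(all(l %in% c("control", "patient", "hc", "pd")),
            "labels must be control/patient (or HC/PD)")
  l %in% c("patient", "pd")
}

# ---- effect size ------------------------------------------------------------

#' Pooled-SD standardized mean difference (Hedges' g) from summary statistics
#'
#' Absolute difference of group means divided by the pooled standard
#' deviation, \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}. The
#' default omits the small-sample bias correction: recomputation from the
#' reference cohort's printed (mean, sd, n) shows that its tabulated effect
#' sizes are the uncorrected statistic (e.g. 1.151, not 1.146, for SN mean
#' susceptibility). Set `corrected = TRUE` for the bias-corrected variant
#' (multiplication by J = 1 - 3/(4 df - 1)).
#'
#' @param mean1,sd1,n1 summary statistics of the first group.
#' @param mean2,sd2,n2 summary statistics of the second group.
#' @param corrected apply the small-sample correction factor.
#' @return Non-negative effect size.
#' @examples
#' hedges_g(84.5, 27.5, 111, 119.2, 33.5, 80)  # 1.151
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2, corrected = FALSE) {
  nq_assert(n1 >= 2 && n2 >= 2, "need n >= 2 per group")
  nq_assert(sd1 >= 0 && sd2 >= 0, "standard deviations must be non-negative")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0)
    nq_stop("pooled variance is zero", "nigraquant_degenerate_groups")
  g <- abs(mean2 - mean1) / sqrt(sp2)
  if (corrected) g <- g * (1 - 3 / (4 * (n1 + n2 - 2) - 1))
  unname(g)
}

# ---- group comparison -------------------------------------------------------

#' Two-group comparison p-value
#'
#' Two-tailed Welch t-test or Kruskal-Wallis rank sum test. In `"auto"` mode
#' a Shapiro-Wilk normality screen (alpha = 0.05, both groups) selects the
#' t-test when neither group rejects normality and Kruskal-Wallis otherwise.
#'
#' @param values numeric vector.
#' @param labels group labels (control/patient, or logical patient flag).
#' @param method `"auto"`, `"t_test"` or `"kruskal_wallis"`.
#' @return p-value in \[0,1\] with attribute `"method"` naming the test used.
#' @export
group_compare <- function(values, labels,
                          method = c("auto", "t_test", "kruskal_wallis")) {
  method <- match.arg(method)
  pat <- is_patient(labels)
  nq_assert(any(pat) && any(!pat), "both groups must be non-empty")
  x <- values[!pat]; y <- values[pat]
  if (method == "auto") {
    normal <- function(v) {
      if (length(unique(v)) < 3) return(FALSE)
      stats::shapiro.test(v[seq_len(min(length(v), 5000))])$p.value > 0.05
    }
    method <- if (normal(x) && normal(y)) "t_test" else "kruskal_wallis"
  }
  if (method == "kruskal_wallis" && length(unique(values)) == 1)
    nq_stop("all values identical; rank test undefined",
            "nigraquant_undefined_statistic")
  p <- if (method == "t_test") {
    stats::t.test(x, y)$p.value
  } else {
    stats::kruskal.test(list(x, y))$p.value
  }
  structure(p, method = method)
}

# ---- ROC --------------------------------------------------------------------

#' Empirical AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties counted 1/2),
#' computed from ranks. The 95% confidence interval uses DeLong's
#' placement-based variance estimator. `direction` states on which side of
#' the score scale patients lie: `"high"` if patients score higher,
#' `"low"` if lower (as for the composite marker); the AUC for the reversed
#' direction is 1 - AUC.
#'
#' @param scores numeric marker values.
#' @param labels group labels (patient = positive class).
#' @param direction `"high"` or `"low"`.
#' @param conf confidence level.
#' @return List with `auc`, `ci` (length-2), `se`, `direction`, `n_patient`,
#'   `n_control`.
#' @export
empirical_auc_ci <- function(scores, labels, direction = c("high", "low"),
                             conf = 0.95) {
  direction <- match.arg(direction)
  pat <- is_patient(labels)
  if (!any(pat) || !any(!pat))
    nq_stop("ROC needs both classes present", "nigraquant_undefined_roc")
  s <- if (direction == "low") -as.numeric(scores) else as.numeric(scores)
  x <- s[pat]; y <- s[!pat]           # positives, negatives
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n           # placements of positives
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m   # placements of negatives
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  list(auc = auc, ci = ci, se = se, direction = direction,
       n_patient = m, n_control = n)
}

#' ROC curve points
#'
#' Sensitivity/1-specificity pairs over all observed cutoffs, suitable for
#' plotting an ROC curve. Classification follows [classify_by_cutoff] (ties
#' at the cutoff go to the patient side).
#'
#' @inheritParams empirical_auc_ci
#' @return Data frame with `cutoff`, `fpr`, `tpr`, ordered by increasing fpr.
#' @export
roc_points <- function(scores, labels, direction = c("high", "low")) {
  direction <- match.arg(direction)
  pat <- is_patient(labels)
  cuts <- sort(unique(as.numeric(scores)))
  cuts <- if (direction == "low") c(-Inf, cuts) else c(cuts, Inf)
  pts <- vapply(cuts, function(cut) {
    pred <- classify_by_cutoff(scores, cut, direction) == "patient"
    c(fpr = mean(pred[!pat]), tpr = mean(pred[pat]))
  }, numeric(2))
  out <- data.frame(cutoff = cuts, fpr = pts["fpr", ], tpr = pts["tpr", ])
  out[order(out$fpr, out$tpr), ]
}

#' Youden-optimal operating point
#'
#' Scans all observed cutoffs and returns the one maximising Youden's
#' J = sensitivity + specificity - 1; ties are broken toward the higher
#' specificity. Accuracy is evaluated at the selected cutoff.
#'
#' @inheritParams empirical_auc_ci
#' @return List of class `operating_point` with `cutoff`, `sensitivity`,
#'   `specificity`, `accuracy`, `youden_j`.
#' @export
youden_operating_point <- function(scores, labels,
                                   direction = c("high", "low")) {
  direction <- match.arg(direction)
  pat <- is_patient(labels)
  if (!any(pat) || !any(!pat))
    nq_stop("ROC needs both classes present", "nigraquant_undefined_roc")
  cuts <- sort(unique(as.numeric(scores)))
  cuts <- if (direction == "low") c(-Inf, cuts) else c(cuts, Inf)
  stats_at <- function(cut) {
    pred <- classify_by_cutoff(scores, cut, direction) == "patient"
    sens <- mean(pred[pat]); spec <- mean(!pred[!pat])
    c(sens = sens, spec = spec, j = sens + spec - 1,
      acc = mean(pred == pat))
  }
  tab <- t(vapply(cuts, stats_at, numeric(4)))
  best <- order(-tab[, "j"], -tab[, "spec"])[1]
  structure(list(cutoff = cuts[best],
                 sensitivity = unname(tab[best, "sens"]),
                 specificity = unname(tab[best, "spec"]),
                 accuracy = unname(tab[best, "acc"]),
                 youden_j = unname(tab[best, "j"]),
                 direction = direction),
            class = "operating_point")
}

# ---- correlation table ------------------------------------------------------

#' Spearman correlation table with Bonferroni family correction
#'
#' Spearman rank correlations (average ranks for ties) between each imaging
#' feature and each clinical variable, with a significance flag at the
#' Bonferroni-adjusted level alpha / (number of cells in the family). Cells
#' with fewer than 3 complete pairs are returned as `NA` and do not count
#' toward the family size.
#'
#' @param features data frame of imaging features (rows = subjects).
#' @param clinical data frame of clinical variables, same row order.
#' @param feature_cols,clinical_cols column names defining the grid.
#' @param alpha family-wise significance level.
#' @return Long data frame with columns `feature`, `variable`, `r`, `p`,
#'   `significant`; attributes `family_size` and `alpha_adjusted`.
#' @export
spearman_bonferroni_table <- function(features, clinical,
                                      feature_cols = intersect(rownames(reference_spearman_targets()), names(features)),
                                      clinical_cols = intersect(colnames(reference_spearman_targets()), names(clinical)),
                                      alpha = 0.05) {
  nq_assert(nrow(features) == nrow(clinical),
            "feature and clinical tables must align by row")
  grid <- expand.grid(feature = feature_cols, variable = clinical_cols,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0)
    return(structure(data.frame(feature = character(), variable = character(),
                                r = numeric(), p = numeric(),
                                significant = logical()),
                     family_size = 0L, alpha_adjusted = NA_real_))
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    x <- features[[grid$feature[i]]]
    y <- clinical[[grid$variable[i]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) return(c(r = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  cells <- do.call(rbind, cells)
  family <- sum(!is.na(cells[, "p"]))
  out <- data.frame(grid, r = cells[, "r"], p = cells[, "p"])
  out$significant <- ifelse(is.na(out$p), NA, out$p < alpha / family)
  structure(out, family_size = family, alpha_adjusted = alpha / family)
}

# ---- agreement --------------------------------------------------------------

agreement_result <- function(statistic, value, n_subjects, n_raters) {
  structure(list(statistic = statistic, value = value,
                 n_subjects = n_subjects, n_raters = n_raters),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (%d subjects, %d raters)\n", x$statistic, x$value,
              x$n_subjects, x$n_raters))
  invisible(x)
}

#' Intraclass correlation, two-way random, absolute agreement, single measure
#'
#' ICC(2,1) from the two-way ANOVA mean squares of a complete
#' subjects-by-raters matrix:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' residual mean squares. Because rater bias enters the denominator, a
#' constant offset added to one rater lowers the coefficient (absolute
#' agreement, not consistency).
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns, no
#'   missing values.
#' @return An `agreement_result` with `statistic = "icc"`.
#' @export
icc_absolute_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  nq_assert(n >= 2 && k >= 2, "need >= 2 subjects and >= 2 raters")
  nq_assert(all(is.finite(ratings)), "ratings matrix must be complete")
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  sse <- sum((ratings - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0)
    nq_stop("no between-subject variance; ICC undefined",
            "nigraquant_degenerate_design")
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  agreement_result("icc", val, n, k)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for a complete subjects-by-raters matrix of
#' categorical ratings, using the standard observed-agreement
#' (\eqn{\bar P}) and chance-agreement (\eqn{\bar P_e}) construction.
#'
#' @param ratings matrix (subjects x raters) of categorical ratings.
#' @param categories optional vector of all possible categories (defaults to
#'   those observed).
#' @return An `agreement_result` with `statistic = "fleiss_kappa"`.
#' @export
fleiss_kappa <- function(ratings, categories = NULL) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  nq_assert(n >= 2 && k >= 2, "need >= 2 subjects and >= 2 raters")
  if (is.null(categories)) categories <- sort(unique(as.vector(ratings)))
  counts <- vapply(categories, function(cat) rowSums(ratings == cat),
                   numeric(n))
  dim(counts) <- c(n, length(categories))
  p_i <- (rowSums(counts^2) - k) / (k * (k - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * k)
  p_e <- sum(p_j^2)
  if (p_e >= 1)
    nq_stop("all ratings in a single category; kappa undefined",
            "nigraquant_undefined_statistic")
  agreement_result("fleiss_kappa", (p_bar - p_e) / (1 - p_e), n, k)
}

#' Cohen's kappa for two raters
#'
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with the chance agreement from the
#' product of the marginal rating distributions.
#'
#' @param ratings_a,ratings_b paired categorical ratings from two raters.
#' @return An `agreement_result` with `statistic = "cohen_kappa"`.
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  nq_assert(length(ratings_a) == length(ratings_b),
            "raters must rate the same subjects")
  lev <- sort(unique(c(as.vector(ratings_a), as.vector(ratings_b))))
  a <- factor(ratings_a, levels = lev); b <- factor(ratings_b, levels = lev)
  tab <- table(a, b) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe >= 1)
    nq_stop("degenerate marginals; kappa undefined",
            "nigraquant_undefined_statistic")
  agreement_result("cohen_kappa", (po - pe) / (1 - pe), length(a), 2L)
}

# ---- relative differences ---------------------------------------------------

#' Ratio and percent contrasts between group means
#'
#' Summarises group differences the way radiology papers quote them: the
#' percent reduction in patients relative to controls, the patient/control
#' and control/patient mean ratios, and - for features paired with their
#' unthresholded parent mask - the thresholding magnification, i.e. the
#' ratio of the absolute relative group difference after thresholding to the
#' one before.
#'
#' @param summary data frame with columns `feature`, `mean_control`,
#'   `mean_patient` (e.g. [reference_feature_marginals] or a
#'   [group_feature_summary] result).
#' @param threshold_pairs named character vector mapping each thresholded
#'   feature to its unthresholded parent (defaults to the standard three
#'   pairs).
#' @return Data frame with `feature`, `pct_reduction`,
#'   `ratio_patient_control`, `ratio_control_patient`, `magnification`
#'   (`NA` where no pairing applies).
#' @export
relative_difference_summary <- function(summary,
                                        threshold_pairs = c(nm_size_high = "nm_size",
                                                            qsm_size_low = "qsm_size",
                                                            smwi_size_low = "smwi_size")) {
  nq_assert(all(c("feature", "mean_control", "mean_patient") %in% names(summary)),
            "summary needs feature/mean_control/mean_patient columns")
  mc <- summary$mean_control; mp <- summary$mean_patient
  if (any(mc == 0, na.rm = TRUE))
    nq_stop("zero control mean; relative contrast undefined",
            "nigraquant_undefined_statistic")
  rel <- abs(mc - mp) / mc
  out <- data.frame(
    feature = summary$feature,
    pct_reduction = 100 * (mc - mp) / mc,
    ratio_patient_control = mp / mc,
    ratio_control_patient = mc / mp,
    magnification = NA_real_,
    stringsAsFactors = FALSE
  )
  for (thr in names(threshold_pairs)) {
    base <- threshold_pairs[[thr]]
    i <- match(thr, out$feature); j <- match(base, summary$feature)
    if (!is.na(i) && !is.na(j) && rel[j] > 0)
      out$magnification[i] <- rel[i] / rel[j]
  }
  out
}

# ---- per-feature group summary ---------------------------------------------

#' Per-feature group summary with effect size and ROC
#'
#' Builds the standard group-difference table for a cohort: per-group n,
#' mean and sd, comparison p-value, pooled-SD effect size, and the AUC (with
#' DeLong CI) in the feature's discriminating direction (chosen so that
#' AUC >= 0.5 on the observed data).
#'
#' @param features data frame of per-subject features.
#' @param labels group labels aligned with `features` rows.
#' @param feature_cols features to summarise.
#' @param method comparison test passed to [group_compare].
#' @return Data frame, one row per feature.
#' @export
group_feature_summary <- function(features, labels,
                                  feature_cols = intersect(feature_names(), names(features)),
                                  method = "auto") {
  pat <- is_patient(labels)
  rows <- lapply(feature_cols, function(f) {
    v <- features[[f]]
    x <- v[!pat]; y <- v[pat]
    p <- group_compare(v, pat, method)
    dir <- if (mean(y) >= mean(x)) "high" else "low"
    roc <- empirical_auc_ci(v, pat, direction = dir)
    data.frame(feature = f,
               n_control = length(x), mean_control = mean(x), sd_control = stats::sd(x),
               n_patient = length(y), mean_patient = mean(y), sd_patient = stats::sd(y),
               p_value = as.numeric(p), test = attr(p, "method"),
               hedges_g = hedges_g(mean(x), stats::sd(x), length(x),
                                   mean(y), stats::sd(y), length(y)),
               auc = roc$auc, auc_lo = roc$ci[1], auc_hi = roc$ci[2],
               auc_direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
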