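test_that("pooled-SD effect sizes reproduce the reference values and basic identities", {
  # published cohort summaries: (mean, sd) per group at n = 111 / 80
  expect_equal(round(hedges_g(84.5, 27.5, 111, 119.2, 33.5, 80), 3), 1.151)
  expect_equal(round(hedges_g(1.18, 0.12, 111, 1.10, 0.25, 80), 3), 0.431)
  expect_equal(hedges_g(0, 1, 2, 1, 1, 2), 1)
  expect_equal(hedges_g(5, 2, 30, 5, 2, 30), 0)
  # the small-sample correction shrinks the estimate
  expect_lt(hedges_g(84.5, 27.5, 111, 119.2, 33.5, 80, corrected = TRUE),
            hedges_g(84.5, 27.5, 111, 119.2, 33.5, 80))
  expect_error(hedges_g(1, 0, 10, 1, 0, 10),
               class = "nigraquant_degenerate_groups")
})

test_that("group comparison selects sensible tests and calibrated p-values", {
  x <- c(1.2, 1.9, 2.4, 3.1, 2.2, 1.8, 2.6, 2.0)
  p <- group_compare(c(x, x), rep(c("control", "patient"), each = 8),
                     method = "t_test")
  expect_equal(as.numeric(p), 1)
  set.seed(41)
  v <- c(rnorm(50), rnorm(50, 3))
  p2 <- group_compare(v, rep(c("control", "patient"), each = 50))
  expect_lt(as.numeric(p2), 1e-4)
  expect_error(group_compare(rep(1, 20), rep(c("control", "patient"), 10),
                             method = "kruskal_wallis"),
               class = "nigraquant_undefined_statistic")

  # p-values are uniform under the null (KS check over seeded replicates)
  set.seed(43)
  ps <- vapply(1:80, function(i) {
    v <- rnorm(80)
    as.numeric(group_compare(v, rep(c("control", "patient"), 40),
                             method = "t_test"))
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("empirical AUC equals brute-force pair counting and DeLong matches pROC", {
  set.seed(47)
  for (i in 1:12) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    s <- c(round(rnorm(n1, 0.8), 1), round(rnorm(n0), 1))  # ties likely
    lab <- rep(c("patient", "control"), c(n1, n0))
    mine <- empirical_auc_ci(s, lab, "high")
    x <- s[lab == "patient"]; y <- s[lab == "control"]
    bf <- mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(mine$auc, bf)
    expect_equal(empirical_auc_ci(s, lab, "low")$auc, 1 - bf)
  }
  expect_equal(empirical_auc_ci(c(5, 6, 1, 2), c("patient", "patient",
                                                 "control", "control"),
                                "high")$auc, 1)
  expect_equal(empirical_auc_ci(rep(2, 10), rep(c("patient", "control"), 5),
                                "high")$auc, 0.5)
  expect_error(empirical_auc_ci(1:4, rep("control", 4)),
               class = "nigraquant_undefined_roc")

  # DeLong interval against the independent pROC implementation
  set.seed(53)
  s <- rnorm(120) + rep(c(0, 1.2), 60)
  lab <- rep(c("control", "patient"), 60)
  mine <- empirical_auc_ci(s, lab, "high")
  pr <- suppressMessages(pROC::roc(lab, s, levels = c("control", "patient"),
                                   direction = "<"))
  ci <- suppressMessages(pROC::ci.auc(pr, method = "delong"))
  expect_equal(mine$auc, as.numeric(pROC::auc(pr)))
  expect_equal(mine$ci, as.numeric(ci)[c(1, 3)], tolerance = 1e-10)
})

test_that("the Youden operating point matches an exhaustive scan", {
  s <- c(1, 2, 3, 10, 11, 12)
  lab <- rep(c("patient", "control"), each = 3)
  op <- youden_operating_point(s, lab, "low")
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$accuracy, 1)

  set.seed(59)
  for (i in 1:8) {
    s <- round(rnorm(20), 1)
    lab <- sample(rep(c("patient", "control"), 10))
    op <- youden_operating_point(s, lab, "high")
    pat <- lab == "patient"
    best_j <- max(vapply(c(sort(unique(s)), Inf), function(cut) {
      pred <- s >= cut
      mean(pred[pat]) + mean(!pred[!pat]) - 1
    }, numeric(1)))
    expect_equal(op$youden_j, best_j)
    # swapping labels and direction preserves the attainable J
    lab2 <- ifelse(pat, "control", "patient")
    op2 <- youden_operating_point(s, lab2, "low")
    expect_equal(op2$youden_j, op$youden_j, tolerance = 1e-12)
  }
})

test_that("Spearman tables match a direct rank computation with Bonferroni flags", {
  f <- data.frame(a = c(3, 1, 4, 1, 5, 9, 2, 6))
  cl <- data.frame(u = c(2, 7, 1, 8, 2, 8, 1, 8), v = 8:1)
  tab <- spearman_bonferroni_table(f, cl, feature_cols = "a",
                                   clinical_cols = c("u", "v"))
  # independent oracle: Pearson correlation of average ranks
  oracle <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(tab$r[tab$variable == "u"], oracle(f$a, cl$u))
  expect_equal(tab$r[tab$variable == "v"], oracle(f$a, cl$v))
  expect_equal(attr(tab, "family_size"), 2)
  expect_equal(attr(tab, "alpha_adjusted"), 0.025)

  mono <- data.frame(m = 1:10)
  cl2 <- data.frame(up = (1:10)^2, down = -exp(1:10))
  t2 <- spearman_bonferroni_table(mono, cl2, "m", c("up", "down"))
  expect_equal(t2$r, c(1, -1))
  # too few complete pairs leaves the cell undefined
  f3 <- data.frame(a = c(1, 2, NA, NA, NA, NA))
  c3 <- data.frame(b = c(1, NA, 3, 4, 5, 6))
  t3 <- spearman_bonferroni_table(f3, c3, "a", "b")
  expect_true(is.na(t3$r))
})

test_that("ICC(2,1) reproduces hand-computed ANOVA mean squares", {
  x <- matrix(c(9, 2, 5, 8, 2, 1, 2, 3), 4, 2)
  # hand ANOVA: grand mean 4; MSR = 22/3, MSC = 32, MSE = 10/3
  gm <- mean(x)
  msr <- 2 * sum((rowMeans(x) - gm)^2) / 3
  msc <- 4 * sum((colMeans(x) - gm)^2) / 1
  sse <- sum((x - outer(rowMeans(x), c(1, 1)) -
                outer(c(1, 1, 1, 1), colMeans(x)) + gm)^2)
  mse <- sse / 3
  expected <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 4)
  expect_equal(icc_absolute_agreement(x)$value, expected)
  expect_equal(icc_absolute_agreement(x)$value, 0.16)

  ident <- cbind(c(1, 5, 9, 4), c(1, 5, 9, 4))
  expect_equal(icc_absolute_agreement(ident)$value, 1)
  # a constant rater offset lowers absolute agreement
  offset <- cbind(c(1, 5, 9, 4), c(1, 5, 9, 4) + 3)
  expect_lt(icc_absolute_agreement(offset)$value, 1)
  expect_error(icc_absolute_agreement(matrix(1, 3, 2)),
               class = "nigraquant_degenerate_design")
})

test_that("Fleiss and Cohen kappa match their closed-form constructions", {
  m <- matrix(c("A", "A", "B",
                "B", "B", "B",
                "A", "B", "A",
                "A", "A", "A",
                "B", "A", "B",
                "B", "B", "A"), 6, 3, byrow = TRUE)
  # direct formula: P_i = (sum n_ij^2 - k) / (k (k-1)); Pe from category props
  counts <- t(apply(m, 1, function(r) c(sum(r == "A"), sum(r == "B"))))
  p_i <- (rowSums(counts^2) - 3) / 6
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / 18
  p_e <- sum(p_j^2)
  expect_equal(fleiss_kappa(m)$value, (p_bar - p_e) / (1 - p_e))

  unan <- matrix(rep(c("A", "B", "A", "B"), each = 3), 4, 3, byrow = TRUE)
  expect_equal(fleiss_kappa(unan)$value, 1)
  expect_error(fleiss_kappa(matrix("A", 4, 3)),
               class = "nigraquant_undefined_statistic")
  set.seed(61)
  rnd <- matrix(sample(c("A", "B"), 3000, TRUE), 1000, 3)
  expect_lt(abs(fleiss_kappa(rnd)$value), 0.05)

  # Cohen 2x2 contingency (40, 5, 5, 30): po = 70/80, pe from marginals
  a <- rep(c("PD", "PD", "non-PD", "non-PD"), c(40, 5, 5, 30))
  b <- rep(c("PD", "non-PD", "PD", "non-PD"), c(40, 5, 5, 30))
  po <- 70 / 80
  pe <- (45 / 80) * (45 / 80) + (35 / 80) * (35 / 80)
  expect_equal(cohen_kappa(a, b)$value, (po - pe) / (1 - pe))
  expect_equal(cohen_kappa(b, b)$value, 1)
  # independent cross-check against e1071
  set.seed(67)
  r1 <- sample(c("PD", "non-PD"), 200, TRUE)
  r2 <- sample(c("PD", "non-PD"), 200, TRUE, prob = c(0.6, 0.4))
  expect_equal(cohen_kappa(r1, r2)$value,
               e1071::classAgreement(table(r1, r2))$kappa)
  expect_lt(abs(cohen_kappa(r1, r2)$value), 0.15)
})

test_that("relative-difference summaries reproduce the published contrasts", {
  fm <- reference_feature_marginals()
  rd <- relative_difference_summary(fm)
  get <- function(col, f) rd[[col]][rd$feature == f]
  expect_equal(round(get("pct_reduction", "qsm_size")), 13)
  expect_equal(round(get("ratio_patient_control", "smwi_size_low"), 1), 1.8)
  expect_gte(get("ratio_control_patient", "nm_size_high"), 3)
  expect_equal(round(get("magnification", "qsm_size_low"), 1), 4.6)

  eq <- data.frame(feature = "x", mean_control = 5, mean_patient = 5)
  rde <- relative_difference_summary(eq, threshold_pairs = character(0))
  expect_equal(rde$pct_reduction, 0)
  expect_equal(rde$ratio_patient_control, 1)
  bad <- data.frame(feature = "x", mean_control = 0, mean_patient = 5)
  expect_error(relative_difference_summary(bad, threshold_pairs = character(0)),
               class = "nigraquant_undefined_statistic")
})

test_that("the per-feature group summary assembles consistent statistics", {
  cfg <- calibrated_config()
  fe <- cohort_features(generate_cohort(cfg))
  gs <- group_feature_summary(fe, fe$group)
  expect_equal(nrow(gs), 10)
  expect_true(all(gs$auc >= 0.5 & gs$auc <= 1))
  expect_true(all(gs$auc_lo <= gs$auc & gs$auc <= gs$auc_hi))
  expect_true(all(gs$p_value >= 0 & gs$p_value <= 1))
  i <- gs$feature == "qsm_chi_mean"
  expect_equal(gs$hedges_g[i],
               hedges_g(gs$mean_control[i], gs$sd_control[i], gs$n_control[i],
                        gs$mean_patient[i], gs$sd_patient[i], gs$n_patient[i]))
  expect_equal(gs$auc_direction[i], "high")  # iron is higher in patients
})
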