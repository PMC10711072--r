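# ---- zero-censored normal marginals ----------------------------------------

# moments of Y = max(0, X), X ~ N(mu, sigma)
censored_normal_moments <- function(mu, sigma) {
  mu <- unname(mu); sigma <- unname(sigma)
  a <- mu / sigma
  p <- stats::pnorm(a); ph <- stats::dnorm(a)
  m <- mu * p + sigma * ph
  m2 <- (mu^2 + sigma^2) * p + mu * sigma * ph
  c(mean = m, sd = sqrt(max(m2 - m^2, 0)))
}

#' Latent parameters of a zero-censored normal with given moments
#'
#' Finds (mu, sigma) such that max(0, N(mu, sigma)) has the requested mean
#' and standard deviation. Used for the size-after-thresholding features and
#' the heavily floored clinical scores, whose published SD approaches or
#' exceeds their mean so a plain normal would put substantial mass below
#' zero.
#'
#' @param mean,sd target moments of the censored variable (`mean > 0`,
#'   `sd >= 0`).
#' @return Named vector `c(mu, sigma)` of the latent normal.
#' @export
censored_normal_params <- function(mean, sd) {
  nq_assert(mean > 0 && sd >= 0, "need mean > 0 and sd >= 0")
  if (sd == 0) return(c(mu = mean, sigma = 0))
  obj <- function(par) {
    mm <- censored_normal_moments(par[1], exp(par[2]))
    (mm["mean"] / mean - 1)^2 + (mm["sd"] / sd - 1)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$value > 1e-6)
    warning(sprintf("censored-normal fit imperfect (residual %.2g) for mean=%g sd=%g",
                    fit$value, mean, sd))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# transform standard-normal scores to a group marginal; a censored marginal
# is `floor` plus a zero-censored normal whose latent parameters are solved
# so the target moments hold exactly
marginal_transform <- function(z, mean, sd, censored = FALSE, floor = 0,
                               lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, length(z)))
  if (censored) {
    par <- censored_normal_params(mean - floor, sd)
    floor + pmax(0, par["mu"] + par["sigma"] * z)
  } else {
    pmin(upper, pmax(lower, mean + sd * z))
  }
}

# ---- configuration ----------------------------------------------------------

#' Configuration of the synthetic midbrain phantom cohort
#'
#' Defines the study conditions the phantom emulates: per-group sample sizes,
#' per-group marginal (mean, sd) distributions for the ten SN-mask features
#' and the clinical scores, and the target full-cohort Spearman correlations
#' between imaging and clinical variables. Defaults reproduce the reference
#' case-control cohort (111 controls / 80 patients). Features and clinical
#' scores are coupled through a single latent disease-severity factor in a
#' Gaussian copula (see [calibrate_copula]), so the printed sign pattern and
#' magnitude of the imaging-clinical rank correlations are approached in
#' expectation while each marginal is matched exactly.
#'
#' @param n_controls,n_patients per-group sample sizes.
#' @param seed RNG seed for cohort generation.
#' @param feature_marginals data frame as [reference_feature_marginals].
#' @param clinical_marginals data frame as [reference_clinical_marginals].
#' @param target_rank_correlations feature x clinical Spearman target matrix
#'   as [reference_spearman_targets].
#' @param gradient_strength unitless scaling of the posterolateral-to-
#'   anteromedial NM depigmentation gradient in rendered volumes (1 = the
#'   calibrated default).
#' @param noise_sd additive Gaussian image-noise SD (a.u. / ppb) for rendered
#'   volumes; 0 gives exactly reproducible painted statistics.
#' @param voxel_dims_nm,voxel_dims_qsm voxel dimensions (mm) of the NM and
#'   QSM/SMWI grids.
#' @param image_level if `TRUE`, [generate_cohort] renders full volumes and
#'   masks per subject; otherwise only feature tables are simulated.
#' @param loadings optional pre-calibrated copula loadings (filled by
#'   [calibrate_copula]; computed on demand otherwise).
#' @param severity_shift mean latent-severity offset of patients relative to
#'   controls (SD units of the within-group severity factor).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_controls = 111, n_patients = 80, seed = 1L,
                           feature_marginals = reference_feature_marginals(),
                           clinical_marginals = reference_clinical_marginals(),
                           target_rank_correlations = reference_spearman_targets(),
                           gradient_strength = 1, noise_sd = 0,
                           voxel_dims_nm = c(0.5, 0.5, 3),
                           voxel_dims_qsm = c(0.5, 0.5, 1),
                           image_level = FALSE,
                           loadings = NULL,
                           severity_shift = 2) {
  nq_assert(n_controls > 0 && n_patients > 0, "group sizes must be positive")
  nq_assert(all(c(feature_marginals$sd_control, feature_marginals$sd_patient,
                  stats::na.omit(c(clinical_marginals$sd_control,
                                   clinical_marginals$sd_patient))) >= 0),
            "all marginal sds must be non-negative")
  nq_assert(all(abs(target_rank_correlations) <= 1, na.rm = TRUE),
            "correlation targets must lie in [-1, 1]")
  nq_assert(all(voxel_dims_nm > 0) && all(voxel_dims_qsm > 0),
            "voxel dimensions must be positive")
  nq_assert(noise_sd >= 0, "noise_sd must be non-negative")
  # feasibility of the dependence structure: a full square joint target must
  # be positive semi-definite on the Pearson scale. A rectangular
  # feature x clinical cross block carries no such constraint on its own
  # (the features are themselves correlated through severity); its
  # realisability is bounded by the one-factor loadings during calibration.
  if (!is.null(rownames(target_rank_correlations)) &&
      identical(rownames(target_rank_correlations),
                colnames(target_rank_correlations))) {
    pearson <- 2 * sin(pi / 6 * target_rank_correlations)
    if (min(eigen(pearson, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      nq_stop("correlation target matrix is not positive semi-definite",
              "nigraquant_infeasible_dependence")
  }
  structure(list(n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 feature_marginals = feature_marginals,
                 clinical_marginals = clinical_marginals,
                 target_rank_correlations = target_rank_correlations,
                 gradient_strength = gradient_strength,
                 noise_sd = noise_sd,
                 voxel_dims_nm = as.numeric(voxel_dims_nm),
                 voxel_dims_qsm = as.numeric(voxel_dims_qsm),
                 image_level = isTRUE(image_level),
                 loadings = loadings,
                 severity_shift = severity_shift),
            class = "phantom_config")
}

# clinical variables that get their own orthogonal auxiliary factor in
# addition to the shared severity factor, and the fixed loading of each
# score on its own factor; per-feature loadings on these factors absorb the
# residual structure a strict one-factor severity model cannot represent
aux_clinical_vars <- function() c("mmse", "updrs1", "updrs2", "updrs3")
AUX_MU <- 0.4

# default (uncalibrated) copula loadings; signs follow the group-difference
# direction of each feature, magnitudes are starting points for calibration
default_loadings <- function(config) {
  feat <- c(nm_signal = -0.30, nm_contrast_range = -0.35, nm_size = 0.15,
            nm_size_high = -0.35, qsm_chi_mean = 0.35, qsm_size = -0.45,
            qsm_size_low = -0.35, smwi_signal = -0.45, smwi_size = -0.45,
            smwi_size_low = 0.45)
  clin <- c(age = 0, mmse = -0.45, updrs1 = 0.50, updrs2 = 0.85, updrs3 = 0.90)
  gamma <- c(nm_signal = 0, nm_contrast_range = 0, nm_size = 0,
             nm_size_high = -0.25, qsm_chi_mean = 0, qsm_size = 0,
             qsm_size_low = 0, smwi_signal = 0, smwi_size = 0,
             smwi_size_low = 0)
  fn <- config$feature_marginals$feature
  aux <- matrix(0, length(fn), length(aux_clinical_vars()),
                dimnames = list(fn, aux_clinical_vars()))
  list(feature = feat[fn], clinical = clin, gamma_age = gamma[fn], aux = aux)
}

# Gaussian score of one feature given the latent factors and its noise
feature_score <- function(f, load, z_sev, z_age, z_aux, eps) {
  lam <- load$feature[f]; gam <- load$gamma_age[f]; a <- load$aux[f, ]
  res <- 1 - lam^2 - gam^2 - sum(a^2)
  nq_assert(res >= 0, "feature loading norm exceeds 1")
  lam * z_sev + gam * z_age + as.vector(z_aux %*% a) + sqrt(res) * eps
}

# Gaussian score of one clinical variable
clinical_score <- function(v, load, z_sev, z_aux, eps) {
  lam <- if (v %in% names(load$clinical)) load$clinical[v] else 0
  mu <- if (v %in% aux_clinical_vars()) AUX_MU else 0
  z <- lam * z_sev + sqrt(max(0, 1 - lam^2 - mu^2)) * eps
  if (mu > 0) z <- z + mu * z_aux[, v]
  z
}

# ---- latent scores -> values -----------------------------------------------

clin_row <- function(cm, var) cm[match(var, cm$variable), ]
feat_row <- function(fm, f) fm[match(f, fm$feature), ]

clinical_value <- function(var, group, z, config) {
  r <- clin_row(config$clinical_marginals, var)
  m <- ifelse(group == "patient", r$mean_patient, r$mean_control)
  s <- ifelse(group == "patient", r$sd_patient, r$sd_control)
  upper <- if (var == "mmse") 30 else if (var == "hy") 5 else Inf
  lower <- if (var %in% c("mmse", "hy")) 0 else -Inf
  out <- numeric(length(z))
  for (g in unique(group)) {
    i <- group == g
    if (any(is.na(c(m[i][1], s[i][1])))) { out[i] <- NA_real_; next }
    out[i] <- marginal_transform(z[i], m[i][1], s[i][1],
                                 censored = r$censored, lower = lower,
                                 upper = upper)
  }
  out
}

feature_value <- function(f, group, z, config) {
  r <- feat_row(config$feature_marginals, f)
  adj <- config$marginal_adjust
  out <- numeric(length(z))
  for (g in unique(group)) {
    i <- group == g
    # calibrated latent parameters override the closed-form censored fit for
    # features whose parent-size clamp measurably distorts the moments
    if (!is.null(adj) && !is.null(adj[[f]][[g]])) {
      p <- adj[[f]][[g]]
      out[i] <- pmax(0, p[1] + p[2] * z[i])
    } else {
      m <- if (g == "patient") r$mean_patient else r$mean_control
      s <- if (g == "patient") r$sd_patient else r$sd_control
      out[i] <- marginal_transform(z[i], m, s, censored = r$censored,
                                   floor = if (is.finite(r$floor)) r$floor else 0)
    }
  }
  out
}

# parent mask feature of each thresholded-size feature
threshold_parents <- function() {
  c(nm_size_high = "nm_size", qsm_size_low = "qsm_size",
    smwi_size_low = "smwi_size")
}

# ---- copula calibration -----------------------------------------------------

#' Calibrate the phantom's latent-severity copula to Spearman targets
#'
#' The phantom couples imaging features and clinical scores through a single
#' latent disease-severity factor per subject: each variable's Gaussian score
#' is `lambda * z_severity + gamma * z_age + sqrt(1 - lambda^2 - gamma^2) *
#' noise`, then pushed through its per-group marginal. Full-cohort rank
#' correlations arise from two sources - the group separation encoded in the
#' marginals, and the within-group factor loadings - so the loadings are
#' calibrated numerically: a large common-random-number calibration cohort is
#' simulated once, and coordinate-descent grid sweeps over the feature and
#' clinical loadings minimise the squared error against the target Spearman
#' matrix. The age loading of the NM thresholded size is fitted against its
#' own target in a final pass. Calibration uses a fixed internal RNG stream,
#' so the fitted loadings are a deterministic function of the targets and do
#' not depend on the cohort seed.
#'
#' @param config a [phantom_config].
#' @param n_scale calibration-cohort size as a multiple of the configured
#'   cohort size (with a floor of about 4000 subjects).
#' @param grid_step grid resolution for the loading sweeps.
#' @param sweeps number of feature/clinical coordinate-descent sweeps.
#' @return The config with `loadings` filled and a `calibration` element
#'   holding the achieved calibration-cohort Spearman matrix.
#' @export
calibrate_copula <- function(config, n_scale = 25, grid_step = 0.05,
                             sweeps = 2) {
  load <- default_loadings(config)
  targets <- config$target_rank_correlations
  t_feats <- intersect(rownames(targets), names(load$feature))
  t_clin <- intersect(colnames(targets), names(load$clinical))
  t_clin_sev <- intersect(t_clin, aux_clinical_vars())

  n_tot <- config$n_controls + config$n_patients
  mult <- max(n_scale, ceiling(4000 / n_tot))
  group <- rep(c("control", "patient"),
               c(config$n_controls, config$n_patients) * mult)
  n <- length(group)
  aux_v <- aux_clinical_vars()

  with_seed(20231127L, {
    z_sev <- stats::rnorm(n)
    z_age <- stats::rnorm(n)
    z_aux <- matrix(stats::rnorm(n * length(aux_v)), n,
                    dimnames = list(NULL, aux_v))
    eps_c <- matrix(stats::rnorm(n * length(t_clin_sev)), n,
                    dimnames = list(NULL, t_clin_sev))
    eps_f <- matrix(stats::rnorm(n * length(load$feature)), n,
                    dimnames = list(NULL, names(load$feature)))
  })

  clin_vals <- function(ld) {
    sapply(t_clin_sev, function(v)
      clinical_value(v, group,
                     clinical_score(v, ld, z_sev, z_aux, eps_c[, v]), config))
  }
  feat_val <- function(f, ld) {
    feature_value(f, group,
                  feature_score(f, ld, z_sev, z_age, z_aux, eps_f[, f]),
                  config)
  }

  grid <- seq(-0.9, 0.9, grid_step)
  # the severity loading of each feature is sign-constrained to its disease
  # direction (the sign of the patient-control mean difference), so that
  # increasing latent severity always moves a feature the way the disease
  # does; the orthogonal auxiliary factors absorb the residual dependence
  fdir <- sign(config$feature_marginals$mean_patient -
                 config$feature_marginals$mean_control)
  names(fdir) <- config$feature_marginals$feature
  cv <- clin_vals(load)
  # stage 1/2: coordinate-descent sweeps over the shared severity loadings
  for (s in seq_len(sweeps)) {
    for (f in t_feats) {
      budget <- load$gamma_age[f]^2 + sum(load$aux[f, ]^2)
      ok <- grid[grid^2 + budget < 1 & grid * fdir[f] >= 0]
      sse <- vapply(ok, function(l) {
        ld <- load; ld$feature[f] <- l
        r <- stats::cor(feat_val(f, ld), cv, method = "spearman")
        sum((r - targets[f, t_clin_sev])^2)
      }, numeric(1))
      load$feature[f] <- ok[which.min(sse)]
    }
    fv <- sapply(t_feats, function(f) feat_val(f, load))
    for (v in t_clin_sev) {
      mu <- AUX_MU
      ok <- grid[grid^2 + mu^2 < 1]
      sse <- vapply(ok, function(l) {
        ld <- load; ld$clinical[v] <- l
        val <- clinical_value(v, group,
                              clinical_score(v, ld, z_sev, z_aux, eps_c[, v]),
                              config)
        sum((stats::cor(fv, val, method = "spearman") - targets[t_feats, v])^2)
      }, numeric(1))
      load$clinical[v] <- ok[which.min(sse)]
    }
    cv <- clin_vals(load)
  }
  # stage 3: age coupling (independent of severity) where an age target exists
  if ("age" %in% t_clin) {
    age_vals <- clinical_value("age", group, z_age, config)
    for (f in t_feats[abs(targets[t_feats, "age"]) >= 0.05]) {
      budget <- load$feature[f]^2 + sum(load$aux[f, ]^2)
      ok <- grid[grid^2 + budget < 1]
      err <- vapply(ok, function(g) {
        ld <- load; ld$gamma_age[f] <- g
        (stats::cor(feat_val(f, ld), age_vals, method = "spearman") -
           targets[f, "age"])^2
      }, numeric(1))
      load$gamma_age[f] <- ok[which.min(err)]
    }
  }
  # stage 4: per-cell residual fit through each clinical score's own
  # orthogonal factor, within the remaining loading-norm budget
  fine <- seq(-0.5, 0.5, grid_step / 2)
  for (f in t_feats) {
    for (v in t_clin_sev) {
      budget <- load$feature[f]^2 + load$gamma_age[f]^2 +
        sum(load$aux[f, setdiff(aux_v, v)]^2)
      ok <- fine[fine^2 + budget < 0.95]
      if (!length(ok)) next
      err <- vapply(ok, function(a) {
        ld <- load; ld$aux[f, v] <- a
        (stats::cor(feat_val(f, ld), cv[, v], method = "spearman") -
           targets[f, v])^2
      }, numeric(1))
      load$aux[f, v] <- ok[which.min(err)]
    }
  }
  # stage 5: the structural clamp (thresholded size <= parent mask size)
  # truncates the upper tail of the thresholded-size marginals; refit their
  # latent parameters so the post-clamp moments match the targets
  parents <- threshold_parents()
  fm <- config$feature_marginals
  adj <- list()
  m_adj <- 200000L
  with_seed(8451319L, {
    for (f in intersect(fm$feature[fm$censored], names(parents))) {
      r <- feat_row(fm, f)
      pf <- parents[[f]]
      for (g in c("control", "patient")) {
        zs <- stats::rnorm(m_adj); za <- stats::rnorm(m_adj)
        zx <- matrix(stats::rnorm(m_adj * length(aux_v)), m_adj,
                     dimnames = list(NULL, aux_v))
        grp <- rep(g, m_adj)
        zf <- feature_score(f, load, zs, za, zx, stats::rnorm(m_adj))
        pv <- feature_value(
          pf, grp, feature_score(pf, load, zs, za, zx, stats::rnorm(m_adj)),
          config)
        tm <- if (g == "patient") r$mean_patient else r$mean_control
        ts <- if (g == "patient") r$sd_patient else r$sd_control
        base <- censored_normal_params(tm, ts)
        v0 <- pmin(pmax(0, base[1] + base[2] * zf), pv)
        if (abs(mean(v0) / tm - 1) < 0.003 && abs(stats::sd(v0) / ts - 1) < 0.003)
          next
        obj <- function(p) {
          v <- pmin(pmax(0, p[1] + exp(p[2]) * zf), pv)
          (mean(v) / tm - 1)^2 + (stats::sd(v) / ts - 1)^2
        }
        fit <- stats::optim(c(base[1], log(base[2])), obj,
                            method = "Nelder-Mead",
                            control = list(maxit = 1000, reltol = 1e-12))
        adj[[f]][[g]] <- c(fit$par[1], exp(fit$par[2]))
      }
    }
  })
  fv <- sapply(t_feats, function(f) feat_val(f, load))
  achieved <- stats::cor(fv, cbind(cv, age = clinical_value("age", group, z_age, config)),
                         method = "spearman")
  config$loadings <- load
  config$marginal_adjust <- adj
  config$calibration <- achieved[, c("age", t_clin_sev)]
  config
}

# ---- cohort generation ------------------------------------------------------

#' Generate a synthetic phantom cohort
#'
#' Draws a cohort of `n_controls + n_patients` subjects whose imaging
#' features and clinical scores follow the configured per-group marginals,
#' coupled through the calibrated latent-severity copula. With
#' `config$image_level = TRUE`, full NM / QSM / SWI-magnitude volumes and SN
#' + background masks are rendered per subject ([render_subject_volumes]);
#' the bundle's `truth_features` are then the statistics actually painted
#' into the volumes (sizes quantised to whole voxels), so that zero-noise
#' extraction reproduces them exactly.
#'
#' @param config a [phantom_config]; if its `loadings` are empty the copula
#'   is calibrated first (see [calibrate_copula]).
#' @return A list of per-subject bundles (class `nigra_cohort`), each with
#'   `record` (demographics + clinical scores + latent severity),
#'   `truth_features`, and - image-level only - `volumes` and `masks`.
#'   The assembled tables are available via [cohort_subjects] and
#'   [cohort_features].
#' @export
generate_cohort <- function(config = phantom_config()) {
  nq_assert(inherits(config, "phantom_config"), "need a phantom_config")
  if (is.null(config$loadings)) config <- calibrate_copula(config)
  load <- config$loadings
  feats <- config$feature_marginals$feature
  clin_vars <- config$clinical_marginals$variable
  n <- config$n_controls + config$n_patients
  group <- rep(c("control", "patient"), c(config$n_controls, config$n_patients))

  aux_v <- aux_clinical_vars()
  with_seed(config$seed, {
    z_sev <- stats::rnorm(n)
    z_age <- stats::rnorm(n)
    z_aux <- matrix(stats::rnorm(n * length(aux_v)), n,
                    dimnames = list(NULL, aux_v))
    male_frac <- reference_sex_male_fraction()
    sex <- ifelse(stats::runif(n) < male_frac[group], "M", "F")
    eps_c <- matrix(stats::rnorm(n * length(clin_vars)), n,
                    dimnames = list(NULL, clin_vars))
    eps_f <- matrix(stats::rnorm(n * length(feats)), n,
                    dimnames = list(NULL, feats))
  })

  clinical <- sapply(clin_vars, function(v) {
    z <- if (v == "age") z_age
         else clinical_score(v, load, z_sev, z_aux, eps_c[, v])
    clinical_value(v, group, z, config)
  })
  features <- sapply(feats, function(f) {
    z <- feature_score(f, load, z_sev, z_age, z_aux, eps_f[, f])
    feature_value(f, group, z, config)
  })
  features <- as.data.frame(features)
  # structural constraint: a thresholded mask cannot exceed its parent mask
  for (p in c("nm", "qsm", "smwi")) {
    thr <- paste0(p, "_size_", if (p == "nm") "high" else "low")
    features[[thr]] <- pmin(features[[thr]], features[[paste0(p, "_size")]])
  }

  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group, sex = sex,
    as.data.frame(clinical),
    latent_severity = z_sev + config$severity_shift * (group == "patient"),
    stringsAsFactors = FALSE
  )
  subjects$hy[subjects$group == "control"] <- 0

  bundles <- lapply(seq_len(n), function(i) {
    b <- list(record = as.list(subjects[i, ]),
              truth_features = features[i, , drop = FALSE],
              volumes = NULL, masks = NULL)
    if (config$image_level) {
      r <- render_subject_volumes(subjects[i, ], config,
                                  truth_features = features[i, ],
                                  noise_seed = derive_seed(config$seed, i))
      b$volumes <- r$volumes; b$masks <- r$masks
      b$truth_features <- r$truth_features
      features[i, ] <<- r$truth_features
    }
    b
  })
  structure(bundles, class = "nigra_cohort",
            subjects = subjects,
            features = cbind(subjects[c("subject_id", "group")], features),
            config = config)
}

#' @rdname generate_cohort
#' @param cohort a `nigra_cohort`.
#' @return `cohort_subjects()` / `cohort_features()`: the cohort's subject
#'   and feature tables as data frames.
#' @export
cohort_subjects <- function(cohort) attr(cohort, "subjects")

#' @rdname generate_cohort
#' @export
cohort_features <- function(cohort) attr(cohort, "features")

#' @export
print.nigra_cohort <- function(x, ...) {
  s <- cohort_subjects(x)
  cat(sprintf("<nigra_cohort> %d subjects (%d controls, %d patients)%s\n",
              nrow(s), sum(s$group == "control"), sum(s$group == "patient"),
              if (!is.null(x[[1]]$volumes)) ", image-level" else ""))
  invisible(x)
}

# ---- reader ratings ---------------------------------------------------------

#' Simulate binary PD / non-PD ratings by radiological readers
#'
#' Given each subject's true group, every reader independently produces a
#' binary rating with the stated per-reader sensitivity (probability of
#' rating a patient "PD") and specificity (probability of rating a control
#' "non-PD"). Defaults use the reference readers' SMWI performance.
#'
#' @param subjects data frame with a `group` column (or a `nigra_cohort`).
#' @param reader_accuracies data frame with `sensitivity` and `specificity`
#'   columns, one row per reader.
#' @param seed RNG seed.
#' @return Character matrix (subjects x readers) with entries `"PD"` /
#'   `"non-PD"`, suitable for [fleiss_kappa] / [cohen_kappa].
#' @export
simulate_reader_ratings <- function(subjects,
                                    reader_accuracies = subset(reference_reader_performance(), modality == "SMWI"),
                                    seed = 1L) {
  if (inherits(subjects, "nigra_cohort")) subjects <- cohort_subjects(subjects)
  sens <- reader_accuracies$sensitivity
  spec <- reader_accuracies$specificity
  nq_assert(all(sens >= 0 & sens <= 1 & spec >= 0 & spec <= 1),
            "sensitivities/specificities must lie in [0, 1]")
  pat <- is_patient(subjects$group)
  n <- length(pat); k <- length(sens)
  with_seed(seed, {
    u <- matrix(stats::runif(n * k), n, k)
  })
  p_pd <- outer(pat, sens) * NA
  for (j in seq_len(k)) p_pd[, j] <- ifelse(pat, sens[j], 1 - spec[j])
  out <- ifelse(u < p_pd, "PD", "non-PD")
  dimnames(out) <- list(subjects$subject_id,
                        paste0("reader", seq_len(k)))
  out
}
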