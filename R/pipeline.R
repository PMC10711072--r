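REPORT_SCHEMA_VERSION <- "1.0"

#' Run the full simulate - extract - composite - stats pipeline
#'
#' One reproducible invocation of the whole analysis: generate (or render and
#' re-extract) a phantom cohort, fill the composite marker, and compute the
#' statistical layer - the per-feature group-difference table (n/mean/sd,
#' p-value, pooled-SD effect size, AUC with DeLong CI), ratio/percent
#' contrasts, ROC operating points and curve data for the composite marker
#' and its three factors, the Bonferroni-corrected Spearman correlation table
#' against clinical scores, and rater-agreement statistics from simulated
#' reader ratings. All randomness derives from `config$seed`, so identical
#' configurations give identical reports.
#'
#' @param config a [phantom_config] (with `image_level = TRUE` the cohort is
#'   rendered as volumes and features are re-extracted from the images).
#' @param policy a [threshold_policy].
#' @param simulate_readers also simulate reader ratings and compute
#'   Fleiss/Cohen kappa.
#' @param out_dir optional directory; when given, [write_report] is called.
#' @return A list of class `nigra_report`: `features`, `subjects`,
#'   `group_summary`, `relative_differences`, `roc` (per-marker operating
#'   point, AUC, CI and curve points), `correlations`, `agreement`,
#'   `schema_version`, `seed`, `thresholds`.
#' @export
run_pipeline <- function(config = phantom_config(), policy = threshold_policy(),
                         simulate_readers = TRUE, out_dir = NULL) {
  cohort <- generate_cohort(config)
  subjects <- cohort_subjects(cohort)
  features <- cohort_features(cohort)

  if (config$image_level) {
    rows <- lapply(cohort, function(b)
      extract_feature_vector(b$volumes, b$masks, policy))
    ex <- do.call(rbind, rows)
    features <- cbind(subjects[c("subject_id", "group")],
                      ex[setdiff(names(ex), "composite")])
  }
  features <- composite_marker(features)

  summary <- group_feature_summary(features, features$group)
  reldiff <- relative_difference_summary(summary)

  markers <- c("composite", "nm_contrast_range", "nm_size_high", "qsm_size_low")
  roc <- lapply(markers, function(mk) {
    res <- empirical_auc_ci(features[[mk]], features$group, direction = "low")
    op <- youden_operating_point(features[[mk]], features$group, direction = "low")
    list(marker = mk, auc = res$auc, auc_ci = res$ci,
         operating_point = op,
         curve = roc_points(features[[mk]], features$group, direction = "low"))
  })
  names(roc) <- markers

  correlations <- spearman_bonferroni_table(
    features, subjects,
    feature_cols = intersect(rownames(reference_spearman_targets()),
                             names(features)),
    clinical_cols = c("age", "mmse", "updrs1", "updrs2", "updrs3"))

  agreement <- NULL
  if (simulate_readers) {
    ratings <- simulate_reader_ratings(subjects,
                                       seed = derive_seed(config$seed, 7001L))
    agreement <- list(
      fleiss_all = fleiss_kappa(ratings),
      cohen_senior = cohen_kappa(ratings[, 1], ratings[, 2]),
      ratings = ratings
    )
  }

  report <- structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    seed = config$seed,
    thresholds = unclass(policy),
    subjects = subjects,
    features = features,
    group_summary = summary,
    relative_differences = reldiff,
    roc = roc,
    correlations = correlations,
    agreement = agreement
  ), class = "nigra_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.nigra_report <- function(x, ...) {
  cat(sprintf("<nigra_report> %d subjects, composite AUC %.3f\n",
              nrow(x$subjects), x$roc$composite$auc))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Serialises a [run_pipeline] report as CSV tables (features, subjects,
#' group summary, relative differences, correlations, ROC curves), a JSON
#' stats summary stamped with the schema version, and a short human-readable
#' markdown digest.
#'
#' @param report a `nigra_report`.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, out_dir) {
  nq_assert(inherits(report, "nigra_report"), "need a nigra_report")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    nq_stop("cannot create output directory", "nigraquant_unwritable_path")
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  files <- c(
    w(report$features, "features.csv"),
    w(report$subjects, "subjects.csv"),
    w(report$group_summary, "group_summary.csv"),
    w(report$relative_differences, "relative_differences.csv"),
    w(report$correlations, "correlations.csv")
  )
  curves <- do.call(rbind, lapply(report$roc, function(r)
    cbind(marker = r$marker, r$curve)))
  files <- c(files, w(curves, "roc_curves.csv"))
  if (!is.null(report$agreement))
    files <- c(files, w(as.data.frame(report$agreement$ratings),
                        "reader_ratings.csv"))

  json <- list(
    schema_version = report$schema_version,
    seed = report$seed,
    thresholds = report$thresholds,
    roc = lapply(report$roc, function(r)
      list(marker = r$marker, auc = r$auc, auc_ci = r$auc_ci,
           cutoff = r$operating_point$cutoff,
           sensitivity = r$operating_point$sensitivity,
           specificity = r$operating_point$specificity,
           accuracy = r$operating_point$accuracy)),
    agreement = if (!is.null(report$agreement)) list(
      fleiss_kappa = report$agreement$fleiss_all$value,
      cohen_kappa_senior = report$agreement$cohen_senior$value
    )
  )
  json_path <- file.path(out_dir, "stats_summary.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  md <- c(
    "# SN iron-neuromelanin quantitative report",
    sprintf("- schema %s, seed %d, %d subjects (%d controls / %d patients)",
            report$schema_version, report$seed, nrow(report$subjects),
            sum(report$subjects$group == "control"),
            sum(report$subjects$group == "patient")),
    sprintf("- composite marker AUC %.3f (%.3f-%.3f); sens %.0f%%, spec %.0f%%, acc %.0f%%",
            report$roc$composite$auc, report$roc$composite$auc_ci[1],
            report$roc$composite$auc_ci[2],
            100 * report$roc$composite$operating_point$sensitivity,
            100 * report$roc$composite$operating_point$specificity,
            100 * report$roc$composite$operating_point$accuracy),
    if (!is.null(report$agreement))
      sprintf("- reader agreement: Fleiss kappa %.3f (all), Cohen kappa %.3f (senior pair)",
              report$agreement$fleiss_all$value,
              report$agreement$cohen_senior$value)
  )
  md_path <- file.path(out_dir, "summary.md")
  writeLines(md, md_path)
  invisible(c(files, json_path, md_path))
}

#' Read and write phantom configurations as YAML
#'
#' @param config a [phantom_config].
#' @param path YAML file path.
#' @return `read_phantom_config` returns a [phantom_config];
#'   `write_phantom_config` returns `path` invisibly.
#' @export
write_phantom_config <- function(config, path) {
  x <- unclass(config)
  x$feature_marginals <- as.list(x$feature_marginals)
  x$clinical_marginals <- as.list(x$clinical_marginals)
  x$target_rank_correlations <- list(
    rows = rownames(x$target_rank_correlations),
    cols = colnames(x$target_rank_correlations),
    values = as.vector(x$target_rank_correlations)
  )
  x$loadings <- NULL; x$calibration <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  x <- yaml::read_yaml(path)
  tm <- matrix(unlist(x$target_rank_correlations$values),
               nrow = length(x$target_rank_correlations$rows),
               dimnames = list(x$target_rank_correlations$rows,
                               x$target_rank_correlations$cols))
  phantom_config(
    n_controls = x$n_controls, n_patients = x$n_patients, seed = x$seed,
    feature_marginals = as.data.frame(x$feature_marginals,
                                      stringsAsFactors = FALSE),
    clinical_marginals = as.data.frame(x$clinical_marginals,
                                       stringsAsFactors = FALSE),
    target_rank_correlations = tm,
    gradient_strength = x$gradient_strength, noise_sd = x$noise_sd,
    voxel_dims_nm = unlist(x$voxel_dims_nm),
    voxel_dims_qsm = unlist(x$voxel_dims_qsm),
    image_level = x$image_level, severity_shift = x$severity_shift
  )
}
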