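# End-to-end pipeline: simulate -> QC -> features -> statistics ->
# classification, with a reproducible output bundle. Each stage is also
# exposed on its own so the analysis scripts can run and inspect stage
# boundaries.

#' Pipeline configuration
#'
#' @param cohort A [cohort_spec()] (or list of its arguments).
#' @param qc A [qc_config()].
#' @param window Displacement window length in frames.
#' @param cv A [cv_config()].
#' @param families Model families to evaluate.
#' @param out_dir Output directory for the bundle.
#' @param seed Global seed; propagated to the cohort spec and the CV
#'   configuration so one integer pins the whole run.
#' @param write_sessions Also write every session CSV (large; default
#'   `FALSE`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(), qc = qc_config(),
                            window = 5L, cv = cv_config(),
                            families = c("svm", "random_forest",
                                         "extra_trees", "adaboost", "knn"),
                            out_dir = "results", seed = 1L,
                            write_sessions = FALSE) {
  if (!inherits(cohort, "cohort_spec")) cohort <- do.call(cohort_spec, cohort)
  stopifnot(inherits(qc, "qc_config"), inherits(cv, "cv_config"))
  cohort$seed <- as.integer(seed)
  cv$seed <- as.integer(seed)
  structure(list(cohort = cohort, qc = qc, window = as.integer(window),
                 cv = cv, families = families, out_dir = out_dir,
                 seed = as.integer(seed), write_sessions = write_sessions),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level sections `cohort`, `qc`, `cv` (each a map of the
#' corresponding constructor's arguments) plus scalar keys `window`,
#' `families`, `out_dir`, `seed`, `write_sessions`. A missing section
#' uses that stage's defaults; an unknown section is an error naming it.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("cohort", "qc", "cv", "window", "families", "out_dir",
             "seed", "write_sessions")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration section: ", paste(unknown, collapse = ", "))
  args <- list()
  if (!is.null(raw$cohort)) {
    for (nm in c("region_amplitude", "risk_multiplier"))
      if (!is.null(raw$cohort[[nm]])) raw$cohort[[nm]] <- unlist(raw$cohort[[nm]])
    args$cohort <- do.call(cohort_spec, raw$cohort)
  }
  if (!is.null(raw$qc)) args$qc <- do.call(qc_config, raw$qc)
  if (!is.null(raw$cv)) args$cv <- do.call(cv_config, raw$cv)
  for (nm in c("window", "families", "out_dir", "seed", "write_sessions"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(pipeline_config, args)
}

#' Read a feature table written by the pipeline
#'
#' @param path `features.csv` produced by [run_pipeline()] (or
#'   [build_feature_table()] output written with `data.table::fwrite`).
#' @return Feature table data frame.
#' @export
read_features <- function(path) {
  as.data.frame(data.table::fread(
    path, colClasses = list(character = "participant_id")))
}

#' Run QC on a cohort and build the feature table
#'
#' Applies [qc_session()] to every session, drops excluded sessions
#' (recording the reason), and computes the per-participant feature
#' table from the retained ones.
#'
#' @param cohort List with `sessions` and `metadata` (from
#'   [generate_cohort()] or read from disk).
#' @param qc A [qc_config()].
#' @param window Displacement window in frames.
#' @return List: `features` (data frame), `qc_report` (one row per
#'   session: missingness, gap census, exclusion flag and reason).
#' @export
extract_features <- function(cohort, qc = qc_config(), window = 5L) {
  qcs <- lapply(cohort$sessions, qc_session, config = qc)
  qc_report <- do.call(rbind, lapply(qcs, function(q) data.frame(
    participant_id = q$session$participant_id,
    missingness = q$missingness, excluded = q$excluded,
    reason = q$reason, n_gaps_linear = q$n_gaps_linear,
    n_gaps_kalman = q$n_gaps_kalman, stringsAsFactors = FALSE)))
  keep <- !qc_report$excluded
  features <- build_feature_table(
    lapply(qcs[keep], `[[`, "session"),
    cohort$metadata[cohort$metadata$participant_id %in%
                      qc_report$participant_id[keep], , drop = FALSE],
    window = window)
  list(features = features, qc_report = qc_report)
}

#' Run the statistics stage on a feature table
#'
#' Normality census over the 17 regional indices plus the global index,
#' the group-comparison table (U, r, BH-FDR), the rating-correlation
#' table, domain-wise Bonferroni flags, the inter-regional correlation
#' matrix, and the global-index test.
#'
#' @param features Feature table.
#' @param alpha Significance level.
#' @return List of tables: `normality`, `group_tests`, `correlations`,
#'   `domain_flags`, `cor_matrix`, `global_test`.
#' @export
run_stats_stage <- function(features, alpha = 0.05) {
  census_regions <- c(regions_all, "global")
  normality <- data.frame(
    region = census_regions,
    decision = vapply(census_regions, function(rg) shapiro_gate(
      split(features[[rg]], features$group), alpha), character(1)),
    stringsAsFactors = FALSE)
  group_tests <- group_test_table(features, alpha = alpha)
  # degenerate cohorts (zero-variance indices or ratings) have no
  # defined correlations; report empty tables rather than aborting
  correlations <- tryCatch(correlation_table(features),
                           error = function(e) data.frame(
                             region = character(), rho = numeric(),
                             ci_low = numeric(), ci_high = numeric(),
                             p = numeric()))
  cor_matrix <- tryCatch(spearman_matrix(features),
                         error = function(e) matrix(numeric(), 0, 0))
  p_by_domain <- lapply(region_domains, function(rgs) {
    rgs <- intersect(rgs, group_tests$region)
    stats::setNames(group_tests$p_raw[match(rgs, group_tests$region)], rgs)
  })
  domain_flags <- domain_bonferroni(p_by_domain, alpha = alpha)
  gm <- mann_whitney(features$global[features$group == "risk"],
                     features$global[features$group == "control"])
  list(normality = normality, group_tests = group_tests,
       correlations = correlations, domain_flags = domain_flags,
       cor_matrix = cor_matrix,
       global_test = data.frame(U = gm$U, Z = gm$Z, p = gm$p,
                                r = effect_size_r(gm$Z, nrow(features)),
                                mean_rank_risk = gm$mean_rank_a,
                                mean_rank_control = gm$mean_rank_b))
}

#' Run the classification stage on a feature table
#'
#' Nested CV for each requested family plus the demographic-only
#' baseline, assembled into a model-comparison report table.
#'
#' @param features Feature table.
#' @param cv A [cv_config()].
#' @param families Families to evaluate.
#' @return List: `reports` (named list of `cv_report`), `baseline`
#'   (`cv_report`), `table` (one row per model: metrics with CIs and
#'   both AUC summaries), `pfi` (data frame of mean importances),
#'   `roc_points` (pooled out-of-fold ROC coordinates per model).
#' @export
run_ml_stage <- function(features, cv = cv_config(),
                         families = c("svm", "random_forest", "extra_trees",
                                      "adaboost", "knn")) {
  xy <- select_features(features)
  reports <- lapply(families, function(fam)
    nested_cv(xy$x, xy$y, model_spec(fam), cv))
  names(reports) <- families
  baseline <- demographic_baseline(features$age_months, features$sex,
                                   features$group, config = cv)
  row_of <- function(nm, rp) {
    m <- rp$metrics
    val <- function(k) m$value[m$metric == k]
    lo <- function(k) m$ci_low[m$metric == k]
    hi <- function(k) m$ci_high[m$metric == k]
    data.frame(model = nm,
               accuracy = val("accuracy"), accuracy_low = lo("accuracy"),
               accuracy_high = hi("accuracy"),
               precision = val("precision"), precision_low = lo("precision"),
               precision_high = hi("precision"),
               sensitivity = val("sensitivity"),
               sensitivity_low = lo("sensitivity"),
               sensitivity_high = hi("sensitivity"),
               specificity = val("specificity"),
               specificity_low = lo("specificity"),
               specificity_high = hi("specificity"),
               f1 = val("f1"), f1_low = lo("f1"), f1_high = hi("f1"),
               mean_fold_auc = rp$auc$mean_fold_auc,
               sd_fold_auc = rp$auc$sd_fold_auc,
               pooled_auc = rp$auc$pooled_auc,
               pooled_auc_low = rp$auc$pooled_ci[1],
               pooled_auc_high = rp$auc$pooled_ci[2],
               stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(Map(row_of, names(reports), reports),
                          list(row_of("demographic_baseline", baseline))))
  pfi <- do.call(rbind, lapply(names(reports), function(nm) data.frame(
    model = nm, feature = names(reports[[nm]]$importance),
    importance = unname(reports[[nm]]$importance),
    stringsAsFactors = FALSE)))
  roc_points <- do.call(rbind, lapply(names(reports), function(nm) {
    rp <- reports[[nm]]
    ord <- order(rp$scores, decreasing = TRUE)
    lab <- rp$truth[ord] == "risk"
    data.frame(model = nm,
               fpr = c(0, cumsum(!lab) / sum(!lab)),
               tpr = c(0, cumsum(lab) / sum(lab)),
               stringsAsFactors = FALSE)
  }))
  list(reports = reports, baseline = baseline, table = tab, pfi = pfi,
       roc_points = roc_points)
}

#' Run the full pipeline and write the output bundle
#'
#' Executes simulate -> QC -> features -> statistics -> classification
#' under one global seed and writes: `metadata.csv`, `qc_report.csv`,
#' `features.csv`, `normality.csv`, `group_tests.csv`,
#' `correlations.csv`, `domain_corrections.csv`,
#' `correlation_matrix.csv`, `global_test.csv`, `ml_report.csv`,
#' `ml_report.json`, `pfi.csv`, `roc_points.csv`, `run_log.txt` (stage
#' milestones, exclusions with reasons, resolved seed) and
#' `manifest.csv` (md5 of every output). Reruns with the same
#' configuration produce identical manifests.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory result plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- sprintf("seed: %d", config$seed)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  note("stage simulate: generating %d risk + %d control sessions (%g s at %g fps)",
       config$cohort$n_risk, config$cohort$n_control,
       config$cohort$duration_s, config$cohort$fps)
  cohort <- generate_cohort(config$cohort)
  if (config$write_sessions) {
    sdir <- file.path(config$out_dir, "sessions")
    dir.create(sdir, showWarnings = FALSE)
    for (s in cohort$sessions)
      write_session(s, file.path(sdir, paste0(s$participant_id, ".csv")))
  }

  note("stage qc: threshold %.2f, exclusion at %.0f%% missingness",
       config$qc$confidence_threshold, 100 * config$qc$exclusion_missingness)
  ext <- extract_features(cohort, config$qc, config$window)
  excl <- ext$qc_report[ext$qc_report$excluded, , drop = FALSE]
  for (i in seq_len(nrow(excl)))
    note("excluded session %s: %s", excl$participant_id[i], excl$reason[i])
  note("stage features: %d participants retained, window %d frames",
       nrow(ext$features), config$window)

  stats_out <- run_stats_stage(ext$features)
  n_sig <- sum(stats_out$group_tests$p_fdr < 0.05)
  note("stage stats: %d/%d regions significant after FDR", n_sig,
       nrow(stats_out$group_tests))
  if (all(vapply(regions_all, function(rg) stats::sd(ext$features[[rg]]), 1) == 0))
    note("warning: degenerate features (no movement variance)")

  note("stage classify: families %s", paste(config$families, collapse = ", "))
  ml <- run_ml_stage(ext$features, config$cv, config$families)

  out <- config$out_dir
  wr <- function(obj, name) data.table::fwrite(obj, file.path(out, name))
  wr(cohort$metadata, "metadata.csv")
  wr(ext$qc_report, "qc_report.csv")
  wr(ext$features, "features.csv")
  wr(stats_out$normality, "normality.csv")
  wr(stats_out$group_tests, "group_tests.csv")
  wr(stats_out$correlations, "correlations.csv")
  wr(stats_out$domain_flags, "domain_corrections.csv")
  if (length(stats_out$cor_matrix))
    wr(as.data.frame(stats_out$cor_matrix), "correlation_matrix.csv")
  else
    writeLines(character(0), file.path(out, "correlation_matrix.csv"))
  wr(stats_out$global_test, "global_test.csv")
  wr(ml$table, "ml_report.csv")
  jsonlite::write_json(ml$table, file.path(out, "ml_report.json"),
                       dataframe = "rows", digits = NA)
  wr(ml$pfi, "pfi.csv")
  wr(ml$roc_points, "roc_points.csv")
  writeLines(log_lines, file.path(out, "run_log.txt"))

  files <- c("metadata.csv", "qc_report.csv", "features.csv", "normality.csv",
             "group_tests.csv", "correlations.csv", "domain_corrections.csv",
             "correlation_matrix.csv", "global_test.csv", "ml_report.csv",
             "ml_report.json", "pfi.csv", "roc_points.csv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))),
                         stringsAsFactors = FALSE)
  wr(manifest, "manifest.csv")
  invisible(list(cohort = cohort, features = ext$features,
                 qc_report = ext$qc_report, stats = stats_out, ml = ml,
                 manifest = manifest))
}
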