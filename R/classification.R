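# Nested cross-validated classification of risk vs control from the 15
# movement features: stratified outer folds for evaluation, stratified
# inner folds for hyperparameter selection, pooled out-of-fold metrics
# with Wilson intervals, fold-wise and pooled AUC summaries, and
# permutation feature importance on the held-out folds.

#' Model specification
#'
#' Five classifier families are supported: support vector machine
#' (`svm`), random forest (`random_forest`), extremely randomized trees
#' (`extra_trees`), AdaBoost over shallow decision trees (`adaboost`)
#' and k-nearest neighbours (`knn`). The distance/geometry based
#' families (svm, knn) default to inverse-frequency class weighting and
#' to train-fold z-standardization; tree ensembles use neither (they are
#' robust to feature scaling).
#'
#' @param family One of `"svm"`, `"random_forest"`, `"extra_trees"`,
#'   `"adaboost"`, `"knn"`.
#' @param grid Data frame of hyperparameter combinations; `NULL` uses
#'   the documented default grid for the family.
#' @param class_weight `"inverse_frequency"` or `"none"`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("svm", "random_forest", "extra_trees",
                                  "adaboost", "knn"),
                       grid = NULL,
                       class_weight = NULL) {
  family <- match.arg(family)
  if (is.null(class_weight))
    class_weight <- if (family %in% c("svm", "knn")) "inverse_frequency" else "none"
  class_weight <- match.arg(class_weight, c("inverse_frequency", "none"))
  if (is.null(grid)) grid <- default_grid(family)
  if (!nrow(grid)) stop("hyperparameter grid must be nonempty")
  structure(list(family = family, grid = grid, class_weight = class_weight),
            class = "model_spec")
}

#' Default hyperparameter grids
#'
#' The documented default search spaces per family: svm — kernel
#' \{rbf, linear\}, C in \{0.1, 1, 10, 100\}, gamma in \{scale
#' heuristic, 0.01, 0.1, 1\} (rbf only); forests — 100/300 trees, depth
#' unlimited/3/5; adaboost — 50/200 stumps of depth 1/2 at learning
#' rate 0.1/1.0; knn — k in \{3, 5, 7, 9\} with uniform or distance
#' vote weighting.
#'
#' @param family Model family name.
#' @return Data frame, one row per hyperparameter combination.
#' @export
default_grid <- function(family) {
  switch(family,
    svm = rbind(
      expand.grid(kernel = "linear", cost = c(0.1, 1, 10, 100),
                  gamma = NA_character_, stringsAsFactors = FALSE),
      expand.grid(kernel = "radial", cost = c(0.1, 1, 10, 100),
                  gamma = c("scale", "0.01", "0.1", "1"),
                  stringsAsFactors = FALSE)),
    random_forest = ,
    extra_trees = expand.grid(num_trees = c(100L, 300L),
                              max_depth = c(0L, 3L, 5L)),
    adaboost = expand.grid(n_estimators = c(50L, 200L),
                           learning_rate = c(0.1, 1.0),
                           stump_depth = c(1L, 2L)),
    knn = expand.grid(k = c(3L, 5L, 7L, 9L),
                      weighting = c("uniform", "distance"),
                      stringsAsFactors = FALSE),
    stop("unknown family: ", family))
}

#' Cross-validation configuration
#'
#' @param outer_folds,inner_folds Fold counts (default 5/5, stratified).
#' @param seed Integer seed; all fold splits, tree fits and permutations
#'   derive from it deterministically.
#' @param inner_metric Inner-loop selection metric: `"auc"` (pooled
#'   inner out-of-fold ROC-AUC, default) or `"accuracy"`.
#' @param pfi_repeats Permutation-importance repetitions per feature and
#'   fold (default 20).
#' @param pfi_metric Score used for permutation importance (default
#'   `"accuracy"`).
#' @return A `cv_config` list.
#' @export
cv_config <- function(outer_folds = 5L, inner_folds = 5L, seed = 1L,
                      inner_metric = c("auc", "accuracy"),
                      pfi_repeats = 20L,
                      pfi_metric = c("accuracy", "auc")) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, pfi_repeats >= 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed),
                 inner_metric = match.arg(inner_metric),
                 pfi_repeats = as.integer(pfi_repeats),
                 pfi_metric = match.arg(pfi_metric)),
            class = "cv_config")
}

#' Select the classifier feature matrix
#'
#' Keeps the 15 analysis regions (head; left/right shoulder, elbow,
#' wrist, hand, knee, ankle, foot). Hip indices are excluded because
#' motion is measured in a pelvis-rooted frame, and the global index is
#' excluded as a redundant composite of the other features. Column order
#' follows [regions_analysis].
#'
#' @param features Feature table from [build_feature_table()].
#' @return List: `x` (numeric matrix, 15 columns), `y` (factor with
#'   levels `control`, `risk`).
#' @export
select_features <- function(features) {
  missing_cols <- setdiff(c(regions_analysis, "group"), names(features))
  if (length(missing_cols))
    stop("feature table missing columns: ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(features[, regions_analysis, drop = FALSE])
  stopifnot(!any(c("left_hip", "right_hip", "global") %in% colnames(x)))
  y <- factor(features$group, levels = c("control", "risk"))
  list(x = x, y = y)
}

derive_seed <- function(seed, ...) {
  k <- c(seed, ...)
  as.integer((sum(k * (7919 ^ seq_along(k))) %% 2147483017) + 1)
}

# Deterministic stratified fold assignment: within each class, shuffle
# and deal members round-robin, so per-fold class ratios differ by at
# most one member.
stratified_folds <- function(y, k, seed) {
  if (any(table(y) < k))
    stop("a class has fewer members than folds")
  fold <- integer(length(y))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Inverse-frequency class weights, normalized so the majority class has
# weight 1: a member of class c counts like max(n)/n_c members. With
# this normalization, weighting is exactly equivalent to duplicating
# minority rows when the class ratio is integer.
inverse_frequency_weights <- function(y) {
  tab <- table(y)
  stats::setNames(as.numeric(max(tab) / tab), names(tab))
}

#' Rank-based AUC for risk scores
#'
#' Probability that a random risk participant scores above a random
#' control, with half credit for ties (the Mann-Whitney statistic
#' normalized by `n1 * n2`).
#'
#' @param scores Numeric risk scores (higher = more risk-like).
#' @param labels Factor or character labels (`risk` = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == "risk"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# ---- model fitting -------------------------------------------------------

# Fit one family with one hyperparameter row; returns an object whose
# predict_scores(x) gives P(risk)-oriented scores and predict_class(x)
# gives labels. Standardization (svm/knn) is fit on the training matrix.
fit_model <- function(family, x, y, params, class_weight, seed) {
  scaler <- NULL
  if (family %in% c("svm", "knn")) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    scaler <- list(center = ctr, scale = scl)
    x <- scale(x, ctr, scl)
  }
  cw <- if (class_weight == "inverse_frequency") inverse_frequency_weights(y) else NULL
  fit <- switch(family,
    svm = {
      gamma <- if (params$kernel == "radial") {
        if (params$gamma == "scale") 1 / (ncol(x) * max(stats::var(as.vector(x)), 1e-12))
        else as.numeric(params$gamma)
      } else 1 / ncol(x)
      e1071::svm(x, y, kernel = params$kernel, cost = params$cost,
                 gamma = gamma, class.weights = cw, scale = FALSE)
    },
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = params$num_trees,
      max.depth = params$max_depth, probability = TRUE,
      seed = seed, num.threads = 1),
    extra_trees = ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = params$num_trees,
      max.depth = params$max_depth, probability = TRUE,
      splitrule = "extratrees", num.random.splits = 1,
      replace = FALSE, sample.fraction = 1,
      seed = seed, num.threads = 1),
    adaboost = adaboost_fit(x, y, params$n_estimators, params$learning_rate,
                            params$stump_depth, seed),
    knn = list(x = x, y = y, k = params$k, weighting = params$weighting,
               class_weights = cw %||% c(control = 1, risk = 1)),
    stop("unknown family: ", family))
  structure(list(family = family, fit = fit, scaler = scaler),
            class = "pov_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

predict_scores <- function(model, x) {
  if (!is.null(model$scaler))
    x <- scale(x, model$scaler$center, model$scaler$scale)
  switch(model$family,
    svm = {
      pr <- stats::predict(model$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision value is positive for the class named first in the
      # "a/b" column label; orient so higher = risk
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      if (first == "risk") dv[, 1] else -dv[, 1]
    },
    random_forest = ,
    extra_trees = stats::predict(model$fit, as.data.frame(x),
                                 num.threads = 1)$predictions[, "risk"],
    adaboost = adaboost_score(model$fit, x),
    knn = knn_score(model$fit, x))
}

predict_class <- function(model, x, threshold = 0.5) {
  s <- predict_scores(model, x)
  cut <- if (model$family == "svm") 0 else threshold
  factor(ifelse(s > cut, "risk", "control"), levels = c("control", "risk"))
}

# ---- AdaBoost (SAMME) over shallow rpart trees ---------------------------
# No boosting implementation for stumps ships with the installed stack,
# so the discrete SAMME recurrence is implemented here over rpart base
# learners.

adaboost_fit <- function(x, y, n_estimators, learning_rate, stump_depth, seed) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(.y = y, x, check.names = FALSE)
  trees <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = stump_depth, cp = 0,
                               minsplit = 2, minbucket = 1, xval = 0)
  for (m in seq_len(n_estimators)) {
    tr <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                       control = ctrl)
    pred <- stats::predict(tr, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5) break
    if (err <= 1e-12) {        # perfect stump: cap its vote, then stop
      trees[[length(trees) + 1L]] <- tr
      alphas <- c(alphas, learning_rate * 10)
      break
    }
    alpha <- learning_rate * log((1 - err) / err)
    trees[[length(trees) + 1L]] <- tr
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (!length(trees)) {        # fall back to the majority class
    maj <- names(which.max(table(y)))
    return(list(trees = list(), alphas = numeric(0), majority = maj))
  }
  list(trees = trees, alphas = alphas, majority = NULL)
}

adaboost_score <- function(fit, x) {
  if (!length(fit$trees))
    return(rep(if (fit$majority == "risk") 1 else 0, nrow(x)))
  df <- as.data.frame(x)
  votes <- vapply(fit$trees, function(tr)
    as.character(stats::predict(tr, df, type = "class")) == "risk",
    logical(nrow(df)))
  votes <- matrix(votes, nrow = nrow(df))
  as.vector(votes %*% fit$alphas) / sum(fit$alphas)
}

# ---- weighted k-nearest neighbours ---------------------------------------
# Class-weighted, optionally distance-weighted voting; written here
# because the installed neighbour classifiers support neither vote
# weighting scheme.

knn_score <- function(fit, x) {
  apply(x, 1, function(q) {
    d <- sqrt(colSums((t(fit$x) - q)^2))
    ord <- order(d, seq_along(d))[seq_len(fit$k)]
    vote <- if (fit$weighting == "distance") 1 / pmax(d[ord], 1e-12) else rep(1, fit$k)
    vote <- vote * fit$class_weights[as.character(fit$y[ord])]
    sum(vote[fit$y[ord] == "risk"]) / sum(vote)
  })
}

# ---- metric assembly -----------------------------------------------------

#' Classification metrics with Wilson intervals
#'
#' Standard definitions with risk as the positive class: accuracy,
#' precision, sensitivity (recall), specificity and F1, each with a
#' Wilson 95% interval. All intervals use the whole-cohort denominator
#' `n_total` — statistically unconventional for the conditional metrics,
#' but adopted deliberately as the reporting convention this pipeline
#' reproduces.
#'
#' @param tp,fn,tn,fp Pooled out-of-fold confusion counts.
#' @param conf Confidence level (default 0.95).
#' @return Data frame: `metric`, `value`, `ci_low`, `ci_high` (all as
#'   proportions in \[0, 1\]).
#' @export
compute_metrics <- function(tp, fn, tn, fp, conf = 0.95) {
  n_total <- tp + fn + tn + fp
  if (n_total == 0) stop("empty confusion table")
  vals <- c(
    accuracy = (tp + tn) / n_total,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
  ci <- t(vapply(vals, function(v) {
    if (is.na(v)) return(c(NA_real_, NA_real_))
    wilson_interval(v * n_total, n_total, conf)  # k = v * n, not rounded
  }, numeric(2)))
  data.frame(metric = names(vals), value = unname(vals),
             ci_low = ci[, 1], ci_high = ci[, 2],
             stringsAsFactors = FALSE)
}

#' Fold-wise and pooled AUC summaries
#'
#' Fold AUCs use the rank statistic within each outer fold (folds with a
#' single class give an undefined AUC and are dropped from the mean with
#' a warning); the pooled AUC is computed on the concatenated
#' out-of-fold scores, with a Hanley-McNeil interval. The two differ in
#' general because AUC is a nonlinear rank statistic.
#'
#' @param scores Out-of-fold risk scores (one per participant).
#' @param labels Labels (factor, `risk` positive).
#' @param fold Outer-fold assignment per participant.
#' @param conf Confidence level.
#' @return List: `fold_auc` (vector), `mean_fold_auc`, `sd_fold_auc`,
#'   `pooled_auc`, `pooled_ci` (low/high).
#' @export
auc_summaries <- function(scores, labels, fold, conf = 0.95) {
  fold_auc <- vapply(sort(unique(fold)), function(f)
    auc_rank(scores[fold == f], labels[fold == f]), numeric(1))
  if (anyNA(fold_auc))
    warning("fold with a single class: its AUC is undefined and excluded from the mean")
  pooled <- auc_rank(scores, labels)
  list(fold_auc = fold_auc,
       mean_fold_auc = mean(fold_auc, na.rm = TRUE),
       sd_fold_auc = stats::sd(fold_auc[!is.na(fold_auc)]),
       pooled_auc = pooled,
       pooled_ci = hanley_mcneil_ci(pooled, sum(labels == "risk"),
                                    sum(labels == "control"), conf))
}

# Inner grid search on one outer-training portion; returns the winning
# grid row (ties broken by grid order).
inner_select <- function(x, y, spec, config, outer_fold_id) {
  folds <- stratified_folds(y, config$inner_folds,
                            derive_seed(config$seed, outer_fold_id, 13L))
  score_grid <- vapply(seq_len(nrow(spec$grid)), function(g) {
    params <- spec$grid[g, , drop = FALSE]
    sc <- rep(NA_real_, length(y))
    for (f in seq_len(config$inner_folds)) {
      tr <- folds != f
      m <- fit_model(spec$family, x[tr, , drop = FALSE], y[tr], params,
                     spec$class_weight,
                     derive_seed(config$seed, outer_fold_id, f, g))
      sc[!tr] <- predict_scores(m, x[!tr, , drop = FALSE])
    }
    if (config$inner_metric == "auc") auc_rank(sc, y)
    else {
      cut <- if (spec$family == "svm") 0 else 0.5
      mean((sc > cut) == (y == "risk"))
    }
  }, numeric(1))
  which.max(score_grid)  # first maximum wins
}

#' Nested stratified cross-validated evaluation
#'
#' Outer stratified folds estimate generalization; within each outer
#' training portion an inner stratified grid search selects the
#' hyperparameters (by pooled inner out-of-fold AUC by default), the
#' model is refit on the full outer-training portion, and predictions,
#' scores and permutation feature importances are recorded on the
#' held-out fold. Every participant is predicted exactly once
#' out-of-fold. The whole procedure is deterministic given
#' `config$seed`.
#'
#' @param x Numeric feature matrix.
#' @param y Factor labels with levels `control`, `risk`.
#' @param spec A [model_spec()].
#' @param config A [cv_config()].
#' @param pfi Also compute permutation feature importance per outer fold
#'   (default `TRUE`).
#' @return A `cv_report` list: `fold` (assignment), `scores`, `pred`
#'   (out-of-fold), `best_params` (per fold), `confusion` (tp/fn/tn/fp),
#'   `metrics` (data frame with Wilson CIs), `auc` (from
#'   [auc_summaries()]), `importance` (named vector, mean over folds; or
#'   `NULL`), `seed`.
#' @export
nested_cv <- function(x, y, spec, config = cv_config(), pfi = TRUE) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- factor(y, levels = c("control", "risk"))
  fold <- stratified_folds(y, config$outer_folds, derive_seed(config$seed, 1L))
  scores <- rep(NA_real_, length(y))
  pred <- factor(rep(NA, length(y)), levels = c("control", "risk"))
  best_params <- vector("list", config$outer_folds)
  imp <- NULL
  for (f in seq_len(config$outer_folds)) {
    tr <- fold != f
    g <- inner_select(x[tr, , drop = FALSE], y[tr], spec, config, f)
    best_params[[f]] <- spec$grid[g, , drop = FALSE]
    model <- fit_model(spec$family, x[tr, , drop = FALSE], y[tr],
                       best_params[[f]], spec$class_weight,
                       derive_seed(config$seed, f, 97L))
    scores[!tr] <- predict_scores(model, x[!tr, , drop = FALSE])
    pred[!tr] <- predict_class(model, x[!tr, , drop = FALSE])
    if (pfi) {
      pfi_f <- permutation_importance(model, x[!tr, , drop = FALSE], y[!tr],
                                      config, fold_id = f)
      imp <- if (is.null(imp)) pfi_f / config$outer_folds
             else imp + pfi_f / config$outer_folds
    }
  }
  stopifnot(!anyNA(scores))
  tp <- sum(pred == "risk" & y == "risk")
  fn <- sum(pred == "control" & y == "risk")
  tn <- sum(pred == "control" & y == "control")
  fp <- sum(pred == "risk" & y == "control")
  structure(list(
    fold = fold, scores = scores, pred = pred, truth = y,
    best_params = best_params,
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    metrics = compute_metrics(tp, fn, tn, fp),
    auc = auc_summaries(scores, y, fold),
    importance = imp, seed = config$seed), class = "cv_report")
}

#' Permutation feature importance on held-out data
#'
#' For each feature, its held-out values are shuffled (all other
#' features unchanged) and the drop in held-out score is recorded;
#' importances average `config$pfi_repeats` seeded permutations. Larger
#' positive values mean the model leans on the feature; values near zero
#' mean it is ignorable; negative values mean permuting it helped.
#'
#' @param model A fitted classifier (internal `pov_classifier`).
#' @param x_test,y_test Held-out features and labels.
#' @param config A [cv_config()].
#' @param fold_id Integer mixed into the permutation seed.
#' @return Named numeric vector of importances (one per feature).
#' @export
permutation_importance <- function(model, x_test, y_test,
                                   config = cv_config(), fold_id = 0L) {
  score_of <- function(xm) {
    if (config$pfi_metric == "auc") return(auc_rank(predict_scores(model, xm), y_test))
    mean(predict_class(model, xm) == y_test)
  }
  baseline <- score_of(x_test)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(config$seed, fold_id, 211L))
  imp <- vapply(seq_len(ncol(x_test)), function(j) {
    drops <- vapply(seq_len(config$pfi_repeats), function(rep_i) {
      xp <- x_test
      xp[, j] <- xp[sample(nrow(xp)), j]
      baseline - score_of(xp)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  stats::setNames(imp, colnames(x_test))
}

#' Demographic-only baseline classifier
#'
#' The same nested cross-validation pipeline run on a two-column
#' age + sex matrix (sex coded 0/1), quantifying how much of the
#' movement models' performance basic demographics could explain.
#'
#' @param age Numeric ages (months).
#' @param sex Character vector (`boy`/`girl`).
#' @param y Labels (factor or character, `risk`/`control`).
#' @param spec A [model_spec()] (default svm, as in the primary model).
#' @param config A [cv_config()].
#' @return A `cv_report` (schema identical to movement-feature reports).
#' @export
demographic_baseline <- function(age, sex, y, spec = model_spec("svm"),
                                 config = cv_config()) {
  x <- cbind(age_months = as.numeric(age),
             sex_boy = as.numeric(sex == "boy"))
  nested_cv(x, factor(y, levels = c("control", "risk")), spec, config)
}

#' @export
print.cv_report <- function(x, ...) {
  acc <- x$metrics$value[x$metrics$metric == "accuracy"]
  cat(sprintf("<cv_report> n=%d | accuracy %.1f%% | mean fold AUC %.2f +/- %.2f | pooled AUC %.2f (%.2f-%.2f)\n",
              length(x$fold), 100 * acc, x$auc$mean_fold_auc, x$auc$sd_fold_auc,
              x$auc$pooled_auc, x$auc$pooled_ci[1], x$auc$pooled_ci[2]))
  invisible(x)
}
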