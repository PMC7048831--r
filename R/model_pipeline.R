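#' Boosted-tree model specification
#'
#' Additive tree ensemble (sum of K regression trees through a logistic link)
#' with L1/L2 regularization, fit by gradient boosting. The positive class is
#' the aberrant state (mutated / methylated / co-deleted); by default the
#' positive class is up-weighted by the class ratio to counter imbalance.
#'
#' @param learning_rate shrinkage per boosting round.
#' @param max_depth maximum tree depth.
#' @param nrounds number of boosting rounds (trees).
#' @param lambda L2 regularization weight; @param alpha L1 weight.
#' @param pos_weight positive-class weight; `NULL` = `N_neg / N_pos`.
#' @param seed integer seed for the booster.
#' @return A `gbt_model_spec` list.
#' @export
gbt_model_spec <- function(learning_rate = 0.3, max_depth = 3, nrounds = 100,
                           lambda = 1, alpha = 0, pos_weight = NULL, seed = 1L) {
  list(learning_rate = learning_rate, max_depth = max_depth,
       nrounds = as.integer(nrounds), lambda = lambda, alpha = alpha,
       pos_weight = pos_weight, seed = as.integer(seed))
}

#' Pipeline configuration for the molecular prediction models
#'
#' @param candidate_sizes feature-set sizes scored during recursive feature
#'   selection (subset of `{2,3,5,7,9,11,13,15}`).
#' @param train_fraction training share of each repeated partition.
#' @param threshold probability threshold for sensitivity/specificity.
#' @param rf_trees random-forest trees for the importance ranking.
#' @param gbt a [gbt_model_spec()].
#' @param n_range inclusive range the number of repetitions is drawn from.
#' @return A `model_config` list.
#' @export
model_config <- function(candidate_sizes = c(2, 3, 5, 7, 9, 11, 13, 15),
                         train_fraction = 0.75, threshold = 0.5,
                         rf_trees = 500, gbt = gbt_model_spec(),
                         n_range = c(10, 15)) {
  if (!all(candidate_sizes %in% c(2, 3, 5, 7, 9, 11, 13, 15)))
    stop("model_config: candidate_sizes must be a subset of {2,3,5,7,9,11,13,15}")
  list(candidate_sizes = sort(as.integer(candidate_sizes)),
       train_fraction = train_fraction, threshold = threshold,
       rf_trees = as.integer(rf_trees), gbt = gbt,
       n_range = as.integer(n_range))
}

as_binary01 <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(as.character(labels) == "positive")
}

#' Binary classification metrics
#'
#' AUC is the normalized Mann-Whitney U statistic (ties count one half);
#' sensitivity and specificity are taken at a fixed probability threshold
#' with the positive class being the aberrant state.
#'
#' @param scores predicted positive-class probabilities.
#' @param labels `positive`/`negative` (or 1/0) per case; both classes must
#'   be present.
#' @param threshold decision threshold (default 0.5).
#' @return List with `auc`, `sensitivity`, `specificity`.
#' @export
evaluate_binary <- function(scores, labels, threshold = 0.5) {
  y <- as_binary01(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) stop("evaluate_binary: both classes required")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  list(auc = auc,
       sensitivity = sum(scores >= threshold & y == 1) / npos,
       specificity = sum(scores < threshold & y == 0) / nneg)
}

#' Stratified train/test partition
#'
#' Training size is `round(train_fraction * N)` with per-class largest-
#' remainder allocation, so class proportions in the training set match the
#' cohort within one case. Deterministic given the seed.
#'
#' @param ids case identifiers.
#' @param labels class labels aligned with `ids` (any discrete coding, >= 2
#'   cases per class).
#' @param train_fraction training share (default 0.75).
#' @param seed integer seed.
#' @return List with `train_ids`, `test_ids`, `seed`.
#' @export
stratified_partition <- function(ids, labels, train_fraction = 0.75, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2)) stop("stratified_partition: every class needs >= 2 cases")
  n_train <- round(train_fraction * length(ids))
  ideal <- as.numeric(tab) * train_fraction
  base <- floor(ideal)
  rem <- n_train - sum(base)
  frac_order <- order(-(ideal - base), names(tab))
  alloc <- base
  if (rem > 0) alloc[frac_order[seq_len(rem)]] <- alloc[frac_order[seq_len(rem)]] + 1
  names(alloc) <- names(tab)
  withr::with_seed(seed, {
    train <- character(0)
    for (cl in names(tab)) {
      members <- ids[labels == cl]
      train <- c(train, sample(members, alloc[[cl]]))
    }
    list(train_ids = sort(train), test_ids = sort(setdiff(ids, train)),
         seed = as.integer(seed))
  })
}

#' Random-forest importance ranking of features
#'
#' Impurity importance from a random-forest fit; the returned order is a
#' strict total order (importance descending, ties broken alphabetically).
#'
#' @param X numeric feature matrix/data frame (cases x features).
#' @param labels class labels (>= 2 classes).
#' @param num_trees forest size.
#' @param seed integer seed.
#' @return Character vector of feature names, most important first.
#' @export
rf_importance_ranking <- function(X, labels, num_trees = 500, seed = 1L) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop("rf_importance_ranking: labels are constant")
  X <- as.data.frame(X)
  fit <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1, verbose = FALSE)
  imp <- fit$variable.importance
  names(imp)[order(-imp, names(imp))]
}

# Lean access to the boosting library's low-level create/update/predict entry
# points. The high-level wrapper re-validates parameters and serializes JSON
# on every call, which dominates run time at nested-LOOCV call volumes
# (hundreds of thousands of one-case fits); the low-level path trains the
# identical model (an equivalence test pins the two routes together).
xgb_low <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- tryCatch({
        ns <- asNamespace("xgboost")
        env <- list(create = get("XGBoosterCreate_R", envir = ns),
                    setparam = get("XGBoosterSetParam_R", envir = ns),
                    update = get("XGBoosterUpdateOneIter_R", envir = ns),
                    pred = get("XGBoosterPredictFromDMatrix_R", envir = ns),
                    handle = get("xgb.get.handle", envir = ns))
        # sanity-check the fast route against the public API once
        Xm <- matrix(as.numeric(1:40), 10, 4)
        y <- rep(c(0, 1), 5)
        spec <- gbt_model_spec(nrounds = 5)
        a <- loocv_scores_lowlevel(Xm, y, spec, env)
        b <- loocv_scores_public(Xm, y, spec)
        stopifnot(max(abs(a - b)) < 1e-7)
        env
      }, error = function(e) FALSE)
    }
    cache
  }
})

xgb_param_strings <- function(gbt, y01) {
  spw <- gbt$pos_weight
  if (is.null(spw)) {
    np <- sum(y01 == 1); nn <- sum(y01 == 0)
    spw <- if (np > 0) nn / np else 1
  }
  c(objective = "binary:logistic",
    eta = as.character(gbt$learning_rate),
    max_depth = as.character(gbt$max_depth),
    lambda = as.character(gbt$lambda),
    alpha = as.character(gbt$alpha),
    scale_pos_weight = as.character(spw),
    nthread = "1",
    seed = as.character(gbt$seed))
}

loocv_scores_lowlevel <- function(Xm, y01, gbt, env) {
  n <- nrow(Xm)
  conf <- paste0('{"training":false,"strict_shape":false,',
                 '"iteration_begin":0,"iteration_end":0,"type":0}')
  scores <- numeric(n)
  for (i in seq_len(n)) {
    dtrain <- xgboost::xgb.DMatrix(Xm[-i, , drop = FALSE], label = y01[-i],
                                   nthread = 1)
    drow <- xgboost::xgb.DMatrix(Xm[i, , drop = FALSE], nthread = 1)
    bst <- .Call(env$create, list(dtrain))
    h <- env$handle(bst)
    pv <- xgb_param_strings(gbt, y01[-i])
    for (p in names(pv)) .Call(env$setparam, h, p, pv[[p]])
    for (r in seq_len(gbt$nrounds)) .Call(env$update, h, as.integer(r - 1), dtrain)
    scores[i] <- as.numeric(.Call(env$pred, h, drow, conf))[1]
  }
  scores
}

loocv_scores_public <- function(Xm, y01, gbt) {
  n <- nrow(Xm)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_gbt_matrix(Xm[-i, , drop = FALSE], y01[-i], gbt)
    scores[i] <- stats::predict(fit, xgboost::xgb.DMatrix(Xm[i, , drop = FALSE]))
  }
  scores
}

# pooled-LOOCV out-of-fold scores of a boosted-tree model on given features
inner_loocv_scores <- function(X, y01, features, gbt) {
  Xm <- as.matrix(X[, features, drop = FALSE])
  env <- xgb_low()
  if (is.environment(env) || is.list(env))
    loocv_scores_lowlevel(Xm, y01, gbt, env)
  else
    loocv_scores_public(Xm, y01, gbt)
}

fit_gbt_matrix <- function(Xm, y01, gbt) {
  spw <- gbt$pos_weight
  if (is.null(spw)) {
    np <- sum(y01 == 1); nn <- sum(y01 == 0)
    spw <- if (np > 0) nn / np else 1
  }
  nclass <- length(unique(y01))
  if (nclass < 2) stop("train_gbt: single-class labels")
  params <- list(objective = "binary:logistic", eta = gbt$learning_rate,
                 max_depth = gbt$max_depth, lambda = gbt$lambda,
                 alpha = gbt$alpha, scale_pos_weight = spw,
                 nthread = 1, seed = gbt$seed)
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(Xm, label = y01),
                     nrounds = gbt$nrounds, verbose = 0)
}

#' @export
predict.gliofract_gbt <- function(object, newdata, ...) {
  Xm <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  stats::predict(object$booster, xgboost::xgb.DMatrix(Xm))
}

#' Train the boosted-tree classifier on selected features
#'
#' @param X feature table (cases x features).
#' @param labels binary labels (`positive`/`negative` or 1/0), both classes
#'   present.
#' @param features feature names to use.
#' @param spec a [gbt_model_spec()].
#' @return A fitted `gliofract_gbt` model with a `predict` method returning
#'   positive-class probabilities.
#' @export
train_gbt <- function(X, labels, features = colnames(X), spec = gbt_model_spec()) {
  y01 <- as_binary01(labels)
  Xm <- as.matrix(as.data.frame(X)[, features, drop = FALSE])
  booster <- fit_gbt_matrix(Xm, y01, spec)
  structure(list(booster = booster, features = features, spec = spec),
            class = "gliofract_gbt")
}

#' Recursive feature selection scored by inner LOOCV
#'
#' Features are first ranked by random-forest importance on all candidates;
#' for each candidate set size (largest first) the surviving features are
#' re-ranked and truncated, and the truncated set is scored by the AUC of the
#' pooled leave-one-out out-of-fold probabilities of the boosted-tree
#' classifier. The chosen size maximizes inner AUC (smallest size on ties).
#'
#' @param X training feature table; @param labels binary labels.
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return List: `per_size` (size -> `features`, `auc`), `chosen_size`,
#'   `chosen_features`, `chosen_auc`.
#' @export
recursive_feature_selection <- function(X, labels, config = model_config(),
                                        seed = 1L) {
  sizes <- sort(config$candidate_sizes, decreasing = TRUE)
  if (nrow(X) < 5 * max(sizes))
    warning("recursive_feature_selection: training set smaller than 5x the ",
            "largest candidate size")
  y01 <- as_binary01(labels)
  ranking <- rf_importance_ranking(X, labels, config$rf_trees, seed)
  current <- ranking
  per_size <- list()
  for (k in sizes) {
    if (length(current) > k) {
      if (length(current) < length(ranking)) # re-rank survivors before pruning
        current <- rf_importance_ranking(X[, current, drop = FALSE], labels,
                                         config$rf_trees, derive_seed(seed, k))
      current <- current[seq_len(k)]
    }
    scores <- inner_loocv_scores(X, y01, current, config$gbt)
    per_size[[as.character(k)]] <-
      list(features = current, auc = evaluate_binary(scores, y01)$auc)
  }
  aucs <- vapply(per_size, function(e) e$auc, 0.0)
  ks <- as.integer(names(per_size))
  best <- max(aucs)
  chosen <- min(ks[aucs >= best - 1e-12])
  list(per_size = per_size[order(ks)],
       chosen_size = chosen,
       chosen_features = per_size[[as.character(chosen)]]$features,
       chosen_auc = best)
}

#' Combine per-fold feature selections into the final set
#'
#' The selection with the uniquely best inner AUC wins; ties are resolved by
#' intersecting the tied sets; an empty intersection falls back to the
#' smallest tied set (flagged).
#'
#' @param selections list of lists with `features` and `auc`.
#' @return Character vector of feature names; attribute `fallback` is `TRUE`
#'   when the empty-intersection fallback was used.
#' @export
final_feature_set <- function(selections) {
  stopifnot(length(selections) > 0)
  aucs <- vapply(selections, function(s) s$auc, 0.0)
  tied <- which(aucs >= max(aucs) - 1e-12)
  sets <- lapply(selections[tied], function(s) s$features)
  sets <- unique(sets)
  if (length(sets) == 1) {
    out <- sets[[1]]
    attr(out, "fallback") <- FALSE
    return(out)
  }
  inter <- Reduce(intersect, sets)
  if (length(inter) > 0) {
    out <- inter
    attr(out, "fallback") <- FALSE
  } else {
    out <- sets[[which.min(lengths(sets))]]
    attr(out, "fallback") <- TRUE
  }
  out
}

#' Outer leave-one-out evaluation with nested feature selection
#'
#' For every held-out case, recursive feature selection and boosted-tree
#' training are re-run on the remaining cases only (no leakage), and the
#' held-out case is scored once. Cross-validated AUC/sensitivity/specificity
#' come from the pooled out-of-fold scores.
#'
#' @param X training feature table; @param labels binary labels.
#' @param config a [model_config()]; @param seed integer seed.
#' @return List: `metrics` (cv auc/sens/spec), `scores` (one out-of-fold
#'   probability per case), `selections` (per-fold chosen features + inner
#'   AUC), `per_size_auc` (matrix folds x candidate sizes of inner AUCs).
#' @export
outer_loocv_evaluate <- function(X, labels, config = model_config(), seed = 1L) {
  n <- nrow(X)
  if (n < 10) stop("outer_loocv_evaluate: need at least 10 cases")
  y01 <- as_binary01(labels)
  scores <- numeric(n)
  selections <- vector("list", n)
  per_size <- matrix(NA_real_, n, length(config$candidate_sizes),
                     dimnames = list(NULL, as.character(config$candidate_sizes)))
  for (i in seq_len(n)) {
    sel <- recursive_feature_selection(X[-i, , drop = FALSE], y01[-i], config,
                                       derive_seed(seed, i))
    fit <- train_gbt(X[-i, , drop = FALSE], y01[-i], sel$chosen_features,
                     config$gbt)
    scores[i] <- predict(fit, X[i, , drop = FALSE])
    selections[[i]] <- list(features = sel$chosen_features, auc = sel$chosen_auc)
    per_size[i, ] <- vapply(sel$per_size, function(e) e$auc, 0.0)
  }
  list(metrics = evaluate_binary(scores, y01, config$threshold),
       scores = scores, selections = selections, per_size_auc = per_size)
}

#' Multiclass metrics with the pairwise-average multiclass AUC
#'
#' One-vs-rest sensitivity and specificity per class under argmax assignment,
#' overall accuracy, and the multiclass AUC
#' `M = 2/(c(c-1)) * sum_{i<j} A_hat(i,j)` where `A_hat` averages the two
#' directed pairwise two-class AUCs (Hand-Till construction).
#'
#' @param scores matrix of per-class probabilities (cases x classes, named
#'   columns).
#' @param labels class label per case (matching column names).
#' @return List: `per_class` (data frame of sensitivity/specificity),
#'   `accuracy`, `multiclass_auc`.
#' @export
multiclass_metrics <- function(scores, labels) {
  classes <- colnames(scores)
  labels <- as.character(labels)
  if (!all(labels %in% classes)) stop("multiclass_metrics: label not in score columns")
  if (any(table(factor(labels, classes)) < 1))
    stop("multiclass_metrics: every class must be present")
  pred <- classes[max.col(scores, ties.method = "first")]
  per_class <- data.frame(class = classes,
    sensitivity = vapply(classes, function(cl)
      sum(pred == cl & labels == cl) / sum(labels == cl), 0.0),
    specificity = vapply(classes, function(cl)
      sum(pred != cl & labels != cl) / sum(labels != cl), 0.0))
  pair_auc <- function(ci, cj) {
    sub <- labels %in% c(ci, cj)
    a_ij <- evaluate_binary(scores[sub, ci], as.integer(labels[sub] == ci))$auc
    a_ji <- evaluate_binary(scores[sub, cj], as.integer(labels[sub] == cj))$auc
    (a_ij + a_ji) / 2
  }
  cc <- length(classes)
  total <- 0
  for (i in seq_len(cc - 1)) for (j in (i + 1):cc)
    total <- total + pair_auc(classes[i], classes[j])
  list(per_class = per_class,
       accuracy = mean(pred == labels),
       multiclass_auc = 2 * total / (cc * (cc - 1)))
}

#' Repeated-partition molecular prediction runs
#'
#' Draws the number of repetitions uniformly from `n_range` (or uses
#' `n_reps`), and for each repetition: a fresh stratified 75/25 partition,
#' nested-LOOCV recursive feature selection on the training set, a final
#' boosted-tree model on the selected features, and test-set evaluation. The
#' `without_fractal` variant first removes the fractal characterization-map
#' features. Both variants of one repetition share the same partition, so
#' with/without comparisons are paired.
#'
#' @param features cohort feature table (rows = cases).
#' @param labels binary labels aligned with the rows (`positive`/`negative`);
#'   `NA` rows are dropped.
#' @param config a [model_config()].
#' @param master_seed integer seed controlling everything.
#' @param variant `"both"`, `"with_fractal"` or `"without_fractal"`.
#' @param n_reps fixed repetition count overriding the random draw.
#' @return A `model_run_result` list: `runs` (one row per repetition x
#'   variant with cv and test metrics), `selected` (feature sets), `sweep`
#'   (per-size inner AUC per repetition), `n_reps`.
#' @export
run_repetitions <- function(features, labels, config = model_config(),
                            master_seed = 1L,
                            variant = c("both", "with_fractal", "without_fractal"),
                            n_reps = NULL) {
  variant <- match.arg(variant)
  keep <- !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- as.character(labels[keep])
  ids <- rownames(features)
  if (is.null(n_reps))
    n_reps <- withr::with_seed(derive_seed(master_seed, 1),
      config$n_range[1] +
        sample.int(config$n_range[2] - config$n_range[1] + 1, 1) - 1L)
  variants <- if (variant == "both") c("with_fractal", "without_fractal") else variant
  frac_cols <- fractal_feature_subset(colnames(features))
  runs <- list(); selected <- list(); sweep <- list()
  for (r in seq_len(n_reps)) {
    part <- stratified_partition(ids, labels, config$train_fraction,
                                 derive_seed(master_seed, 100 + r))
    tr <- match(part$train_ids, ids); te <- match(part$test_ids, ids)
    for (v in variants) {
      Xv <- features
      if (v == "without_fractal")
        Xv <- Xv[, setdiff(colnames(Xv), frac_cols), drop = FALSE]
      outer <- outer_loocv_evaluate(Xv[tr, , drop = FALSE], labels[tr], config,
                                    derive_seed(master_seed, 200 + r))
      final_set <- final_feature_set(outer$selections)
      fit <- train_gbt(Xv[tr, , drop = FALSE], labels[tr], final_set, config$gbt)
      test_scores <- predict(fit, Xv[te, , drop = FALSE])
      test <- evaluate_binary(test_scores, labels[te], config$threshold)
      runs[[length(runs) + 1]] <- data.frame(
        repetition = r, variant = v,
        cv_auc = outer$metrics$auc, cv_sens = outer$metrics$sensitivity,
        cv_spec = outer$metrics$specificity,
        test_auc = test$auc, test_sens = test$sensitivity,
        test_spec = test$specificity,
        n_selected = length(final_set))
      selected[[paste(r, v, sep = ".")]] <- as.character(final_set)
      sweep[[paste(r, v, sep = ".")]] <-
        c(repetition = r, variant = v, colMeans(outer$per_size_auc))
    }
  }
  structure(list(runs = do.call(rbind, runs), selected = selected,
                 sweep = sweep, n_reps = n_reps, variant = variant),
            class = "model_run_result")
}

#' Summary table of repeated runs (mean and SD per metric)
#'
#' @param object a `model_run_result`.
#' @param ... unused.
#' @return Data frame: one row per variant with `n` and mean/SD of each
#'   metric.
#' @export
summary.model_run_result <- function(object, ...) {
  runs <- object$runs
  do.call(rbind, lapply(split(runs, runs$variant), function(d) {
    metrics <- c("cv_auc", "cv_sens", "cv_spec", "test_auc", "test_sens", "test_spec")
    out <- data.frame(variant = d$variant[1], n = nrow(d))
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    out
  }))
}

# multiclass boosted-tree fit + probability prediction
fit_gbt_multiclass <- function(Xm, y, gbt) {
  classes <- levels(factor(y))
  params <- list(objective = "multi:softprob", num_class = length(classes),
                 eta = gbt$learning_rate, max_depth = gbt$max_depth,
                 lambda = gbt$lambda, alpha = gbt$alpha, nthread = 1,
                 seed = gbt$seed)
  booster <- xgboost::xgb.train(params = params,
    data = xgboost::xgb.DMatrix(Xm, label = as.integer(factor(y)) - 1L),
    nrounds = gbt$nrounds, verbose = 0)
  list(booster = booster, classes = classes)
}

predict_gbt_multiclass <- function(fit, Xm) {
  p <- stats::predict(fit$booster, xgboost::xgb.DMatrix(Xm))
  m <- matrix(p, ncol = length(fit$classes), byrow = TRUE)
  colnames(m) <- fit$classes
  m
}

#' Repeated-partition 3-class molecular subtype prediction
#'
#' The three LGG molecular subtypes (IDH wild-type, IDH mutant with 1p/19q
#' co-deletion, IDH mutant without co-deletion) are predicted jointly with
#' the same repeated-partition scheme: random-forest feature ranking with
#' inner-LOOCV scoring by multiclass AUC, then a softmax boosted-tree model.
#'
#' @param features cohort feature table.
#' @param labels3 3-class label per row (`NA` dropped).
#' @param config a [model_config()]; @param master_seed integer seed.
#' @param n_reps number of repetitions (default 5).
#' @return List: `runs` (per-repetition cv/test accuracy and multiclass AUC
#'   plus per-class sensitivity/specificity), `summary` (means and SDs).
#' @export
run_multiclass_repetitions <- function(features, labels3,
                                       config = model_config(),
                                       master_seed = 1L, n_reps = 5) {
  keep <- !is.na(labels3)
  features <- features[keep, , drop = FALSE]
  labels3 <- as.character(labels3[keep])
  ids <- rownames(features)
  runs <- list()
  for (r in seq_len(n_reps)) {
    part <- stratified_partition(ids, labels3, config$train_fraction,
                                 derive_seed(master_seed, 300 + r))
    tr <- match(part$train_ids, ids); te <- match(part$test_ids, ids)
    Xtr <- features[tr, , drop = FALSE]; ytr <- labels3[tr]
    ranking <- rf_importance_ranking(Xtr, ytr, config$rf_trees,
                                     derive_seed(master_seed, 400 + r))
    # inner LOOCV over candidate sizes, scored by multiclass AUC
    best <- NULL
    for (k in sort(config$candidate_sizes, decreasing = TRUE)) {
      feats <- ranking[seq_len(min(k, length(ranking)))]
      Xm <- as.matrix(Xtr[, feats, drop = FALSE])
      oof <- matrix(NA_real_, nrow(Xm), length(unique(ytr)),
                    dimnames = list(NULL, levels(factor(ytr))))
      for (i in seq_len(nrow(Xm))) {
        fit <- fit_gbt_multiclass(Xm[-i, , drop = FALSE], ytr[-i], config$gbt)
        oof[i, ] <- predict_gbt_multiclass(fit, Xm[i, , drop = FALSE])
      }
      m <- multiclass_metrics(oof, ytr)
      if (is.null(best) || m$multiclass_auc >= best$auc + 1e-12)
        best <- list(features = feats, auc = m$multiclass_auc, cv = m)
    }
    fit <- fit_gbt_multiclass(as.matrix(Xtr[, best$features, drop = FALSE]),
                              ytr, config$gbt)
    test_scores <- predict_gbt_multiclass(
      fit, as.matrix(features[te, best$features, drop = FALSE]))
    test <- multiclass_metrics(test_scores, labels3[te])
    runs[[r]] <- list(repetition = r, cv = best$cv, test = test,
                      features = best$features)
  }
  cvA <- vapply(runs, function(x) x$cv$multiclass_auc, 0.0)
  teA <- vapply(runs, function(x) x$test$multiclass_auc, 0.0)
  cvAcc <- vapply(runs, function(x) x$cv$accuracy, 0.0)
  teAcc <- vapply(runs, function(x) x$test$accuracy, 0.0)
  list(runs = runs,
       summary = data.frame(
         metric = c("cv_multiclass_auc", "test_multiclass_auc",
                    "cv_accuracy", "test_accuracy"),
         mean = c(mean(cvA), mean(teA), mean(cvAcc), mean(teAcc)),
         sd = c(stats::sd(cvA), stats::sd(teA), stats::sd(cvAcc), stats::sd(teAcc))))
}
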