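test_that("stratified partition reproduces the 75/25 arithmetic", {
  ids <- sprintf("c%03d", 1:108)
  labs <- c(rep("positive", 85), rep("negative", 23))
  p <- stratified_partition(ids, labs, 0.75, 1)
  expect_length(p$train_ids, 81)
  expect_length(p$test_ids, 27)
  expect_length(intersect(p$train_ids, p$test_ids), 0)
  # per-class proportions within one case of the cohort proportions
  tr_pos <- sum(labs[match(p$train_ids, ids)] == "positive")
  expect_lte(abs(tr_pos - 0.75 * 85), 1)
  # exact stratification on a balanced toy cohort
  p8 <- stratified_partition(sprintf("x%d", 1:8), rep(c("a", "b"), 4), 0.75, 2)
  expect_length(p8$train_ids, 6)
  expect_identical(p, stratified_partition(ids, labs, 0.75, 1))
  expect_error(stratified_partition(c("a", "b", "c"), c("p", "p", "n")), ">= 2 cases")
})

test_that("AUC equals brute-force pair counting", {
  ev <- evaluate_binary(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(ev$auc, 0.75) # 3 of 4 pairs ordered
  perfect <- evaluate_binary(c(0.1, 0.2, 0.8, 0.9), c("negative", "negative", "positive", "positive"))
  expect_equal(unlist(perfect), c(auc = 1, sensitivity = 1, specificity = 1))
  expect_equal(evaluate_binary(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(evaluate_binary(1:3 / 4, c(1, 1, 1)), "both classes")
  for (s in 1:30) {
    n <- withr::with_seed(s, sample(5:50, 1))
    scores <- withr::with_seed(s + 100, round(runif(n), 2)) # coarse grid forces ties
    y <- withr::with_seed(s + 200, rbinom(n, 1, 0.5))
    if (length(unique(y)) < 2) next
    expect_equal(evaluate_binary(scores, y)$auc, pair_count_auc(scores, y),
                 info = paste("seed", s))
  }
})

test_that("random-forest ranking finds planted informative features", {
  hits <- sapply(1:20, function(s) {
    d <- toy_feature_table(n = 60, p_noise = 98, n_inf = 2, effect = 2, seed = s)
    rk <- rf_importance_ranking(d$X, d$y, 300, seed = s)
    all(c("inf01", "inf02") %in% rk[1:5])
  })
  expect_gte(mean(hits), 0.9)
  d <- toy_feature_table(n = 40, p_noise = 30, n_inf = 2, effect = 0, seed = 1)
  winners <- sapply(1:10, function(s) rf_importance_ranking(d$X, d$y, 100, s)[1])
  expect_gt(length(unique(winners)), 1) # no stable winner without signal
  expect_identical(rf_importance_ranking(d$X, d$y, 100, 7),
                   rf_importance_ranking(d$X, d$y, 100, 7))
})

test_that("recursive selection recovers planted features and scores the full grid", {
  cfg <- model_config(rf_trees = 200, gbt = gbt_model_spec(nrounds = 15))
  found <- sapply(1:15, function(s) {
    d <- toy_feature_table(n = 36, p_noise = 40, n_inf = 2, effect = 2.5, seed = s)
    sel <- suppressWarnings(recursive_feature_selection(d$X, d$y, cfg, seed = s))
    expect_setequal(names(sel$per_size), as.character(c(2, 3, 5, 7, 9, 11, 13, 15)))
    all(c("inf01", "inf02") %in% sel$chosen_features)
  })
  expect_gte(mean(found), 0.8)
})

test_that("tied per-fold selections are combined by intersection", {
  expect_equal(final_feature_set(list(list(features = c("a", "b", "c"), auc = 0.9))),
               c("a", "b", "c"), ignore_attr = TRUE)
  tied <- final_feature_set(list(list(features = c("a", "b", "c"), auc = 0.9),
                                 list(features = c("b", "c", "d"), auc = 0.9),
                                 list(features = c("a", "b"), auc = 0.5)))
  expect_setequal(as.character(tied), c("b", "c"))
  disj <- final_feature_set(list(list(features = c("a", "b"), auc = 0.9),
                                 list(features = c("c"), auc = 0.9)))
  expect_true(attr(disj, "fallback"))
  expect_equal(as.character(disj), "c") # smallest tied set
})

test_that("boosted trees separate separable data and stay at chance on nulls", {
  d <- toy_feature_table(n = 30, p_noise = 0, n_inf = 2, effect = 6, seed = 3)
  fit <- train_gbt(d$X, d$y, spec = gbt_model_spec(nrounds = 30))
  tr_auc <- evaluate_binary(predict(fit, d$X), as.integer(d$y == "positive"))$auc
  expect_equal(tr_auc, 1.0)
  expect_error(train_gbt(d$X, rep("positive", 30)), "single-class")
  null_auc <- sapply(1:20, function(s) {
    d <- toy_feature_table(n = 40, p_noise = 8, n_inf = 2, effect = 0, seed = s)
    perm <- withr::with_seed(s, sample(d$y))
    fit <- train_gbt(d$X[1:30, ], perm[1:30], spec = gbt_model_spec(nrounds = 15, seed = s))
    evaluate_binary(predict(fit, d$X[31:40, ]), as.integer(perm[31:40] == "positive"))$auc
  })
  expect_gte(mean(null_auc), 0.35); expect_lte(mean(null_auc), 0.65)
})

test_that("outer LOOCV scores every case exactly once and resists leakage", {
  cfg <- model_config(candidate_sizes = c(2, 3, 5), rf_trees = 150,
                      gbt = gbt_model_spec(nrounds = 15))
  d <- toy_feature_table(n = 16, p_noise = 10, n_inf = 2, effect = 2.5, seed = 4)
  out <- suppressWarnings(outer_loocv_evaluate(d$X, d$y, cfg, seed = 1))
  expect_length(out$scores, 16)
  expect_true(all(out$scores > 0 & out$scores < 1))
  expect_equal(dim(out$per_size_auc), c(16, 3))
  expect_gt(out$metrics$auc, 0.8)
  # canary: a feature equal to the label on held-out rows only must not leak
  d2 <- toy_feature_table(n = 20, p_noise = 10, n_inf = 0, effect = 0, seed = 5)
  y01 <- as.integer(d2$y == "positive")
  aucs <- sapply(1:8, function(r) {
    X <- d2$X
    X$canary <- withr::with_seed(r, rnorm(20))
    tr <- 1:12; te <- 13:20
    X$canary[te] <- y01[te] # informative only on test rows
    sel <- suppressWarnings(recursive_feature_selection(
      X[tr, ], d2$y[tr], model_config(candidate_sizes = c(2, 3), rf_trees = 100,
                                      gbt = gbt_model_spec(nrounds = 10)), seed = r))
    fit <- train_gbt(X[tr, ], d2$y[tr], sel$chosen_features, gbt_model_spec(nrounds = 10))
    evaluate_binary(predict(fit, X[te, ]), y01[te])$auc
  })
  expect_lte(mean(aucs), 0.8) # no test-row information reaches training
})

test_that("multiclass metrics match the pairwise-average construction", {
  sc <- rbind(c(0.8, 0.1, 0.1), c(0.7, 0.2, 0.1),
              c(0.1, 0.8, 0.1), c(0.2, 0.7, 0.1),
              c(0.1, 0.1, 0.8), c(0.1, 0.2, 0.7))
  colnames(sc) <- c("A", "B", "C")
  labs <- c("A", "A", "B", "B", "C", "C")
  m <- multiclass_metrics(sc, labs)
  expect_equal(m$multiclass_auc, 1)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$sensitivity == 1))
  # null calibration
  nulls <- sapply(1:50, function(s) {
    sc <- withr::with_seed(s, matrix(runif(60), 20, 3,
                                     dimnames = list(NULL, c("A", "B", "C"))))
    labs <- rep(c("A", "B", "C"), length.out = 20)
    multiclass_metrics(sc / rowSums(sc), labs)$multiclass_auc
  })
  expect_gte(mean(nulls), 0.45); expect_lte(mean(nulls), 0.55)
  expect_error(multiclass_metrics(sc, rep("A", 6)), "every class")
})

test_that("repeated runs draw n in range and are reproducible", {
  d <- toy_feature_table(n = 20, p_noise = 10, n_inf = 2, effect = 3, seed = 6)
  cfg <- model_config(candidate_sizes = c(2, 3), rf_trees = 100,
                      gbt = gbt_model_spec(nrounds = 10), n_range = c(2, 3))
  res <- suppressWarnings(run_repetitions(d$X, d$y, cfg, master_seed = 11,
                                          variant = "with_fractal"))
  expect_true(res$n_reps >= 2 && res$n_reps <= 3)
  expect_true(all(res$runs$test_auc >= 0 & res$runs$test_auc <= 1))
  res2 <- suppressWarnings(run_repetitions(d$X, d$y, cfg, master_seed = 11,
                                           variant = "with_fractal"))
  expect_identical(res$runs, res2$runs)
  sm <- summary(res)
  expect_true(all(c("test_auc_mean", "test_auc_sd") %in% names(sm)))
  sw <- feature_count_sweep(res, "with_fractal")
  expect_equal(sw$size, c(2, 3))
  expect_true(all(sw$mean_auc >= 0 & sw$mean_auc <= 1))
})

test_that("3-class repeated runs report per-class and pairwise-average metrics", {
  withr::with_seed(8, {
    y3 <- rep(c("IDH_WT", "IDHmut_codel", "IDHmut_noncodel"), each = 8)
    X <- data.frame(f1 = rnorm(24) + 2 * (y3 == "IDH_WT"),
                    f2 = rnorm(24) + 2 * (y3 == "IDHmut_codel"),
                    n1 = rnorm(24), n2 = rnorm(24), n3 = rnorm(24))
    rownames(X) <- sprintf("m%02d", 1:24)
  })
  cfg <- model_config(candidate_sizes = c(2, 3), rf_trees = 100,
                      gbt = gbt_model_spec(nrounds = 8))
  res <- suppressWarnings(run_multiclass_repetitions(X, y3, cfg,
                                                     master_seed = 3, n_reps = 2))
  expect_length(res$runs, 2)
  expect_equal(nrow(res$runs[[1]]$test$per_class), 3)
  expect_true(all(res$summary$mean >= 0 & res$summary$mean <= 1))
  expect_gt(res$summary$mean[res$summary$metric == "test_multiclass_auc"], 0.6)
})

test_that("low-level and public boosting routes produce identical LOOCV scores", {
  expect_false(isFALSE(gliofract:::xgb_low())) # fast route must self-verify
  withr::with_seed(17, {
    Xm <- matrix(rnorm(30 * 6), 30, 6)
    y <- rbinom(30, 1, 0.5)
  })
  spec <- gbt_model_spec(nrounds = 12, max_depth = 2)
  a <- gliofract:::loocv_scores_lowlevel(Xm, y, spec, gliofract:::xgb_low())
  b <- gliofract:::loocv_scores_public(Xm, y, spec)
  expect_equal(a, b, tolerance = 1e-7)
})
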