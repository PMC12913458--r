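# compact planted feature table: informative columns in chosen domains,
# pure noise elsewhere, on the canonical 80-column schema
planted_table <- function(n_per_group = 30, effects = NULL, seed = 1) {
  set.seed(seed)
  cols <- feature_names()
  n <- 2 * n_per_group
  x <- matrix(rnorm(n * length(cols)), n, dimnames = list(NULL, cols))
  y <- rep(c("NT", "ASD"), each = n_per_group)
  for (f in names(effects))
    x[y == "ASD", f] <- x[y == "ASD", f] + effects[[f]]
  list(x = as.data.frame(x), y = factor(y, levels = c("NT", "ASD")))
}

test_that("confusion metrics match direct arithmetic on random tables", {
  m <- evaluate_metrics(3, 2, 2, 1)
  expect_equal(unname(m), c(62.5, 75, 50, 200 / 3), tolerance = 1e-9)
  expect_equal(unname(evaluate_metrics(10, 0, 10, 0)), rep(100, 4))
  pa <- suppressWarnings(evaluate_metrics(5, 5, 0, 0)) # always-positive
  expect_equal(pa[["sensitivity"]], 100)
  expect_equal(pa[["specificity"]], 0)
  set.seed(50)
  for (i in 1:100) {
    cm <- sample(0:20, 4, replace = TRUE)
    if (cm[1] + cm[4] == 0 || cm[3] + cm[2] == 0 || cm[1] + cm[2] == 0) next
    m <- suppressWarnings(evaluate_metrics(cm[1], cm[2], cm[3], cm[4]))
    expect_equal(m[["accuracy"]], 100 * (cm[1] + cm[3]) / sum(cm))
    expect_equal(m[["sensitivity"]], 100 * cm[1] / (cm[1] + cm[4]))
    expect_equal(m[["specificity"]], 100 * cm[3] / (cm[3] + cm[2]))
  }
  expect_error(evaluate_metrics(-1, 0, 1, 0), "negative")
})

test_that("stratified folds balance classes and keep subjects together", {
  y <- rep(c(0, 1), each = 25)
  f <- stratified_folds(y, 5, seed = 3)
  expect_equal(as.vector(table(f)), rep(10, 5))
  for (k in 1:5) expect_equal(sum(y[f == k]), 5) # balanced
  subj <- rep(sprintf("s%02d", 1:10), each = 5)
  ys <- rep(c(0, 1), each = 25)
  fg <- stratified_folds(ys, 5, seed = 3, subject = subj)
  expect_true(all(tapply(fg, subj, function(v) length(unique(v))) == 1))
})

test_that("a separable planted cohort is classified accurately and deterministically", {
  pt <- planted_table(30, effects = list(state_0_coverage = 2.5,
                                         delta_power_state3 = 2.5,
                                         ngram_entropy = 2.5), seed = 2)
  ev <- cross_validated_eval(pt$x, pt$y, classifiers = c("logreg", "xgb"),
                             folds = 5, search_iters = 4, seed = 42,
                             unit = "epoch")
  expect_gte(max(ev$accuracy_mean), 85)
  expect_true(all(ev$auc >= 0.9))
  ev2 <- cross_validated_eval(pt$x, pt$y, classifiers = c("logreg", "xgb"),
                              folds = 5, search_iters = 4, seed = 42,
                              unit = "epoch")
  expect_identical(ev, ev2)
  expect_error(cross_validated_eval(pt$x, pt$y, classifiers = "nope",
                                    folds = 5), "unknown classifier")
})

test_that("every roster member runs and returns sane metrics on an easy problem", {
  pt <- planted_table(20, effects = list(switching_rate = 3,
                                         sampen_s1 = 3), seed = 4)
  ev <- cross_validated_eval(pt$x, pt$y, # full 80-column table
                             classifiers = c("rf", "svm_rbf", "mlp",
                                             "boost_hist", "stack"),
                             folds = 4, search_iters = 2, seed = 7,
                             unit = "epoch")
  expect_equal(nrow(ev), 5)
  expect_true(all(is.finite(ev$accuracy_mean)))
  expect_true(all(ev$accuracy_mean >= 0 & ev$accuracy_mean <= 100))
  expect_true(all(ev$accuracy_mean > 60)) # d ~ 4.2 combined signal
})

test_that("randomly permuted labels yield chance-level accuracy", {
  pt <- planted_table(28, effects = list(state_0_coverage = 3), seed = 5)
  set.seed(51)
  yperm <- sample(as.character(pt$y))
  ev <- cross_validated_eval(pt$x, factor(yperm, levels = c("NT", "ASD")),
                             classifiers = "xgb", folds = 7,
                             search_iters = 2, seed = 9, unit = "epoch")
  expect_gte(ev$accuracy_mean, 40)
  expect_lte(ev$accuracy_mean, 60)
})

test_that("fold preprocessing is fit on the training split only (no leakage)", {
  set.seed(52)
  x <- matrix(rnorm(40 * 3), 40)
  x[1, 2] <- NaN
  pp <- microstatr:::fold_preprocess(x[1:30, ], x[31:40, ],
                                     "impute_median", scale = TRUE)
  med <- median(x[2:30, 2])
  mu <- colMeans(rbind(x[2:30, , drop = FALSE],
                       c(x[1, 1], med, x[1, 3])))[2]
  # imputed from training rows only, then scaled by training statistics
  expect_equal(pp$train[1, 2] * sd(c(x[2:30, 2], med)) + mean(c(x[2:30, 2], med)),
               med, tolerance = 1e-9)
  expect_error(microstatr:::fold_preprocess(x[1:30, ], x[31:40, ],
                                            "error", TRUE), "non-finite")
})

test_that("cumulative ablation walks the canonical domain stages", {
  pt <- planted_table(30, effects = list(
    state_0_coverage = 1.2, switching_rate = 1.0, # temporal
    delta_power_state3 = 1.5, # spectral
    sampen_s1 = 1.2, # complexity
    ngram_entropy = 1.6), seed = 6) # higher-order
  ab <- cumulative_ablation(pt$x, pt$y, folds = 5, search_iters = 3,
                            seed = 42, unit = "epoch")
  expect_equal(ab$n_features, c(35, 55, 70, 80))
  expect_equal(nrow(ab), 4)
  expect_true(all(is.finite(ab$accuracy_mean)))
  expect_equal(ab$increment[-1],
               diff(ab$accuracy_mean), tolerance = 1e-9)
  expect_error(cumulative_ablation(pt$x[, 1:10], pt$y), "missing")
})

test_that("tree-path attributions are additive and rank the true signal first", {
  pt <- planted_table(40, effects = list(plv_sync = 3), seed = 8)
  xm <- as.matrix(pt$x)
  m <- fit_xgb(xm, as.numeric(pt$y == "ASD"),
               list(nrounds = 100, max_depth = 3), seed = 1)
  ar <- attribution_rank(m, xm, k = 20)
  expect_equal(ar$ranking[1], "plv_sync")
  expect_equal(sort(ar$ranking), sort(colnames(xm)))
  expect_true(all(ar$importance >= 0))
  # local accuracy: contributions (incl. bias) sum to the logit margin
  marg <- predict(m, xgboost::xgb.DMatrix(xm), outputmargin = TRUE)
  expect_equal(unname(rowSums(ar$contributions)), unname(marg),
               tolerance = 1e-5)
  # a constant feature cannot receive attribution
  xm2 <- xm; xm2[, "dfa_s1"] <- 1
  m2 <- fit_xgb(xm2, as.numeric(pt$y == "ASD"), list(nrounds = 50), seed = 1)
  ar2 <- attribution_rank(m2, xm2)
  expect_equal(unname(ar2$importance[["dfa_s1"]]), 0)
  expect_error(attribution_rank(lm(rnorm(10) ~ 1), xm), "unsupported")
})

test_that("top-k retraining keeps accuracy when the signal is concentrated", {
  pt <- planted_table(30, effects = list(hurst_s2 = 4), seed = 9)
  xm <- as.matrix(pt$x)
  m <- fit_xgb(xm, as.numeric(pt$y == "ASD"), list(nrounds = 100), seed = 2)
  ar <- attribution_rank(m, xm)
  expect_equal(ar$ranking[1], "hurst_s2")
  full <- cross_validated_eval(pt$x, pt$y, classifiers = "xgb", folds = 5,
                               search_iters = 3, seed = 42, unit = "epoch")
  top1 <- topk_retrain(pt$x, pt$y, ar$ranking, k = 1, folds = 5, seed = 42,
                       unit = "epoch",
                       grid = expand.grid(eta = c(0.1, 0.3), max_depth = 2:3,
                                          nrounds = 50))
  expect_gte(top1$metrics$accuracy_mean, full$accuracy_mean - 5)
  expect_error(topk_retrain(pt$x, pt$y, ar$ranking, k = 999), "exceeds")
  # perfect scorer has unit ROC area
  roc <- pROC::roc(response = rep(0:1, each = 10),
                   predictor = c(rnorm(10), rnorm(10) + 100), quiet = TRUE,
                   levels = c(0, 1), direction = "<")
  expect_equal(as.numeric(pROC::auc(roc)), 1)
})
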