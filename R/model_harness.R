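#' @title Cross-validated classification harness
#' @description
#' Stratified k-fold evaluation of a roster of classifiers (regularized
#' logistic regression, random forest, RBF-kernel SVM, a shallow
#' feed-forward network, two gradient-boosted tree ensembles, and a
#' stacked ensemble of the boosters with a logistic meta-learner) with
#' randomized hyperparameter search nested inside the training split,
#' leakage-safe subject-grouped folds, cumulative-domain ablation,
#' exact tree-path Shapley attributions and top-k retraining.
#' @name model_harness
NULL

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (recall of the positive class), specificity and
#' F1 score, all in percent. Ratios with a zero denominator return `NaN`
#' with a warning.
#'
#' @param tp,fp,tn,fn nonnegative confusion counts.
#' @return Named numeric vector (`accuracy`, `sensitivity`, `specificity`,
#'   `f1`), in percent.
#' @export
evaluate_metrics <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stopf("negative confusion counts")
  safe <- function(num, den, what) {
    if (den == 0) { warnf("%s undefined (zero denominator)", what); NaN }
    else num / den
  }
  acc <- safe(tp + tn, tp + fp + tn + fn, "accuracy")
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (!is.finite(prec) || !is.finite(sens) || prec + sens == 0) {
    warnf("F1 undefined")
    NaN
  } else 2 * prec * sens / (prec + sens)
  100 * c(accuracy = acc, sensitivity = sens, specificity = spec, f1 = f1)
}

# ---- classifier registry -------------------------------------------------

# Each entry: sample(rng-active) -> params list; fit(x, y01, params, seed);
# prob(fit, x) -> P(positive).
classifier_registry <- function() {
  list(
    logreg = list(
      sample = function() list(alpha = sample(c(0, 1), 1),
                               lambda = 10^runif(1, -4, 0)),
      fit = function(x, y, p, seed) with_seed(seed,
        glmnet::glmnet(x, y, family = "binomial", alpha = p$alpha,
                       lambda = p$lambda)),
      prob = function(m, x) as.numeric(predict(m, x, type = "response"))),
    rf = list(
      sample = function() list(mtry = sample(2:20, 1),
                               nodesize = sample(1:5, 1), ntree = 300),
      fit = function(x, y, p, seed) with_seed(seed,
        randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                   ntree = p$ntree,
                                   mtry = min(p$mtry, ncol(x)),
                                   nodesize = p$nodesize)),
      prob = function(m, x) predict(m, x, type = "prob")[, "1"]),
    svm_rbf = list(
      sample = function() list(cost = 10^runif(1, -2, 3),
                               gamma = 10^runif(1, -4, 0)),
      fit = function(x, y, p, seed) with_seed(seed,
        e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                   cost = p$cost, gamma = p$gamma, probability = TRUE,
                   scale = FALSE)),
      prob = function(m, x)
        attr(predict(m, x, probability = TRUE), "probabilities")[, "1"]),
    mlp = list(
      sample = function() list(size = sample(2:16, 1),
                               decay = 10^runif(1, -4, 0)),
      fit = function(x, y, p, seed) with_seed(seed,
        nnet::nnet(x, y, size = p$size, decay = p$decay, maxit = 200,
                   entropy = TRUE, trace = FALSE, MaxNWts = 20000)),
      prob = function(m, x) as.numeric(predict(m, x))),
    xgb = list(
      sample = function() list(eta = 10^runif(1, -2, -0.3),
                               max_depth = sample(2:6, 1),
                               subsample = runif(1, 0.6, 1),
                               colsample_bytree = runif(1, 0.5, 1),
                               nrounds = sample(c(50, 100, 200), 1)),
      fit = function(x, y, p, seed) fit_xgb(x, y, p, seed),
      prob = function(m, x) predict(m, xgboost::xgb.DMatrix(x))),
    boost_hist = list( # leaf-wise histogram growth
      sample = function() list(eta = 10^runif(1, -2, -0.3),
                               max_leaves = sample(c(7, 15, 31), 1),
                               subsample = runif(1, 0.6, 1),
                               colsample_bytree = runif(1, 0.5, 1),
                               nrounds = sample(c(50, 100, 200), 1)),
      fit = function(x, y, p, seed) fit_xgb(x, y, p, seed, lossguide = TRUE),
      prob = function(m, x) predict(m, xgboost::xgb.DMatrix(x))),
    stack = list(
      sample = function() list(eta = 10^runif(1, -2, -0.3),
                               max_depth = sample(2:6, 1),
                               max_leaves = sample(c(7, 15, 31), 1),
                               subsample = runif(1, 0.6, 1),
                               colsample_bytree = runif(1, 0.5, 1),
                               nrounds = sample(c(50, 100), 1)),
      fit = function(x, y, p, seed) fit_stack(x, y, p, seed),
      prob = function(m, x) predict_stack(m, x))
  )
}

#' Fit a gradient-boosted tree classifier
#'
#' Thin wrapper over `xgboost::xgb.train` (binary logistic objective,
#' single thread for determinism). With `lossguide = TRUE` trees grow
#' leaf-wise on histograms (`tree_method = "hist"`,
#' `grow_policy = "lossguide"`) instead of depth-wise.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 numeric labels (1 = positive class).
#' @param params list with `eta`, `max_depth` or `max_leaves`,
#'   `subsample`, `colsample_bytree`, `nrounds`.
#' @param seed RNG seed.
#' @param lossguide leaf-wise growth.
#' @return An `xgb.Booster`.
#' @export
fit_xgb <- function(x, y, params = list(), seed = 42, lossguide = FALSE) {
  p <- utils::modifyList(list(eta = 0.1, max_depth = 3, subsample = 0.9,
                              colsample_bytree = 0.9, nrounds = 100,
                              max_leaves = 15), params)
  xp <- list(objective = "binary:logistic", eta = p$eta,
             subsample = p$subsample, colsample_bytree = p$colsample_bytree,
             nthread = 1, seed = seed)
  if (lossguide) {
    xp$tree_method <- "hist"; xp$grow_policy <- "lossguide"
    xp$max_leaves <- p$max_leaves; xp$max_depth <- 0
  } else xp$max_depth <- p$max_depth
  dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
  with_seed(seed, xgboost::xgb.train(params = xp, data = dm,
                                     nrounds = p$nrounds, verbose = 0))
}

# stacked ensemble: depth-wise + leaf-wise boosters, logistic meta-learner
# trained on out-of-fold base predictions
fit_stack <- function(x, y, p, seed, inner_folds = 5) {
  folds <- stratified_folds(y, inner_folds, seed = derive_seed(seed, 77))
  oof <- matrix(NA_real_, length(y), 2)
  for (f in seq_len(inner_folds)) {
    tr <- folds != f
    m1 <- fit_xgb(x[tr, , drop = FALSE], y[tr], p, derive_seed(seed, f, 1))
    m2 <- fit_xgb(x[tr, , drop = FALSE], y[tr], p, derive_seed(seed, f, 2),
                  lossguide = TRUE)
    te <- x[!tr, , drop = FALSE]
    oof[!tr, 1] <- predict(m1, xgboost::xgb.DMatrix(te))
    oof[!tr, 2] <- predict(m2, xgboost::xgb.DMatrix(te))
  }
  meta <- suppressWarnings(
    glm(y ~ ., data = data.frame(y = y, p1 = oof[, 1], p2 = oof[, 2]),
        family = binomial()))
  base1 <- fit_xgb(x, y, p, derive_seed(seed, 0, 1))
  base2 <- fit_xgb(x, y, p, derive_seed(seed, 0, 2), lossguide = TRUE)
  list(base1 = base1, base2 = base2, meta = meta)
}

predict_stack <- function(m, x) {
  dm <- xgboost::xgb.DMatrix(as.matrix(x))
  nd <- data.frame(p1 = predict(m$base1, dm), p2 = predict(m$base2, dm))
  as.numeric(predict(m$meta, newdata = nd, type = "response"))
}

# ---- folds and search ----------------------------------------------------

#' Stratified fold assignment
#'
#' Shuffles within each class and deals observations round-robin into
#' folds, so class proportions are balanced per fold. With `subject`
#' given, whole subjects are dealt instead of rows (grouped,
#' leakage-safe).
#'
#' @param y labels (anything coercible to factor, or 0/1).
#' @param folds number of folds.
#' @param seed RNG seed.
#' @param subject optional subject id per row.
#' @return Integer fold id per row.
#' @export
stratified_folds <- function(y, folds, seed = 42, subject = NULL) {
  with_seed(seed, {
    if (is.null(subject)) {
      fold <- integer(length(y))
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
      fold
    } else {
      subj <- unique(subject)
      sub_y <- y[match(subj, subject)]
      sub_fold <- integer(length(subj))
      for (cl in unique(sub_y)) {
        idx <- sample(which(sub_y == cl))
        sub_fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
      sub_fold[match(subject, subj)]
    }
  })
}

# median-impute / scale using statistics from the training rows only
fold_preprocess <- function(xtr, xte, nan_policy, scale) {
  if (any(!is.finite(xtr)) || any(!is.finite(xte))) {
    if (nan_policy == "error")
      stopf("non-finite feature values; set nan_policy = 'impute_median'")
    med <- apply(xtr, 2, function(v) median(v[is.finite(v)]))
    med[!is.finite(med)] <- 0
    for (j in seq_len(ncol(xtr))) {
      xtr[!is.finite(xtr[, j]), j] <- med[j]
      xte[!is.finite(xte[, j]), j] <- med[j]
    }
  }
  if (scale) {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
  }
  list(train = xtr, test = xte)
}

# hyperparameter search: best candidate by inner-CV accuracy on the
# training split; candidates are random draws (randomized search) or a
# fixed list (grid search)
search_params <- function(reg_entry, x, y, search_iters, seed,
                          inner_folds = 3, candidates = NULL) {
  if (is.null(candidates) && search_iters <= 1)
    return(with_seed(seed, reg_entry$sample()))
  cands <- candidates %||%
    with_seed(seed, lapply(seq_len(search_iters),
                           function(i) reg_entry$sample()))
  folds <- stratified_folds(y, inner_folds, seed = derive_seed(seed, 5))
  acc <- vapply(seq_along(cands), function(ci) {
    p <- cands[[ci]]
    hits <- 0
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) return(0)
      m <- reg_entry$fit(x[tr, , drop = FALSE], y[tr], p,
                         derive_seed(seed, ci, f))
      pr <- reg_entry$prob(m, x[!tr, , drop = FALSE])
      hits <- hits + sum((pr >= 0.5) == (y[!tr] == 1))
    }
    hits / length(y)
  }, numeric(1))
  cands[[which.max(acc)]]
}

#' Cross-validated evaluation of a classifier roster
#'
#' Stratified k-fold cross-validation with randomized hyperparameter
#' search nested inside each training split; feature imputation and
#' scaling are fit on training folds only. `unit = "subject"` groups all
#' rows of a subject into the same fold (leakage-safe; the default when
#' `subject` ids are given); `unit = "epoch"` is a plain stratified split.
#'
#' @param x feature matrix or data.frame (numeric columns only).
#' @param y group labels; coerced to factor.
#' @param positive label of the positive class (sensitivity target);
#'   default: second factor level.
#' @param classifiers roster subset (see [classifier_registry()] names).
#' @param folds number of outer folds.
#' @param search_iters randomized-search candidates per model.
#' @param seed RNG seed (controls folds, search and fits).
#' @param unit `"subject"` or `"epoch"`.
#' @param subject subject id per row (required for `unit = "subject"` with
#'   repeated rows per subject).
#' @param nan_policy `"error"` or `"impute_median"`.
#' @param scale standardize features using training-fold statistics.
#' @param candidates optional fixed list of parameter lists (grid search)
#'   instead of randomized sampling.
#' @return data.frame with one row per classifier: mean and SD over folds
#'   of accuracy / sensitivity / specificity / F1 (percent) and pooled
#'   `auc`; per-classifier ROC curves in `attr(, "roc")`, fold ids in
#'   `attr(, "folds")`, selected parameters in `attr(, "params")`.
#' @export
cross_validated_eval <- function(x, y,
                                 classifiers = c("logreg", "rf", "svm_rbf",
                                                 "mlp", "xgb", "boost_hist",
                                                 "stack"),
                                 folds = 10, search_iters = 20, seed = 42,
                                 unit = c("subject", "epoch"),
                                 subject = NULL, positive = NULL,
                                 nan_policy = c("error", "impute_median"),
                                 scale = TRUE, candidates = NULL) {
  unit <- match.arg(unit)
  nan_policy <- match.arg(nan_policy)
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) != 2) stopf("binary classification only")
  positive <- positive %||% levels(y)[2]
  y01 <- as.numeric(y == positive)
  reg <- classifier_registry()
  unknown <- setdiff(classifiers, names(reg))
  if (length(unknown)) stopf("unknown classifier id: %s",
                             paste(unknown, collapse = ", "))
  if (min(table(y01)) < folds)
    stopf("need >= %d observations per class for %d folds", folds, folds)
  fold_id <- stratified_folds(
    y01, folds, seed = derive_seed(seed, 11),
    subject = if (unit == "subject") subject else NULL)
  res <- list(); rocs <- list(); sel_params <- list()
  for (cl in classifiers) {
    ent <- reg[[cl]]
    per_fold <- matrix(NA_real_, folds, 4,
                       dimnames = list(NULL, c("accuracy", "sensitivity",
                                               "specificity", "f1")))
    scores <- rep(NA_real_, length(y01))
    pars <- list()
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      pp <- fold_preprocess(x[tr, , drop = FALSE], x[!tr, , drop = FALSE],
                            nan_policy, scale)
      fseed <- derive_seed(seed, match(cl, names(reg)), f)
      p <- search_params(ent, pp$train, y01[tr], search_iters, fseed,
                         candidates = candidates)
      pars[[f]] <- p
      m <- ent$fit(pp$train, y01[tr], p, derive_seed(fseed, 999))
      pr <- ent$prob(m, pp$test)
      scores[!tr] <- pr
      pred <- as.numeric(pr >= 0.5)
      yt <- y01[!tr]
      per_fold[f, ] <- suppressWarnings(evaluate_metrics(
        tp = sum(pred == 1 & yt == 1), fp = sum(pred == 1 & yt == 0),
        tn = sum(pred == 0 & yt == 0), fn = sum(pred == 0 & yt == 1)))
    }
    roc <- pROC::roc(response = y01, predictor = scores, quiet = TRUE,
                     levels = c(0, 1), direction = "<")
    res[[cl]] <- data.frame(
      classifier = cl,
      accuracy_mean = mean(per_fold[, 1], na.rm = TRUE),
      accuracy_sd = stats::sd(per_fold[, 1], na.rm = TRUE),
      sensitivity_mean = mean(per_fold[, 2], na.rm = TRUE),
      sensitivity_sd = stats::sd(per_fold[, 2], na.rm = TRUE),
      specificity_mean = mean(per_fold[, 3], na.rm = TRUE),
      specificity_sd = stats::sd(per_fold[, 3], na.rm = TRUE),
      f1_mean = mean(per_fold[, 4], na.rm = TRUE),
      f1_sd = stats::sd(per_fold[, 4], na.rm = TRUE),
      auc = as.numeric(pROC::auc(roc)))
    rocs[[cl]] <- data.frame(fpr = 1 - roc$specificities,
                             tpr = roc$sensitivities)
    sel_params[[cl]] <- pars
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "roc") <- rocs
  attr(out, "folds") <- fold_id
  attr(out, "params") <- sel_params
  attr(out, "positive") <- positive
  out
}

#' Cumulative-domain ablation
#'
#' Evaluates the chosen booster on progressively larger cumulative column
#' subsets (temporal; + spectral; + complexity; + higher-order) and
#' reports per-stage accuracy and increments.
#'
#' @param features feature data.frame containing the canonical columns.
#' @param y group labels.
#' @param domain_order domain inclusion order.
#' @param classifier booster id (`"xgb"` or `"boost_hist"`).
#' @param ... passed to [cross_validated_eval()].
#' @return data.frame: stage, n_features, accuracy mean/SD, increment.
#' @export
cumulative_ablation <- function(features, y,
                                domain_order = c("temporal", "spectral",
                                                 "complexity",
                                                 "higher_order"),
                                classifier = "xgb", ...) {
  features <- as.data.frame(features)
  rows <- list()
  cols <- character(0)
  prev <- NA_real_
  for (i in seq_along(domain_order)) {
    dcols <- feature_names(domain_order[i])
    missing <- setdiff(dcols, names(features))
    if (length(missing)) stopf("missing %s columns (e.g. %s)",
                               domain_order[i], missing[1])
    cols <- c(cols, dcols)
    ev <- cross_validated_eval(features[, cols, drop = FALSE], y,
                               classifiers = classifier, ...)
    rows[[i]] <- data.frame(
      stage = paste(substr(domain_order[seq_len(i)], 1, 1), collapse = "+"),
      domains = paste(domain_order[seq_len(i)], collapse = "+"),
      n_features = length(cols),
      accuracy_mean = ev$accuracy_mean, accuracy_sd = ev$accuracy_sd,
      increment = if (i == 1) NA_real_ else ev$accuracy_mean - prev)
    prev <- ev$accuracy_mean
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shapley-value feature ranking of a tree ensemble
#'
#' Exact tree-path Shapley attributions (TreeSHAP as implemented by the
#' booster's `predcontrib` predictions) per instance, ranked by mean
#' absolute value. Non-tree models are rejected; a permutation-importance
#' fallback is available explicitly.
#'
#' @param model an `xgb.Booster`.
#' @param x feature matrix the attributions are evaluated on.
#' @param k top-k subset size to expose.
#' @return List with `importance` (named, sorted mean |attribution|),
#'   `ranking` (feature names, best first), `top` (first `k` names) and
#'   the per-instance `contributions` matrix.
#' @export
attribution_rank <- function(model, x, k = 20) {
  if (!inherits(model, "xgb.Booster"))
    stopf("unsupported model for exact tree-path attribution; use a tree ensemble or permutation importance")
  x <- as.matrix(x)
  contrib <- predict(model, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
  bias_col <- which(colnames(contrib) %in% c("BIAS", "(Intercept)"))
  if (!length(bias_col)) bias_col <- ncol(contrib)
  phi <- contrib[, -bias_col, drop = FALSE]
  if (is.null(colnames(phi))) colnames(phi) <- colnames(x)
  imp <- sort(colMeans(abs(phi)), decreasing = TRUE)
  list(importance = imp, ranking = names(imp),
       top = head(names(imp), k), contributions = contrib)
}

#' Retrain on the top-k ranked features
#'
#' Subsets the feature matrix to the first `k` ranked features, tunes the
#' booster by grid search with stratified cross-validation, and reports
#' the cross-validated metrics plus ROC curve data.
#'
#' @param x feature matrix / data.frame.
#' @param y group labels.
#' @param ranking feature names, best first (e.g.
#'   `attribution_rank(...)$ranking`).
#' @param k number of features to keep.
#' @param grid data.frame of booster parameter combinations to try
#'   (columns `eta`, `max_depth`, `nrounds`); a small default grid is
#'   used when `NULL`.
#' @param ... passed to [cross_validated_eval()].
#' @return List with `metrics` (one-row data.frame), `roc` (points) and
#'   `auc`.
#' @export
topk_retrain <- function(x, y, ranking, k = 20, grid = NULL, ...) {
  x <- as.data.frame(x)
  if (k > length(ranking) || k > ncol(x)) stopf("k exceeds feature count")
  keep <- ranking[seq_len(k)]
  if (is.null(grid))
    grid <- expand.grid(eta = c(0.05, 0.1, 0.3), max_depth = c(2, 3, 4),
                        nrounds = c(50, 100))
  cands <- lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ]))
  ev <- cross_validated_eval(x[, keep, drop = FALSE], y,
                             classifiers = "xgb", candidates = cands, ...)
  list(metrics = ev, roc = attr(ev, "roc")$xgb, auc = ev$auc)
}
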