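#' Merge class labels under a mapping
#'
#' @param labels character vector of labels.
#' @param mapping named character vector/list, `old -> new`; must cover all
#'   observed labels.
#' @return relabeled vector.
#' @export
merge_classes <- function(labels, mapping) {
  mapping <- unlist(mapping)
  missing_lab <- setdiff(unique(labels), names(mapping))
  if (length(missing_lab))
    abort2(paste("mapping misses label(s):",
                 paste(missing_lab, collapse = ", ")),
           "phenogait_config_error")
  unname(mapping[labels])
}

#' Fit a linear discriminant model
#'
#' Gaussian LDA with a shared (pooled within-class) covariance. When the
#' pooled covariance is ill-conditioned (condition number above
#' `max_condition`), it is shrunk toward a scaled identity with the
#' smallest intensity restoring the condition bound; the intensity is
#' recorded. Discriminant directions (at most C-1) maximize the
#' between/within scatter ratio; prediction is by maximum class posterior.
#'
#' @param X samples x features matrix.
#' @param y class labels (>= 2 classes, each with >= 2 samples).
#' @param max_condition condition-number threshold triggering shrinkage.
#' @return object of class `lda_model`.
#' @export
fit_lda <- function(X, y, max_condition = 1e8) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    abort2("need >= 2 classes", "phenogait_config_error")
  if (any(table(y) < 2))
    abort2("every class needs >= 2 samples",
           "phenogait_insufficient_data_error")
  p <- ncol(X)
  n <- nrow(X)
  means <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                    numeric(p)))
  priors <- as.numeric(table(factor(y, classes)) / n)
  # pooled within-class covariance
  Sw <- matrix(0, p, p)
  for (k in classes) {
    Xi <- X[y == k, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Sw <- Sw + crossprod(Xi)
  }
  Sw <- Sw / (n - length(classes))
  ev <- eigen(Sw, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev); lmin <- min(ev)
  gamma <- 0
  if (lmin <= 0 || lmax / lmin > max_condition) {
    # smallest gamma with cond((1-g)Sw + g*mu*I) <= max_condition
    mu <- mean(diag(Sw))
    gamma <- (lmax - max_condition * lmin) /
      (lmax - max_condition * lmin + (max_condition - 1) * mu)
    gamma <- min(1, max(gamma, 1e-12))
    Sw <- (1 - gamma) * Sw + gamma * mu * diag(p)
  }
  Swi <- solve(Sw)
  # between-class scatter and discriminant directions
  gm <- colSums(means * priors)
  Sb <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    d <- means[i, ] - gm
    Sb <- Sb + priors[i] * tcrossprod(d)
  }
  eg <- eigen(Swi %*% Sb)
  ndir <- min(length(classes) - 1, p)
  ord <- order(Re(eg$values), decreasing = TRUE)[seq_len(ndir)]
  scalings <- Re(eg$vectors[, ord, drop = FALSE])
  colnames(scalings) <- paste0("LD", seq_len(ndir))
  rownames(scalings) <- colnames(X)
  structure(list(classes = classes, means = means, priors = priors,
                 cov = Sw, cov_inv = Swi, shrinkage = gamma,
                 scalings = scalings, feature_names = colnames(X)),
            class = "lda_model")
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  # linear discriminant score per class under shared-covariance Gaussians
  A <- object$means %*% object$cov_inv            # C x p
  const <- -0.5 * rowSums(A * object$means) + log(object$priors)
  scores <- X %*% t(A) + rep(const, each = nrow(X))
  object$classes[max.col(scores, ties.method = "first")]
}

#' Project data on the discriminant directions
#' @param model an `lda_model`; `X` samples x features.
#' @param X data matrix.
#' @return samples x directions matrix.
#' @export
lda_transform <- function(model, X) {
  as.matrix(X) %*% model$scalings
}

# ---- metrics -------------------------------------------------------------

#' Balanced accuracy (mean per-class recall)
#' @param y_true,y_pred label vectors.
#' @return scalar in [0, 1].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  classes <- unique(y_true)
  mean(vapply(classes, function(k)
    mean(y_pred[y_true == k] == k), numeric(1)))
}

binary_prf <- function(y_true, y_pred, positive) {
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' F1 score
#'
#' @param y_true,y_pred label vectors.
#' @param positive positive class; `NULL` gives the macro average over
#'   observed classes.
#' @return scalar F1.
#' @export
f1_score <- function(y_true, y_pred, positive = NULL) {
  if (!is.null(positive)) return(unname(binary_prf(y_true, y_pred,
                                                   positive)["f1"]))
  mean(vapply(unique(y_true), function(k)
    binary_prf(y_true, y_pred, k)["f1"], numeric(1)))
}

#' Row-normalized confusion matrix
#' @param y_true,y_pred label vectors.
#' @param classes class order (default: sorted union).
#' @return matrix with rows (true classes) summing to 1.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  classes <- classes %||% sort(unique(c(y_true, y_pred)))
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  cm <- unclass(cm / pmax(rowSums(cm), 1))
  cm
}

#' Evaluate a classifier on a held-out partition
#'
#' @param model an `lda_model` (or any object with a `predict` method
#'   returning labels).
#' @param X_test,y_test held-out partition.
#' @param positive_class class treated as positive for the binary metrics.
#' @return list with `confusion` (row-normalized), `precision`, `recall`,
#'   `f1`, `f1_macro`, `balanced_accuracy`; or `undefined = TRUE` when the
#'   positive class is absent from `y_test`.
#' @export
evaluate_classifier <- function(model, X_test, y_test, positive_class) {
  if (!positive_class %in% y_test)
    return(list(undefined = TRUE, positive_class = positive_class))
  y_pred <- predict(model, X_test)
  prf <- binary_prf(y_test, y_pred, positive_class)
  list(confusion = confusion_matrix(y_test, y_pred),
       precision = unname(prf["precision"]), recall = unname(prf["recall"]),
       f1 = unname(prf["f1"]), f1_macro = f1_score(y_test, y_pred),
       balanced_accuracy = balanced_accuracy(y_test, y_pred),
       undefined = FALSE)
}

#' Permutation feature importance (balanced-accuracy drop)
#'
#' Importance of feature `j` is the mean drop in balanced accuracy over
#' `n_repeats` independent permutations of column `j` of the held-out
#' partition.
#'
#' @param model fitted model with a `predict` method.
#' @param X_test,y_test held-out partition.
#' @param n_repeats permutations per feature.
#' @param seed RNG seed.
#' @param metric `"balanced_accuracy"` (default) or `"f1"` (macro).
#' @return data.frame `feature`, `importance`, `rank` (1 = most important).
#' @export
permutation_importance <- function(model, X_test, y_test, n_repeats = 10,
                                   seed = 1, metric = "balanced_accuracy") {
  if (n_repeats < 1)
    abort2("n_repeats must be >= 1", "phenogait_config_error")
  X_test <- as.matrix(X_test)
  score <- function(X) {
    yp <- predict(model, X)
    if (metric == "f1") f1_score(y_test, yp)
    else balanced_accuracy(y_test, yp)
  }
  base <- score(X_test)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  imp <- vapply(seq_len(ncol(X_test)), function(j) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X_test
      Xp[, j] <- Xp[sample(nrow(Xp)), j]
      base - score(Xp)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- data.frame(feature = colnames(X_test), importance = imp)
  out$rank <- rank(-out$importance, ties.method = "first")
  out[order(out$rank), ]
}

#' Cross-validated LDA with importance and confusion summaries
#'
#' Runs the full grouped cross-validation: per fold, fits LDA on training
#' runs, evaluates on test runs, computes permutation importance, and
#' aggregates importance means and the averaged row-normalized confusion
#' matrix.
#'
#' @param dataset a `multimodal_dataset` (or labeled `feature_matrix`).
#' @param plan a `split_plan` from [group_kfold()].
#' @param feature_subset optional feature names to use.
#' @param positive_class positive class for binary metrics.
#' @param class_mapping optional label merge applied before fitting.
#' @param n_repeats,seed importance settings.
#' @return list with `folds` (per-fold results), `importance` (aggregated),
#'   `confusion_mean`, `confusion_sd`, `metrics` (cross-fold mean +- sd).
#' @export
cv_lda <- function(dataset, plan, feature_subset = NULL, positive_class,
                   class_mapping = NULL, n_repeats = 10, seed = 1) {
  X <- dataset$values
  if (!is.null(feature_subset)) X <- X[, feature_subset, drop = FALSE]
  y <- dataset$labels
  keep <- y != "unlabeled"
  if (!is.null(class_mapping)) y[keep] <- merge_classes(y[keep], class_mapping)
  runs <- dataset$run_id
  fold_res <- list()
  imp_acc <- NULL
  cms <- list()
  mets <- list()
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    tr <- keep & runs %in% f$train_runs
    te <- keep & runs %in% f$test_runs
    if (!any(te) || length(unique(y[tr])) < 2) next
    model <- fit_lda(X[tr, , drop = FALSE], y[tr])
    ev <- evaluate_classifier(model, X[te, , drop = FALSE], y[te],
                              positive_class)
    if (isTRUE(ev$undefined)) next
    imp <- permutation_importance(model, X[te, , drop = FALSE], y[te],
                                  n_repeats, seed = seed + i)
    fold_res[[length(fold_res) + 1L]] <-
      list(fold = i, model = model, metrics = ev, importance = imp)
    imp_acc <- if (is.null(imp_acc)) setNames(imp$importance[order(imp$feature)],
                                              sort(imp$feature))
    else imp_acc + imp$importance[order(imp$feature)]
    cms[[length(cms) + 1L]] <- ev$confusion
    mets[[length(mets) + 1L]] <-
      c(f1 = ev$f1, precision = ev$precision, recall = ev$recall,
        balanced_accuracy = ev$balanced_accuracy)
  }
  if (!length(fold_res))
    abort2("no evaluable folds", "phenogait_insufficient_data_error")
  imp_mean <- imp_acc / length(fold_res)
  importance <- data.frame(feature = names(imp_mean),
                           importance = unname(imp_mean))
  importance$rank <- rank(-importance$importance, ties.method = "first")
  importance <- importance[order(importance$rank), ]
  cm_arr <- simplify2array(cms)
  met_mat <- do.call(rbind, mets)
  list(folds = fold_res, importance = importance,
       confusion_mean = apply(cm_arr, 1:2, mean),
       confusion_sd = apply(cm_arr, 1:2, sd),
       metrics = list(mean = colMeans(met_mat),
                      sd = apply(met_mat, 2, sd)))
}
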