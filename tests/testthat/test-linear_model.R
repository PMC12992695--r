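test_that("class merging shrinks the vocabulary and validates coverage", {
  y <- c("gait", "stationary", "akinesia", "gait")
  m <- c(gait = "gait", stationary = "nonGait", akinesia = "nonGait")
  expect_identical(merge_classes(y, m),
                   c("gait", "nonGait", "nonGait", "gait"))
  expect_identical(merge_classes(y, c(gait = "gait",
                                      stationary = "stationary",
                                      akinesia = "akinesia")), y)
  expect_error(merge_classes(y, c(gait = "gait")),
               class = "phenogait_config_error")
})

test_that("LDA separates two spherical Gaussians near the Bayes boundary", {
  set.seed(31)
  n <- 500
  X <- rbind(matrix(rnorm(n * 2), n), sweep(matrix(rnorm(n * 2), n), 2,
                                            c(4, 0), `+`))
  y <- rep(c("a", "b"), each = n)
  Xte <- rbind(matrix(rnorm(n * 2), n), sweep(matrix(rnorm(n * 2), n), 2,
                                              c(4, 0), `+`))
  m <- fit_lda(X, y)
  acc <- mean(predict(m, Xte) == y)
  expect_gte(acc, 0.97)
  # boundary normal within 5 degrees of the x-axis
  w <- m$cov_inv %*% (m$means[2, ] - m$means[1, ])
  ang <- acos(abs(w[1]) / sqrt(sum(w^2))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("LDA direction converges to the line joining class means", {
  set.seed(32)
  n <- 10000
  X <- rbind(matrix(rnorm(n * 3), n),
             sweep(matrix(rnorm(n * 3), n), 2, c(2, 1, 0), `+`))
  y <- rep(c("a", "b"), each = n)
  m <- fit_lda(X, y)
  v <- m$scalings[, 1]
  d <- c(2, 1, 0)
  cosang <- abs(sum(v * d)) / sqrt(sum(v^2) * sum(d^2))
  expect_lt(acos(min(1, cosang)) * 180 / pi, 2)
})

test_that("LDA has at most C-1 directions and shrinks degenerate inputs", {
  set.seed(33)
  X <- matrix(rnorm(300 * 10), 300)
  y <- rep(c("a", "b", "c"), each = 100)
  m <- fit_lda(X, y)
  expect_lte(ncol(m$scalings), 2)
  # duplicated feature column: fit succeeds via shrinkage
  X2 <- cbind(X[, 1:3], X[, 3])
  colnames(X2) <- paste0("f", 1:4)
  m2 <- fit_lda(X2, y)
  expect_gt(m2$shrinkage, 0)
  expect_length(predict(m2, X2), 300)
  expect_error(fit_lda(X, rep("a", 300)), class = "phenogait_config_error")
})

test_that("LDA agrees with an independent reference implementation", {
  set.seed(34)
  n <- 300
  X <- rbind(matrix(rnorm(n * 3), n),
             sweep(matrix(rnorm(n * 3), n), 2, c(1.5, -1, 0.5), `+`))
  colnames(X) <- paste0("f", 1:3)
  y <- rep(c("a", "b"), each = n)
  ours <- predict(fit_lda(X, y), X)
  ref <- as.character(predict(MASS::lda(X, grouping = y), X)$class)
  expect_gt(mean(ours == ref), 0.99)
})

test_that("the LDA projection matches the exhaustive-direction oracle", {
  # both rules get the same optimal 1-D thresholding, so the comparison
  # isolates the quality of the fitted direction; the oracle may overfit
  # any single small instance by a sample or two, hence the mean-gap form
  set.seed(35)
  gaps <- vapply(1:8, function(trial) {
    p <- sample(2:3, 1)
    n <- 60
    mu <- rnorm(p)
    mu <- mu / sqrt(sum(mu^2)) * 3
    X <- rbind(matrix(rnorm(n / 2 * p), n / 2),
               sweep(matrix(rnorm(n / 2 * p), n / 2), 2, mu, `+`))
    y <- rep(c("a", "b"), each = n / 2)
    m <- fit_lda(X, y)
    lda_bal <- best_threshold_balacc(lda_transform(m, X)[, 1], y == "a")
    oracle <- best_linear_balacc(X, y)
    expect_gte(oracle, lda_bal - 1e-9)
    oracle - lda_bal
  }, numeric(1))
  expect_lt(mean(gaps), 0.02 + 1e-9)
  expect_lt(max(gaps), 0.05 + 1e-9)
})

test_that("binary metrics follow their definitions", {
  # TP=6, FP=2, FN=4, TN=8
  y_true <- c(rep("pos", 10), rep("neg", 10))
  y_pred <- c(rep("pos", 6), rep("neg", 4), rep("pos", 2), rep("neg", 8))
  ev <- list(
    precision = 6 / 8, recall = 6 / 10,
    f1 = 2 * (0.75 * 0.6) / (0.75 + 0.6))
  prf <- phenogait:::binary_prf(y_true, y_pred, "pos")
  expect_equal(unname(prf["precision"]), ev$precision)
  expect_equal(unname(prf["recall"]), ev$recall)
  expect_equal(unname(prf["f1"]), ev$f1, tolerance = 1e-4)
  # perfect predictions
  expect_equal(f1_score(y_true, y_true, "pos"), 1)
  expect_equal(unname(diag(confusion_matrix(y_true, y_true))), c(1, 1))
  # constant predictor of the majority class: balanced accuracy 0.5
  expect_equal(balanced_accuracy(y_true, rep("pos", 20)), 0.5)
  # confusion rows always sum to 1
  cm <- confusion_matrix(y_true, y_pred)
  expect_equal(unname(rowSums(cm)), c(1, 1), tolerance = 1e-9)
})

test_that("permutation importance recovers the sole informative feature", {
  hits <- 0L
  null_imps <- numeric(0)
  for (s in 1:10) {
    d <- make_single_signal_dataset(n = 1200, n_noise = 3, seed = 100 + s)
    idx <- seq_len(800)
    m <- fit_lda(d$X[idx, ], d$y[idx])
    imp <- permutation_importance(m, d$X[-idx, ], d$y[-idx],
                                  n_repeats = 5, seed = s)
    if (imp$feature[imp$rank == 1] == "signal") hits <- hits + 1L
    null_imps <- c(null_imps,
                   imp$importance[grepl("noise", imp$feature)])
  }
  expect_gte(hits, 9)
  expect_true(all(abs(null_imps) < 0.02 + 1e-9))
})

test_that("permutation importance is deterministic under a fixed seed", {
  d <- make_single_signal_dataset(seed = 7)
  m <- fit_lda(d$X[1:1500, ], d$y[1:1500])
  i1 <- permutation_importance(m, d$X[1501:2000, ], d$y[1501:2000],
                               n_repeats = 3, seed = 11)
  i2 <- permutation_importance(m, d$X[1501:2000, ], d$y[1501:2000],
                               n_repeats = 3, seed = 11)
  expect_identical(i1, i2)
  expect_error(permutation_importance(m, d$X, d$y, n_repeats = 0),
               class = "phenogait_config_error")
})

test_that("permuting all feature columns drives accuracy to chance", {
  set.seed(36)
  d <- make_single_signal_dataset(n = 2000, n_noise = 2, seed = 3)
  m <- fit_lda(d$X[1:1500, ], d$y[1:1500])
  Xp <- apply(d$X[1501:2000, ], 2, sample)
  expect_lt(abs(balanced_accuracy(d$y[1501:2000], predict(m, Xp)) - 0.5),
            0.05)
})
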