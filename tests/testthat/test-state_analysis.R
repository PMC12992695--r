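step_features <- function(n = 1000, rate = 200, onsets, value = 1) {
  x <- numeric(n)
  t <- (seq_len(n) - 1) / rate
  for (o in onsets) x[t >= o] <- x[t >= o] + value
  feature_matrix(cbind(step = x), t, rate)
}

test_that("peri-onset mean of identical step traces is a step with sd 0", {
  rate <- 200
  onsets <- c(5, 15, 25)
  ev <- event_table(data.frame(state = "akinesia", t_start = onsets,
                               t_end = onsets + 2), 30)
  fm <- step_features(30 * rate, rate, onsets = numeric(0))
  # build a clean unit step at each onset (reset between events)
  vals <- numeric(30 * rate)
  t <- (seq_len(30 * rate) - 1) / rate
  for (o in onsets) vals[t >= o & t < o + 3] <- 1
  fm$values[, 1] <- vals
  pc <- peri_onset_curves(fm, ev, "akinesia", window = c(2, 2))
  expect_equal(pc$n_events, 3)
  expect_equal(unname(pc$sd[, 1]), rep(0, length(pc$time)))
  expect_equal(unname(pc$mean[pc$time < 0, 1]),
               rep(0, sum(pc$time < 0)))
  expect_equal(unname(pc$mean[pc$time >= 0, 1]),
               rep(1, sum(pc$time >= 0)))
})

test_that("onsets too close to the run edge are excluded and counted", {
  rate <- 200
  ev <- event_table(data.frame(state = "akinesia",
                               t_start = c(5, 9.5), t_end = c(6, 10)), 10)
  fm <- step_features(10 * rate, rate, onsets = numeric(0))
  pc <- peri_onset_curves(fm, ev, "akinesia", window = c(2, 2))
  expect_equal(pc$n_events, 1)
  expect_equal(pc$n_excluded, 1)
  pc2 <- peri_onset_curves(fm, ev, "gait", window = c(2, 2))
  expect_true(pc2$empty)
})

test_that("joint ranking combines the two importance tables", {
  li <- data.frame(feature = c("a", "b", "c"), importance = c(3, 2, 1),
                   rank = 1:3)
  ei <- data.frame(feature = c("a", "b", "c"), importance = c(5, 1, 2),
                   rank = c(1, 3, 2))
  jr <- joint_ranking(li, ei)
  expect_equal(jr$feature[jr$combined_rank == 1], "a")
  jr2 <- joint_ranking(li, ei, method = "mean")
  expect_equal(jr2$feature[jr2$combined_rank == 1], "a")
  expect_error(joint_ranking(li, data.frame(feature = "zzz",
                                            importance = 1, rank = 1)),
               class = "phenogait_config_error")
})

test_that("state-feature table has exactly 12 Holm-adjusted tests", {
  set.seed(51)
  subjects <- paste0("s", 1:6)
  grid <- expand.grid(subject = subjects, state = RODENT_STATES,
                      stringsAsFactors = FALSE)
  for (f in paste0("f", 1:4)) grid[[f]] <- rnorm(nrow(grid))
  res <- state_feature_tests(grid)
  expect_equal(nrow(res), 12)
  expect_true(all(res$p_holm >= res$p_raw - 1e-12))
  # Holm is monotone in the raw ordering
  o <- order(res$p_raw)
  expect_true(all(diff(res$p_holm[o]) >= -1e-12))
  # identical states per subject: all adjusted p = 1
  grid2 <- grid
  for (f in paste0("f", 1:4))
    grid2[[f]] <- rep(rnorm(6), times = 3)
  res2 <- state_feature_tests(grid2)
  expect_true(all(res2$p_holm > 0.999))
})

test_that("a one-sd within-subject shift is detected after Holm", {
  # per-subject per-state means average many samples, so a shift of one
  # within-subject (raw signal) sd is large relative to the sd of the
  # cell mean (raw sd 1, 50 samples per cell)
  set.seed(52)
  hits <- 0L
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    grid <- expand.grid(subject = paste0("s", 1:6),
                        state = RODENT_STATES, stringsAsFactors = FALSE)
    base <- rnorm(6, sd = 0.3)
    for (f in paste0("f", 1:4)) {
      eff <- if (f == "f1") ifelse(grid$state == "akinesia", 1, 0) else 0
      cell_means <- vapply(seq_len(nrow(grid)), function(i)
        mean(rnorm(50, sd = 1)), numeric(1))
      grid[[f]] <- base[as.integer(factor(grid$subject))] + eff +
        cell_means
    }
    res <- state_feature_tests(grid)
    sig <- res$significant[res$feature == "f1" &
                             res$state_a == "akinesia" &
                             res$state_b == "gait"]
    if (isTRUE(sig)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("binning uses the floor rule and majority labels", {
  rate <- 10
  n <- 105  # 10.5 s at 10 Hz
  labs <- c(rep("fog", 6), rep("gait", 4), rep("gait", 95))
  fm <- feature_matrix(cbind(f = rep(2.5, n)), (seq_len(n) - 1) / rate,
                       rate, labels = labs)
  b <- bin_episodes(fm, bin = 1)
  expect_equal(nrow(b$values), 10)
  expect_equal(b$labels[1], "fog")   # 0.6 s fog vs 0.4 s gait
  expect_equal(b$labels[2], "gait")
  expect_true(all(b$values == 2.5))
  short <- feature_matrix(cbind(f = 1:5), (0:4) / 10, 10,
                          labels = rep("gait", 5))
  expect_true(bin_episodes(short, bin = 1)$skipped)
})

test_that("PCA matches the analytic eigendecomposition on Gaussian data", {
  set.seed(53)
  n <- 10000
  S <- matrix(c(4, 1.2, 1.2, 1), 2)
  L <- chol(S)
  X <- matrix(rnorm(n * 2), n) %*% L
  colnames(X) <- c("a", "b")
  # correlation-scale oracle (pca_project z-scores internally)
  ev <- eigen(stats::cov2cor(S), symmetric = TRUE)$values
  p <- pca_project(X, 2)
  expect_equal(p$variance_ratio, ev / sum(ev), tolerance = 0.02)
  # duplicated feature splits loadings symmetrically
  X2 <- cbind(X, a2 = X[, "a"])
  p2 <- pca_project(X2, 2)
  expect_equal(abs(p2$loadings["a", 1]), abs(p2$loadings["a2", 1]),
               tolerance = 1e-6)
  # deterministic sign convention: top-magnitude loading positive
  expect_gte(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)
})

test_that("isotropic clouds give near-equal variance ratios", {
  set.seed(54)
  X <- matrix(rnorm(10000 * 2), ncol = 2)
  colnames(X) <- c("a", "b")
  p <- pca_project(X, 2)
  expect_lt(abs(p$variance_ratio[1] - p$variance_ratio[2]), 0.1)
})

test_that("top correlated features rank a label-identical feature first", {
  set.seed(55)
  n <- 1000
  labels <- sample(c("gait", "fog"), n, replace = TRUE)
  X <- cbind(ind = as.numeric(labels == "gait"),
             noise1 = rnorm(n), noise2 = rnorm(n))
  tf <- top_correlated_features(X, labels, "gait", n = 2)
  expect_equal(tf$feature[1], "ind")
  expect_equal(tf$r[1], 1, tolerance = 1e-9)
  expect_true(all(abs(tf$r[tf$feature != "ind"]) < 0.1))
  expect_warning(full <- top_correlated_features(X, labels, "gait", n = 10),
                 "exceeds")
  expect_equal(nrow(full), 3)
  expect_error(top_correlated_features(X, rep("gait", n), "gait"),
               class = "phenogait_undefined_error")
})

test_that("channel selection picks the injected modulation and flags ties", {
  ep <- data.frame(episode = 1:8, session = 1, label = rep(c("fog", "gait"), 4),
                   chA_beta = rep(c(0.5, 0.5), 4),
                   chB_beta = rep(c(2.5, 0.5), 4))
  sel <- select_channel_by_band_modulation(
    ep, c(chA = "chA_beta", chB = "chB_beta"))
  expect_equal(sel$channel, "chB")
  expect_false(sel$tie)
  sel2 <- select_channel_by_band_modulation(
    ep, c(chA = "chA_beta", chA2 = "chA_beta"))
  expect_equal(sel2$channel, "chA")
  expect_true(sel2$tie)
  sel3 <- select_channel_by_band_modulation(ep, c(chB = "chB_beta"))
  expect_equal(sel3$channel, "chB")
})

test_that("episode permutation test is calibrated and respects strata", {
  # a strong effect attains the add-one lower bound
  set.seed(56)
  ep <- data.frame(episode = 1:20, session = rep(1:2, each = 10),
                   label = rep(c("fog", "gait"), 10),
                   f = rep(c(5, 0), 10) + rnorm(20, sd = 0.1))
  r <- episode_permutation_test(ep, "f", n_perm = 1000, seed = 1)
  expect_equal(r$p, 1 / 1001)
  # permutations never cross sessions: separating sessions by a huge
  # offset does not affect the within-session statistic distribution
  ep2 <- ep
  ep2$f <- rnorm(20) + ifelse(ep2$session == 2, 1000, 0)
  r2 <- episode_permutation_test(ep2, "f", n_perm = 400, seed = 2)
  expect_gt(r2$p, 0.05)  # no spurious cross-session effect
  # degenerate strata
  ep3 <- data.frame(episode = 1:4, session = c(1, 1, 2, 2),
                    label = c("fog", "fog", "gait", "gait"), f = rnorm(4))
  expect_error(episode_permutation_test(ep3, "f", n_perm = 10),
               class = "phenogait_undefined_error")
})

test_that("episode feature tests apply the Bonferroni factor", {
  set.seed(57)
  ep <- data.frame(episode = 1:16, session = rep(1:2, each = 8),
                   label = rep(c("fog", "gait"), 8),
                   f1 = rnorm(16), f2 = rnorm(16), f3 = rnorm(16),
                   f4 = rnorm(16))
  res <- episode_feature_tests(ep, paste0("f", 1:4), n_perm = 200, seed = 3)
  expect_equal(nrow(res), 4)
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 4))
})
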