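test_that("encoder designs realize the requested receptive field exactly", {
  for (rf in c(10, 20, 50, 128, 200)) {
    p <- phenogait:::design_encoder(rf, 6)
    realized <- p$kernels[1] + p$strides[1] * sum(p$kernels[-1] - 1L)
    expect_equal(realized, rf)
  }
})

test_that("analytic gradients match numerical differentiation", {
  pg <- asNamespace("phenogait")
  set.seed(41)
  cfg <- embedding_config(receptive_field = 12, layers = 3,
                          hidden_width = 4, batch_size = 6,
                          max_iterations = 1, seed = 1)
  enc <- pg$init_encoder(2, cfg)
  B <- 6
  Xw <- array(rnorm(2 * B * 12 * 2), c(2 * B, 12, 2))
  lossfun <- function(e) {
    fw <- pg$encoder_forward(e, Xw)
    A <- fw$emb[seq_len(B), ]
    P <- fw$emb[B + seq_len(B), ]
    pg$infonce_loss(A, P, 0.5)$loss
  }
  fw <- pg$encoder_forward(enc, Xw)
  ls <- pg$infonce_loss(fw$emb[1:B, ], fw$emb[B + 1:B, ], 0.5)
  gr <- pg$encoder_backward(enc, fw, rbind(ls$dA, ls$dP))
  eps <- 1e-6
  for (li in 1:3) for (trial in 1:4) {
    i <- sample(length(enc$layers[[li]]$W), 1)
    e2 <- enc
    e2$layers[[li]]$W[i] <- e2$layers[[li]]$W[i] + eps
    num <- (lossfun(e2) - ls$loss) / eps
    expect_equal(gr[[li]]$dW[i], num, tolerance = 1e-3)
  }
})

test_that("training reduces the InfoNCE loss and yields unit-norm output", {
  d <- make_state_dataset(n = 2000, n_runs = 1, seed = 5)
  cfg <- tiny_embedding_cfg(seed = 2, iters = 200)
  m <- train_embedding(d$X, d$y, cfg)
  expect_length(m$loss_trace, 200)
  expect_true(all(is.finite(m$loss_trace)))
  expect_lt(mean(tail(m$loss_trace, 30)), mean(head(m$loss_trace, 30)))
  E <- embed(m, d$X)
  expect_lt(max(abs(sqrt(rowSums(E^2)) - 1)), 1e-5)
})

test_that("embedding is deterministic and enforces shapes", {
  d <- make_state_dataset(n = 1500, n_runs = 1, seed = 6)
  cfg <- tiny_embedding_cfg(seed = 3, iters = 50)
  m <- train_embedding(d$X, d$y, cfg)
  e1 <- embed(m, d$X)
  e2 <- embed(m, d$X)
  expect_identical(e1, e2)
  expect_error(embed(m, d$X[, 1:3]), class = "phenogait_shape_error")
  expect_error(embed(m, d$X[1:10, ]), class = "phenogait_shape_error")
})

test_that("full-sequence embedding equals per-window encoding", {
  pg <- asNamespace("phenogait")
  d <- make_state_dataset(n = 800, n_runs = 1, seed = 8)
  cfg <- tiny_embedding_cfg(seed = 4, iters = 30)
  m <- train_embedding(d$X, d$y, cfg)
  E <- embed(m, d$X)
  pos <- attr(E, "positions")
  rf <- cfg$receptive_field
  for (t in c(rf, rf + 7, 500)) {
    w <- pg$gather_windows(d$X, t, rf)
    ew <- pg$encoder_forward(m$encoder, w, keep_cache = FALSE)$emb
    expect_equal(unname(E[which(pos == t), ]), unname(drop(ew)),
                 tolerance = 1e-10)
  }
  # windows never cross run boundaries
  E2 <- embed(m, d$X, run_ids = rep(c("a", "b"), each = 400))
  expect_true(all(attr(E2, "positions") != 401))
  expect_true(any(attr(E2, "positions") == 400 + rf))
})

test_that("KNN decoding votes by cosine neighbors with nearest-tie break", {
  tr <- rbind(c(1, 0, 0), c(0.99, 0.1, 0), c(0, 1, 0))
  tr <- tr / sqrt(rowSums(tr^2))
  lab <- c("a", "a", "b")
  # identical test point: its own label wins
  ev <- knn_evaluate(tr, lab, tr[3, , drop = FALSE], "b", k = 1)
  expect_equal(ev$predicted, "b")
  # k = 3 majority among collinear-ish vectors
  ev2 <- knn_evaluate(tr, lab, matrix(c(1, 0.05, 0), 1), "a", k = 3)
  expect_equal(ev2$predicted, "a")
  expect_error(knn_evaluate(tr[0, , drop = FALSE], character(0),
                            tr, lab), class = "phenogait_config_error")
})

test_that("KNN metrics are invariant to a global rotation of coordinates", {
  set.seed(44)
  tr <- matrix(rnorm(300), 100, 3)
  te <- matrix(rnorm(90), 30, 3)
  lab_tr <- sample(c("x", "y"), 100, replace = TRUE)
  lab_te <- sample(c("x", "y"), 30, replace = TRUE)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  e1 <- knn_evaluate(tr, lab_tr, te, lab_te, k = 3)
  e2 <- knn_evaluate(tr %*% R, lab_tr, te %*% R, lab_te, k = 3)
  expect_equal(e1$predicted, e2$predicted)
  expect_equal(e1$f1_macro, e2$f1_macro)
})

test_that("embedding importance recovers the informative feature", {
  d <- make_single_signal_dataset(n = 1600, n_noise = 2, seed = 9,
                                  block = 100)
  cfg <- embedding_config(receptive_field = 20, hidden_width = 8,
                          layers = 4, batch_size = 64,
                          max_iterations = 150, time_offset = 100,
                          seed = 5)
  idx <- seq_len(1100)
  m <- train_embedding(d$X[idx, ], d$y[idx], cfg)
  imp <- embedding_importance(m, d$X[idx, ], d$y[idx],
                              d$X[-idx, ], d$y[-idx],
                              n_repeats = 2, seed = 1, hop = 3)
  expect_equal(imp$feature[imp$rank == 1], "signal")
  expect_true(all(abs(imp$importance[grepl("noise", imp$feature)]) < 0.1))
  imp2 <- embedding_importance(m, d$X[idx, ], d$y[idx],
                               d$X[-idx, ], d$y[-idx],
                               n_repeats = 2, seed = 1, hop = 3)
  expect_identical(imp, imp2)
})

test_that("single-feature embeddings order features by informativeness", {
  d <- make_state_dataset(n = 3000, n_runs = 2, seed = 10)
  fm <- feature_matrix(d$X, seq_len(nrow(d$X)) / 200, 200, labels = d$y,
                       run_id = d$runs)
  plan <- group_kfold(d$runs, k = 2, seed = 1)
  cfg <- embedding_config(receptive_field = 20, hidden_width = 8,
                          layers = 4, batch_size = 64,
                          max_iterations = 150, time_offset = 100, seed = 6)
  fm$normalization <- NULL
  a <- single_feature_embedding(fm, "sig1", cfg, plan)
  b <- single_feature_embedding(fm, "noise1", cfg, plan)
  expect_gt(a$f1_macro, b$f1_macro)
  expect_error(single_feature_embedding(fm, "nope", cfg, plan),
               class = "phenogait_config_error")
})
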