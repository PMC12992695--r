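#' Configuration for the contrastive embedding model
#'
#' The encoder is a temporal convolutional network over the trailing
#' `receptive_field` samples of the feature time series: a strided first
#' layer followed by stride-1 valid convolutions, GELU activations, and a
#' final linear map to `output_dim`, normalized to the unit sphere.
#' Training minimizes a supervised InfoNCE loss (cosine similarity over
#' `temperature`) whose positives share the anchor's state label within
#' `time_offset` samples; negatives are the other anchors of the batch.
#'
#' Two profiles are provided: `"desk"` (batch 128, 2000 iterations), used
#' throughout the package tests, and `"full"` (batch 512, 50000
#' iterations), the full-scale setting.
#'
#' @param receptive_field window length in samples (default 200 = 1 s at
#'   200 Hz).
#' @param layers number of convolutional layers.
#' @param hidden_width channels per hidden layer.
#' @param output_dim embedding dimensionality.
#' @param temperature InfoNCE temperature.
#' @param batch_size anchors per iteration.
#' @param learning_rate Adam step size.
#' @param max_iterations training iterations.
#' @param time_offset maximum |offset| (samples) for positive sampling.
#' @param seed RNG seed for initialization and sampling.
#' @param profile `"desk"` or `"full"`; sets batch/iteration defaults.
#' @return object of class `embedding_config`.
#' @export
embedding_config <- function(receptive_field = 200, layers = 6,
                             hidden_width = 32, output_dim = 3,
                             temperature = 0.1, batch_size = NULL,
                             learning_rate = 5e-4, max_iterations = NULL,
                             time_offset = 200, seed = 1,
                             profile = c("desk", "full")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "desk") c(128, 2000) else c(512, 50000)
  batch_size <- batch_size %||% defaults[1]
  max_iterations <- max_iterations %||% defaults[2]
  if (output_dim < 2 || temperature <= 0 || receptive_field < 1)
    abort2("invalid embedding configuration", "phenogait_config_error")
  structure(list(receptive_field = receptive_field, layers = layers,
                 hidden_width = hidden_width, output_dim = output_dim,
                 temperature = temperature, batch_size = batch_size,
                 learning_rate = learning_rate,
                 max_iterations = max_iterations, time_offset = time_offset,
                 seed = seed, profile = profile),
            class = "embedding_config")
}

# Kernel/stride plan realizing exactly the requested receptive field:
# a strided first layer downsamples, the remaining layers reduce the
# post-stride length to 1.
design_encoder <- function(rf, n_layers) {
  n_layers <- as.integer(n_layers)
  stopifnot(n_layers >= 2)
  s <- max(1L, as.integer(floor(rf / 20)))
  P <- 19L
  if (rf - s * (P - 1L) < 1L) {
    s <- 1L
    P <- as.integer(rf)
  }
  k1 <- as.integer(rf - s * (P - 1L))
  red <- P - 1L                      # total length reduction after layer 1
  nr <- n_layers - 1L
  base <- red %/% nr
  extra <- red %% nr
  ks <- rep(base, nr) + c(rep(1L, extra), rep(0L, nr - extra))
  ks <- ks + 1L                      # kernel = reduction + 1
  list(kernels = as.integer(c(k1, ks)),
       strides = as.integer(c(s, rep(1L, nr))), post_len = P)
}

# sigmoid-approximated GELU (x * sigmoid(1.702 x)); the approximation is
# standard and substantially cheaper than the exact Gaussian CDF form
gelu <- function(x) x / (1 + exp(-1.702 * x))
gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s * (1 + 1.702 * x * (1 - s))
}

init_encoder <- function(n_features, cfg) {
  plan <- design_encoder(cfg$receptive_field, cfg$layers)
  cin <- c(n_features, rep(cfg$hidden_width, cfg$layers - 1))
  cout <- c(rep(cfg$hidden_width, cfg$layers - 1), cfg$output_dim)
  layers <- vector("list", cfg$layers)
  for (i in seq_len(cfg$layers)) {
    k <- plan$kernels[i]
    sd_w <- sqrt(2 / (k * cin[i]))
    layers[[i]] <- list(
      W = array(rnorm(k * cin[i] * cout[i], sd = sd_w),
                dim = c(k, cin[i], cout[i])),
      b = numeric(cout[i]),
      k = k, stride = plan$strides[i], cin = cin[i], cout = cout[i])
  }
  list(layers = layers, plan = plan, n_features = n_features)
}

# im2col: (B, L, C) -> (B*L_out, k*C) with kernel-position blocks
im2col <- function(X, k, s, L_out) {
  d <- dim(X)
  B <- d[1]
  M <- matrix(0, B * L_out, k * d[3])
  idx0 <- s * (seq_len(L_out) - 1L)
  for (u in seq_len(k)) {
    Xu <- X[, idx0 + u, , drop = FALSE]
    dim(Xu) <- c(B * L_out, d[3])
    M[, seq.int((u - 1L) * d[3] + 1L, u * d[3])] <- Xu
  }
  M
}

# X: (B, L, C) array -> (B, L_out, Cout)
conv_forward <- function(X, layer, cache = NULL) {
  d <- dim(X)
  B <- d[1]; L <- d[2]
  k <- layer$k; s <- layer$stride
  L_out <- (L - k) %/% s + 1L
  Wm <- layer$W
  dim(Wm) <- c(k * layer$cin, layer$cout)      # W is (k, cin, cout)
  M <- im2col(X, k, s, L_out)
  O <- M %*% Wm
  O <- O + rep(layer$b, each = B * L_out)
  dim(O) <- c(B, L_out, layer$cout)
  attr(O, "im2col") <- if (is.null(cache)) NULL else M
  O
}

conv_backward <- function(X, M, dO, layer, need_dx = TRUE) {
  B <- dim(X)[1]
  L_out <- dim(dO)[2]
  dO_mat <- dO
  dim(dO_mat) <- c(B * L_out, layer$cout)
  k <- layer$k
  Wm <- layer$W
  dim(Wm) <- c(k * layer$cin, layer$cout)
  dW <- crossprod(M, dO_mat)
  dim(dW) <- c(k, layer$cin, layer$cout)
  dX <- NULL
  if (need_dx) {
    dM <- tcrossprod(dO_mat, Wm)               # (B*L_out, k*cin)
    dX <- array(0, dim(X))
    idx0 <- layer$stride * (seq_len(L_out) - 1L)
    for (u in seq_len(k)) {
      dXu <- dM[, seq.int((u - 1L) * layer$cin + 1L, u * layer$cin),
                drop = FALSE]
      dim(dXu) <- c(B, L_out, layer$cin)
      idx <- idx0 + u
      dX[, idx, ] <- dX[, idx, , drop = FALSE] + dXu
    }
  }
  list(dX = dX, dW = dW, db = colSums(dO_mat))
}

# Forward pass through the full stack; keeps activations for backprop.
encoder_forward <- function(enc, X, keep_cache = TRUE) {
  cache <- list()
  A <- X
  nl <- length(enc$layers)
  for (i in seq_len(nl)) {
    Z <- conv_forward(A, enc$layers[[i]], cache = keep_cache)
    if (keep_cache)
      cache[[i]] <- list(input = A, pre = Z, M = attr(Z, "im2col"))
    A <- if (i < nl) gelu(Z) else Z
  }
  # unit-sphere normalization of the final coordinates
  d <- dim(A)
  E <- matrix(A, d[1] * d[2], d[3])
  nrm <- sqrt(rowSums(E^2)) + 1e-12
  list(emb = E / nrm, raw = E, nrm = nrm, out_dim = d, cache = cache)
}

encoder_backward <- function(enc, fwd, dE) {
  # through normalization: dZ = (dE - e * <dE, e>) / ||z||
  e <- fwd$emb
  dZ <- (dE - e * rowSums(dE * e)) / fwd$nrm
  dim(dZ) <- fwd$out_dim
  nl <- length(enc$layers)
  grads <- vector("list", nl)
  dA <- dZ
  for (i in rev(seq_len(nl))) {
    if (i < nl) dA <- dA * gelu_grad(fwd$cache[[i]]$pre)
    bk <- conv_backward(fwd$cache[[i]]$input, fwd$cache[[i]]$M, dA,
                        enc$layers[[i]], need_dx = i > 1)
    grads[[i]] <- list(dW = bk$dW, db = bk$db)
    dA <- bk$dX
  }
  grads
}

# gather windows ending at positions `pos` into a (B, RF, F) array
gather_windows <- function(X, pos, rf) {
  B <- length(pos)
  idx <- outer(pos - rf, seq_len(rf), `+`)      # B x RF of row indices
  W <- X[as.vector(idx), , drop = FALSE]        # (B*RF) x F, row-major pairs
  A <- array(W, dim = c(B, rf, ncol(X)))
  A
}

infonce_loss <- function(A, P, tau) {
  B <- nrow(A)
  s_pos <- rowSums(A * P) / tau
  S <- tcrossprod(A) / tau
  diag(S) <- -Inf
  m <- pmax(s_pos, apply(S, 1, max))
  Zpos <- exp(s_pos - m)
  Eneg <- exp(S - m)
  Z <- Zpos + rowSums(Eneg)
  loss <- mean(-(s_pos - m) + log(Z))
  p_pos <- Zpos / Z
  Pneg <- Eneg / Z
  dA <- ((p_pos - 1) * P + Pneg %*% A + crossprod(Pneg, A)) / (tau * B)
  dP <- ((p_pos - 1) * A) / (tau * B)
  list(loss = loss, dA = dA, dP = dP)
}

adam_init <- function(enc) {
  lapply(enc$layers, function(l)
    list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b))))
}

adam_step <- function(enc, st, grads, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (i in seq_along(enc$layers)) {
    g <- grads[[i]]
    st[[i]]$mW <- b1 * st[[i]]$mW + (1 - b1) * g$dW
    st[[i]]$vW <- b2 * st[[i]]$vW + (1 - b2) * g$dW^2
    enc$layers[[i]]$W <- enc$layers[[i]]$W -
      lr * (st[[i]]$mW / c1) / (sqrt(st[[i]]$vW / c2) + eps)
    st[[i]]$mb <- b1 * st[[i]]$mb + (1 - b1) * g$db
    st[[i]]$vb <- b2 * st[[i]]$vb + (1 - b2) * g$db^2
    enc$layers[[i]]$b <- enc$layers[[i]]$b -
      lr * (st[[i]]$mb / c1) / (sqrt(st[[i]]$vb / c2) + eps)
  }
  list(enc = enc, st = st)
}

# valid window-end positions: full window inside one run, labeled sample
valid_positions <- function(n, rf, run_ids, labels) {
  pos <- seq.int(rf, n)
  if (!is.null(run_ids))
    pos <- pos[run_ids[pos] == run_ids[pos - rf + 1]]
  if (!is.null(labels)) pos <- pos[labels[pos] != "unlabeled"]
  pos
}

#' Train the supervised contrastive embedding
#'
#' @param X samples x features matrix (z-scored).
#' @param labels per-sample state label ("unlabeled" samples are skipped).
#' @param cfg an [embedding_config()].
#' @param run_ids optional per-sample run key; windows never cross runs.
#' @return object of class `embedding_model` with the trained encoder and
#'   the training `loss_trace`.
#' @export
train_embedding <- function(X, labels, cfg = embedding_config(),
                            run_ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  rf <- cfg$receptive_field
  pos <- valid_positions(n, rf, run_ids, labels)
  if (length(pos) < cfg$batch_size)
    abort2("fewer labeled window positions than batch_size",
           "phenogait_config_error")
  # per (run, label) sorted position lists for positive sampling;
  # singleton strata cannot yield positives and are excluded
  runkey <- if (is.null(run_ids)) rep("r", n) else run_ids
  grp <- split(pos, paste(runkey[pos], labels[pos]))
  grp <- grp[vapply(grp, length, integer(1)) >= 2]
  keep <- paste(runkey[pos], labels[pos]) %in% names(grp)
  pos <- pos[keep]
  if (length(pos) < cfg$batch_size)
    abort2("too few samples per label for positive sampling",
           "phenogait_config_error")
  key_of <- paste(runkey[pos], labels[pos])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  enc <- init_encoder(ncol(X), cfg)
  st <- adam_init(enc)
  trace <- numeric(cfg$max_iterations)
  B <- cfg$batch_size
  for (it in seq_len(cfg$max_iterations)) {
    ai <- sample(length(pos), B, replace = length(pos) < B)
    anchors <- pos[ai]
    positives <- integer(B)
    for (b in seq_len(B)) {
      cand <- grp[[key_of[ai[b]]]]
      lo <- findInterval(anchors[b] - cfg$time_offset - 1L, cand) + 1L
      hi <- findInterval(anchors[b] + cfg$time_offset, cand)
      cc <- cand[lo:hi]
      cc <- cc[cc != anchors[b]]
      if (!length(cc)) cc <- cand[cand != anchors[b]]
      positives[b] <- cc[sample.int(length(cc), 1L)]
    }
    # anchors and positives share one forward/backward pass
    Wap <- gather_windows(X, c(anchors, positives), rf)
    fw <- encoder_forward(enc, Wap)
    A <- fw$emb[seq_len(B), , drop = FALSE]
    P <- fw$emb[B + seq_len(B), , drop = FALSE]
    ls <- infonce_loss(A, P, cfg$temperature)
    trace[it] <- ls$loss
    if (!is.finite(ls$loss))
      abort2("non-finite InfoNCE loss; check input scaling",
             "phenogait_training_error")
    g <- encoder_backward(enc, fw, rbind(ls$dA, ls$dP))
    up <- adam_step(enc, st, g, cfg$learning_rate, it)
    enc <- up$enc
    st <- up$st
  }
  structure(list(encoder = enc, config = cfg, loss_trace = trace,
                 n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "embedding_model")
}

#' Embed a feature time series
#'
#' Produces one unit-norm coordinate per valid window position (window end
#' at sample `receptive_field` onward, never crossing run boundaries).
#' Deterministic given the trained parameters.
#'
#' @param model an `embedding_model`.
#' @param X samples x features matrix matching the training feature count.
#' @param run_ids optional per-sample run key.
#' @param hop embed every `hop`-th valid position (1 = all positions,
#'   computed by shared full-sequence convolution; larger hops use
#'   batched windows).
#' @return matrix (valid positions x output_dim) with attribute
#'   `positions` giving the window-end sample index of each row.
#' @export
embed <- function(model, X, run_ids = NULL, hop = 1) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    abort2(sprintf("expected %d features, got %d", model$n_features,
                   ncol(X)), "phenogait_shape_error")
  rf <- model$config$receptive_field
  if (nrow(X) < rf)
    abort2("input shorter than the receptive field", "phenogait_shape_error")
  runkey <- if (is.null(run_ids)) rep("r", nrow(X)) else run_ids
  enc <- model$encoder
  if (hop > 1) {
    pos <- valid_positions(nrow(X), rf, run_ids, NULL)
    pos <- pos[seq(1, length(pos), by = hop)]
    out <- NULL
    for (s0 in seq(1, length(pos), by = 512)) {
      ii <- s0:min(s0 + 511L, length(pos))
      fw <- encoder_forward(enc, gather_windows(X, pos[ii], rf),
                            keep_cache = FALSE)
      out <- rbind(out, fw$emb)
    }
    attr(out, "positions") <- pos
    return(out)
  }
  s <- enc$layers[[1]]$stride
  k1 <- enc$layers[[1]]$k
  red <- sum(vapply(enc$layers[-1], function(l) l$k - 1L, integer(1)))
  out_pos <- integer(0)
  out_emb <- NULL
  for (r in unique(runkey)) {
    rows <- which(runkey == r)
    Xr <- X[rows, , drop = FALSE]
    Tn <- nrow(Xr)
    if (Tn < rf) next
    for (p in seq_len(s)) {
      Tp <- Tn - p + 1L
      L1 <- (Tp - k1) %/% s + 1L
      n_out <- L1 - red
      if (n_out < 1L) next
      need <- k1 + s * (L1 - 1L)
      Ap <- array(Xr[(p - 1L) + seq_len(need), , drop = FALSE],
                  dim = c(1L, need, ncol(X)))
      fw <- encoder_forward(enc, Ap, keep_cache = FALSE)
      pos_r <- rows[(p - 1L) + rf + s * (seq_len(n_out) - 1L)]
      out_pos <- c(out_pos, pos_r)
      out_emb <- rbind(out_emb, fw$emb)
    }
  }
  o <- order(out_pos)
  emb <- out_emb[o, , drop = FALSE]
  attr(emb, "positions") <- out_pos[o]
  emb
}

#' Cosine k-nearest-neighbor decoding of embedded states
#'
#' Votes among the `k` nearest training coordinates under cosine distance;
#' ties are broken by the single nearest neighbor.
#'
#' @param train_coords,train_labels reference embedding and labels.
#' @param test_coords,test_labels query embedding and labels.
#' @param k neighbors.
#' @param positive_class class for binary metrics (default: majority-vote
#'   macro metrics only).
#' @return list with `predicted`, `confusion`, `f1_macro`,
#'   `balanced_accuracy`, and binary metrics when `positive_class` given.
#' @export
knn_evaluate <- function(train_coords, train_labels, test_coords,
                         test_labels, k = 3, positive_class = NULL) {
  if (nrow(train_coords) == 0)
    abort2("empty training set", "phenogait_config_error")
  k <- min(k, nrow(train_coords))
  nrmz <- function(M) M / (sqrt(rowSums(M^2)) + 1e-12)
  Tr <- nrmz(as.matrix(train_coords))
  Te <- nrmz(as.matrix(test_coords))
  pred <- character(nrow(Te))
  chunk <- 2048L
  for (s0 in seq(1, nrow(Te), by = chunk)) {
    ii <- s0:min(s0 + chunk - 1L, nrow(Te))
    S <- Te[ii, , drop = FALSE] %*% t(Tr)
    for (j in seq_along(ii)) {
      nb <- order(S[j, ], decreasing = TRUE)[seq_len(k)]
      votes <- table(train_labels[nb])
      top <- names(votes)[votes == max(votes)]
      pred[ii[j]] <- if (length(top) == 1) top else train_labels[nb[1]]
    }
  }
  out <- list(predicted = pred,
              confusion = confusion_matrix(test_labels, pred),
              f1_macro = f1_score(test_labels, pred),
              balanced_accuracy = balanced_accuracy(test_labels, pred))
  if (!is.null(positive_class)) {
    prf <- binary_prf(test_labels, pred, positive_class)
    out$precision <- unname(prf["precision"])
    out$recall <- unname(prf["recall"])
    out$f1 <- unname(prf["f1"])
  }
  out
}

#' Embedding-space permutation feature importance
#'
#' Importance of feature `j` is the drop in KNN macro F1 after permuting
#' column `j` of the test block prior to embedding.
#'
#' @param model trained `embedding_model`.
#' @param X_train,y_train training block (per-sample) used as the KNN
#'   reference.
#' @param X_test,y_test held-out block (per-sample).
#' @param run_ids_train,run_ids_test optional run keys.
#' @param n_repeats permutations per feature.
#' @param seed RNG seed.
#' @param k KNN neighbors.
#' @param hop evaluate every `hop`-th window position (keeps the
#'   importance scan tractable on long recordings).
#' @return data.frame `feature`, `importance`, `rank`.
#' @export
embedding_importance <- function(model, X_train, y_train, X_test, y_test,
                                 run_ids_train = NULL, run_ids_test = NULL,
                                 n_repeats = 3, seed = 1, k = 3, hop = 1) {
  if (n_repeats < 1)
    abort2("n_repeats must be >= 1", "phenogait_config_error")
  tr <- embed(model, X_train, run_ids_train, hop = hop)
  ptr <- attr(tr, "positions")
  te <- embed(model, X_test, run_ids_test, hop = hop)
  pte <- attr(te, "positions")
  keep_tr <- y_train[ptr] != "unlabeled"
  keep_te <- y_test[pte] != "unlabeled"
  ref <- knn_evaluate(tr[keep_tr, , drop = FALSE], y_train[ptr][keep_tr],
                      te[keep_te, , drop = FALSE], y_test[pte][keep_te], k)
  base <- ref$f1_macro
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  X_test <- as.matrix(X_test)
  imp <- vapply(seq_len(ncol(X_test)), function(j) {
    mean(vapply(seq_len(n_repeats), function(r) {
      Xp <- X_test
      Xp[, j] <- Xp[sample(nrow(Xp)), j]
      tep <- embed(model, Xp, run_ids_test, hop = hop)
      ev <- knn_evaluate(tr[keep_tr, , drop = FALSE], y_train[ptr][keep_tr],
                         tep[keep_te, , drop = FALSE],
                         y_test[pte][keep_te], k)
      base - ev$f1_macro
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(feature = colnames(X_test) %||%
                      paste0("f", seq_len(ncol(X_test))),
                    importance = imp)
  out$rank <- rank(-out$importance, ties.method = "first")
  out[order(out$rank), ]
}

#' Embedding trained on a single feature
#'
#' Used to compare candidate biomarkers: trains the contrastive model on
#' one feature column and reports cross-validated KNN macro F1.
#'
#' @param dataset a `multimodal_dataset` (labeled `feature_matrix`).
#' @param feature_name feature column to use.
#' @param cfg an [embedding_config()].
#' @param plan a `split_plan`; only `folds` of it are evaluated.
#' @param folds fold indices (default first fold, for speed).
#' @param k KNN neighbors.
#' @return list `models`, `f1_macro` (mean across evaluated folds),
#'   `per_fold`.
#' @export
single_feature_embedding <- function(dataset, feature_name, cfg, plan,
                                     folds = 1, k = 3) {
  if (!feature_name %in% dataset$feature_names)
    abort2(paste("unknown feature", feature_name), "phenogait_config_error")
  res <- cv_embedding(dataset, plan, cfg,
                      feature_subset = feature_name, folds = folds, k = k,
                      importance = FALSE)
  list(models = lapply(res$folds, `[[`, "model"),
       f1_macro = res$metrics$mean[["f1_macro"]],
       per_fold = vapply(res$folds, function(f) f$metrics$f1_macro,
                         numeric(1)))
}

#' Cross-validated contrastive embedding with KNN evaluation
#'
#' @param dataset labeled `multimodal_dataset`.
#' @param plan a `split_plan`.
#' @param cfg an [embedding_config()].
#' @param feature_subset optional feature names.
#' @param folds fold indices to evaluate (default: all).
#' @param k KNN neighbors.
#' @param positive_class optional positive class for binary metrics.
#' @param importance compute embedding-space permutation importance.
#' @param importance_repeats permutations per feature.
#' @param eval_hop evaluate every `eval_hop`-th window position.
#' @return list with `folds`, aggregated `importance` (when requested),
#'   `confusion_mean`, `metrics`.
#' @export
cv_embedding <- function(dataset, plan, cfg = embedding_config(),
                         feature_subset = NULL, folds = NULL, k = 3,
                         positive_class = NULL, importance = FALSE,
                         importance_repeats = 1, eval_hop = 1) {
  X <- dataset$values
  if (!is.null(feature_subset)) X <- X[, feature_subset, drop = FALSE]
  y <- dataset$labels
  runs <- dataset$run_id
  folds <- folds %||% seq_along(plan$folds)
  fold_res <- list()
  imp_acc <- NULL
  cms <- list()
  mets <- list()
  for (i in folds) {
    f <- plan$folds[[i]]
    tr <- runs %in% f$train_runs
    te <- runs %in% f$test_runs
    model <- train_embedding(X[tr, , drop = FALSE], y[tr], cfg,
                             run_ids = runs[tr])
    etr <- embed(model, X[tr, , drop = FALSE], runs[tr], hop = eval_hop)
    ete <- embed(model, X[te, , drop = FALSE], runs[te], hop = eval_hop)
    ytr <- y[tr][attr(etr, "positions")]
    yte <- y[te][attr(ete, "positions")]
    ktr <- ytr != "unlabeled"
    kte <- yte != "unlabeled"
    ev <- knn_evaluate(etr[ktr, , drop = FALSE], ytr[ktr],
                       ete[kte, , drop = FALSE], yte[kte], k,
                       positive_class)
    fr <- list(fold = i, model = model, metrics = ev)
    if (importance) {
      imp <- embedding_importance(model, X[tr, , drop = FALSE], y[tr],
                                  X[te, , drop = FALSE], y[te],
                                  runs[tr], runs[te],
                                  n_repeats = importance_repeats,
                                  seed = cfg$seed + i, k = k,
                                  hop = eval_hop)
      fr$importance <- imp
      v <- setNames(imp$importance[order(imp$feature)], sort(imp$feature))
      imp_acc <- if (is.null(imp_acc)) v else imp_acc + v
    }
    fold_res[[length(fold_res) + 1L]] <- fr
    cms[[length(cms) + 1L]] <- ev$confusion
    mets[[length(mets) + 1L]] <- c(f1_macro = ev$f1_macro,
                                   balanced_accuracy = ev$balanced_accuracy)
  }
  out <- list(folds = fold_res)
  if (!is.null(imp_acc)) {
    im <- imp_acc / length(fold_res)
    importance_df <- data.frame(feature = names(im), importance = unname(im))
    importance_df$rank <- rank(-importance_df$importance,
                               ties.method = "first")
    out$importance <- importance_df[order(importance_df$rank), ]
  }
  if (length(cms) > 1 &&
      all(vapply(cms, function(m) identical(dim(m), dim(cms[[1]])),
                 logical(1))))
    out$confusion_mean <- apply(simplify2array(cms), 1:2, mean)
  met_mat <- do.call(rbind, mets)
  out$metrics <- list(mean = colMeans(met_mat),
                      sd = if (nrow(met_mat) > 1) apply(met_mat, 2, sd)
                      else rep(0, ncol(met_mat)))
  out
}
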