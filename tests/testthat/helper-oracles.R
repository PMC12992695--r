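# Brute-force linear-classifier oracle: exhaustive unit directions, each
# followed by optimal 1-D thresholding, maximizing balanced accuracy on
# the given data. `best_threshold_balacc` applies the same optimal
# thresholding to a single projection, so a fitted direction can be
# compared to the exhaustive search on equal terms.

grid_directions <- function(p, n_dir = 2000) {
  if (p == 1) return(matrix(1, 1, 1))
  if (p == 2) {
    th <- seq(0, pi, length.out = n_dir)
    return(cbind(cos(th), sin(th)))
  }
  i <- seq_len(n_dir)
  phi <- acos(1 - 2 * (i - 0.5) / n_dir)     # Fibonacci sphere
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

best_threshold_balacc <- function(z, pos) {
  n1 <- sum(pos)
  n0 <- length(pos) - n1
  zp <- pos[order(z)]
  c1 <- cumsum(zp)
  c0 <- cumsum(!zp)
  bal_a <- (c0 / n0 + (n1 - c1) / n1) / 2     # positives above threshold
  bal_b <- (c1 / n1 + (n0 - c0) / n0) / 2     # positives below threshold
  max(bal_a, bal_b)
}

best_linear_balacc <- function(X, y) {
  pos <- y == sort(unique(y))[1]
  D <- grid_directions(ncol(X))
  best <- 0
  for (d in seq_len(nrow(D)))
    best <- max(best, best_threshold_balacc(X %*% D[d, ], pos))
  best
}
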