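# Shared fixtures, built in code. Heavy objects are cached per session.

.fix <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# A reduced cohort specification used when full signals are needed.
small_spec <- function(seed = 7) {
  cohort_spec(n_sham = 3, n_lesioned = 3, runs_sham = 2,
              runs_lesioned = c(4, 4, 4), run_duration = 12, seed = seed)
}

# Compact embedding configuration for fast training in tests.
tiny_embedding_cfg <- function(seed = 1, iters = 300) {
  embedding_config(receptive_field = 50, hidden_width = 16,
                   batch_size = 64, max_iterations = iters,
                   time_offset = 100, seed = seed)
}

# Feature-level synthetic 3-state dataset: informative features carry
# state-dependent means, the rest are pure noise.
make_state_dataset <- function(n = 4000, n_runs = 2, n_noise = 3,
                               effect = 2, seed = 1, block = 100) {
  set.seed(seed)
  states <- c("gait", "stationary", "akinesia")
  mk <- function(run_seed) {
    set.seed(run_seed)
    st <- rep(sample(states, n / block, replace = TRUE), each = block)
    mu <- cbind(gait = c(effect, 0, -effect / 2),
                stationary = c(0, effect * 0.75, 0),
                akinesia = c(-effect, 0, effect * 0.75))
    X <- cbind(t(mu[, st]), matrix(0, n, n_noise)) +
      matrix(rnorm(n * (3 + n_noise)), n)
    colnames(X) <- c("sig1", "sig2", "sig3", paste0("noise", seq_len(n_noise)))
    list(X = X, y = st)
  }
  runs <- lapply(seq_len(n_runs), function(i) mk(seed + i))
  list(X = do.call(rbind, lapply(runs, `[[`, "X")),
       y = unlist(lapply(runs, `[[`, "y")),
       runs = rep(paste0("run", seq_len(n_runs)), each = n))
}

# One informative feature among noise, for importance-recovery checks.
make_single_signal_dataset <- function(n = 2000, n_noise = 3, seed = 1,
                                       block = 50) {
  set.seed(seed)
  states <- c("gait", "akinesia")
  st <- rep(sample(states, n / block, replace = TRUE), each = block)
  X <- cbind(ifelse(st == "gait", 1.5, -1.5), matrix(0, n, n_noise)) +
    matrix(rnorm(n * (1 + n_noise)), n)
  colnames(X) <- c("signal", paste0("noise", seq_len(n_noise)))
  list(X = X, y = st)
}

# Cached small cohort with extracted multimodal features.
small_cohort_features <- function() {
  cached("small_cohort_features", {
    sess <- generate_cohort(small_spec())$sessions
    lapply(sess, function(s) {
      f <- session_features(s)
      f$group <- s$group
      f$events <- s$events
      f
    })
  })
}

small_lesioned_dataset <- function() {
  cached("small_lesioned_dataset", {
    feats <- small_cohort_features()
    les <- vapply(feats, function(f) f$group == "lesioned", logical(1))
    ds <- assemble_dataset(lapply(feats[les], `[[`, "features"))
    ds$neural_block <- intersect(feats[[1]]$neural_names, ds$feature_names)
    ds$kinematic_block <- intersect(feats[[1]]$kinematic_names,
                                    ds$feature_names)
    ds
  })
}

# Simple trajectory writer for parser fixtures.
write_traj_fixture <- function(path, markers, frames, frame_rate = 200,
                               na_frame = NULL) {
  set.seed(42)
  pos <- lapply(markers, function(m) {
    p <- matrix(rnorm(frames * 3), frames, 3)
    if (!is.null(na_frame)) p[na_frame, ] <- NA
    p
  })
  names(pos) <- markers
  write_marker_trajectories(marker_trajectories(pos, frame_rate), path)
  pos
}
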