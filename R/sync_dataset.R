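#' Label feature samples from an event table
#'
#' Each sample time is labeled by the interval containing it under the
#' half-open convention `[t_start, t_end)`; samples outside any interval
#' are labeled `"unlabeled"`.
#'
#' @param events an [event_table].
#' @param times monotone increasing sample times, seconds.
#' @return character vector of per-sample labels.
#' @export
align_events_to_samples <- function(events, times) {
  if (is.unsorted(times, strictly = FALSE))
    abort2("sample times must be monotone increasing",
           "phenogait_validation_error")
  lab <- rep("unlabeled", length(times))
  for (i in seq_len(nrow(events)))
    lab[times >= events$t_start[i] & times < events$t_end[i]] <-
      events$state[i]
  lab
}

#' Fraction of trial time spent in each state
#'
#' @param events an [event_table].
#' @return named numeric vector over the state vocabulary plus
#'   `"unlabeled"`; sums to 1.
#' @export
state_time_fractions <- function(events) {
  dur <- attr(events, "trial_duration")
  states <- attr(events, "states")
  fr <- setNames(numeric(length(states)), states)
  for (i in seq_len(nrow(events)))
    fr[events$state[i]] <- fr[events$state[i]] +
      (events$t_end[i] - events$t_start[i]) / dur
  c(fr, unlabeled = max(0, 1 - sum(fr)))
}

#' Compare per-subject state occupancy between groups
#'
#' One two-sided independent t-test per state comparing per-subject mean
#' fractions between groups (e.g. sham vs. lesioned), Holm-adjusted over
#' the states tested.
#'
#' @param fractions data.frame with columns `subject`, `group`, then one
#'   column per state holding per-subject mean fractions.
#' @param states states to test (default: all fraction columns except
#'   `unlabeled`).
#' @param alpha significance level (reported, not enforced).
#' @return data.frame with state, group means, t, raw and Holm-adjusted p,
#'   and significance at `alpha`.
#' @export
compare_group_fractions <- function(fractions, states = NULL, alpha = 0.05) {
  states <- states %||% setdiff(names(fractions),
                                c("subject", "group", "unlabeled"))
  groups <- unique(fractions$group)
  if (length(groups) != 2)
    abort2("exactly two groups required", "phenogait_config_error")
  if (any(table(fractions$group) < 2))
    abort2("each group needs >= 2 subjects",
           "phenogait_insufficient_data_error")
  res <- lapply(states, function(st) {
    a <- fractions[fractions$group == groups[1], st]
    b <- fractions[fractions$group == groups[2], st]
    if (sd(c(a, b)) < 1e-12) {
      # identical constant fractions carry no evidence of a difference
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- t.test(a, b, var.equal = FALSE)
    }
    data.frame(state = st, mean_1 = mean(a), mean_2 = mean(b),
               t = unname(tt$statistic), p_raw = tt$p.value)
  })
  res <- do.call(rbind, res)
  names(res)[2:3] <- paste0("mean_", groups)
  res$p_holm <- p.adjust(res$p_raw, method = "holm")
  res$significant <- res$p_holm < alpha
  res
}

#' Assemble the cleaned multimodal dataset
#'
#' Concatenates per-run feature matrices, replaces outliers (|z| >
#' `outlier_z` on the feature's mean/sd scale) with the feature median,
#' then z-scores each feature. Zero-variance features are dropped with a
#' warning. The normalization record (median, mean, sd, outlier count per
#' feature) is retained so held-out partitions can be transformed with
#' training statistics. Detection on the mean/sd scale (rather than
#' median/MAD) keeps genuinely bimodal state-dependent features intact
#' while still catching isolated spikes.
#'
#' @param fms list of labeled [feature_matrix] objects (one per run) with
#'   identical feature names, or a single concatenated `feature_matrix`.
#' @param outlier_z robust z threshold for outlier replacement.
#' @return object of class `multimodal_dataset`: a `feature_matrix` plus
#'   `normalization` record and `kinematic_block`/`neural_block` name sets
#'   when supplied.
#' @export
assemble_dataset <- function(fms, outlier_z = 4) {
  fm <- if (inherits(fms, "feature_matrix")) fms else fm_rbind(fms)
  norm <- normalization_fit(fm$values, outlier_z)
  vals <- normalization_apply(norm, fm$values)
  if (length(norm$dropped))
    warning("dropped zero-variance feature(s): ",
            paste(norm$dropped, collapse = ", "))
  out <- feature_matrix(vals, fm$times, fm$rate, labels = fm$labels,
                        run_id = fm$run_id, subject_id = fm$subject_id,
                        day_id = fm$day_id)
  out$normalization <- norm
  class(out) <- c("multimodal_dataset", class(out))
  out
}

#' Fit an outlier-to-median + z-score normalization record
#'
#' @param X numeric matrix with feature column names.
#' @param outlier_z robust z threshold.
#' @return list of per-feature statistics usable by
#'   [normalization_apply()].
#' @export
normalization_fit <- function(X, outlier_z = 4) {
  med <- apply(X, 2, median)
  mu0 <- colMeans(X)
  sd0 <- apply(X, 2, sd)
  n_out <- integer(ncol(X))
  Xc <- X
  for (j in seq_len(ncol(X))) {
    if (sd0[j] > 0) {
      out <- abs(X[, j] - mu0[j]) / sd0[j] > outlier_z
      n_out[j] <- sum(out)
      Xc[out, j] <- med[j]
    }
  }
  mu <- colMeans(Xc)
  sdv <- apply(Xc, 2, sd)
  dropped <- colnames(X)[sdv == 0]
  list(median = med, detect_mean = mu0, detect_sd = sd0, mean = mu,
       sd = sdv, outlier_z = outlier_z,
       n_outliers = setNames(n_out, colnames(X)),
       features = colnames(X), dropped = dropped)
}

#' Apply a stored normalization to a feature block
#'
#' @param norm record from [normalization_fit()].
#' @param X matrix whose columns match the record's features.
#' @return cleaned, z-scored matrix (dropped features removed).
#' @export
normalization_apply <- function(norm, X) {
  stopifnot(identical(colnames(X), norm$features))
  for (j in seq_len(ncol(X))) {
    if (norm$detect_sd[j] > 0) {
      out <- abs(X[, j] - norm$detect_mean[j]) / norm$detect_sd[j] >
        norm$outlier_z
      X[out, j] <- norm$median[j]
    }
    X[, j] <- (X[, j] - norm$mean[j]) /
      (if (norm$sd[j] > 0) norm$sd[j] else 1)
  }
  X[, !(colnames(X) %in% norm$dropped), drop = FALSE]
}

#' Grouped K-fold split plan over runs
#'
#' Runs are shuffled once with the given seed and partitioned into `k`
#' near-equal folds; all samples of a run stay on one side of each split.
#'
#' @param run_ids per-sample run key, or the vector of unique run ids.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return object of class `split_plan`: list of folds, each with
#'   `test_runs` and `train_runs`.
#' @export
group_kfold <- function(run_ids, k, seed = 1) {
  runs <- unique(run_ids)
  if (k > length(runs))
    abort2("k exceeds the number of runs", "phenogait_config_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  runs <- sample(runs)
  fold_of <- rep(seq_len(k), length.out = length(runs))
  fold_of <- sort(fold_of)
  folds <- lapply(seq_len(k), function(i)
    list(test_runs = runs[fold_of == i],
         train_runs = runs[fold_of != i]))
  structure(list(folds = folds, k = k, seed = seed, runs = runs),
            class = "split_plan")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
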