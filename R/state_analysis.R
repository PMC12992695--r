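#' Peri-onset feature curves
#'
#' Extracts the feature traces around each onset of `target_state` (time 0
#' = onset) on the feature timeline and averages them pointwise; the
#' across-event standard deviation is reported. Onsets whose full window
#' does not fit inside the run are excluded and counted. No per-event
#' re-baselining is applied.
#'
#' @param features a [feature_matrix] for one run.
#' @param events the run's [event_table].
#' @param target_state state whose onsets are analyzed.
#' @param window `c(before, after)` in seconds (default 2 s each side).
#' @return list with `time` (s relative to onset), `mean` and `sd`
#'   matrices (time x features), `n_events`, `n_excluded`; `empty = TRUE`
#'   when no onset qualifies.
#' @export
peri_onset_curves <- function(features, events, target_state,
                              window = c(2, 2)) {
  rate <- features$rate
  nb <- round(window[1] * rate)
  na_ <- round(window[2] * rate)
  onsets <- events$t_start[events$state == target_state]
  n <- nrow(features$values)
  traces <- list()
  excluded <- 0L
  for (t0 in onsets) {
    i0 <- which.min(abs(features$times - t0))
    if (i0 - nb < 1 || i0 + na_ > n) {
      excluded <- excluded + 1L
      next
    }
    traces[[length(traces) + 1L]] <-
      features$values[(i0 - nb):(i0 + na_), , drop = FALSE]
  }
  if (!length(traces))
    return(list(empty = TRUE, n_events = 0L, n_excluded = excluded))
  arr <- simplify2array(traces)
  list(time = (seq(-nb, na_)) / rate,
       mean = apply(arr, 1:2, mean),
       sd = if (length(traces) > 1) apply(arr, 1:2, sd)
       else matrix(0, nrow(traces[[1]]), ncol(traces[[1]]),
                   dimnames = dimnames(traces[[1]])),
       n_events = length(traces), n_excluded = excluded, empty = FALSE)
}

#' Pool peri-onset curves across runs
#'
#' @param fms list of per-run [feature_matrix] objects.
#' @param evs matching list of [event_table]s.
#' @param target_state,window as in [peri_onset_curves()].
#' @return same structure as [peri_onset_curves()], pooled over all events.
#' @export
peri_onset_cohort <- function(fms, evs, target_state, window = c(2, 2)) {
  rate <- fms[[1]]$rate
  nb <- round(window[1] * rate)
  na_ <- round(window[2] * rate)
  traces <- list()
  excluded <- 0L
  for (i in seq_along(fms)) {
    fm <- fms[[i]]
    onsets <- evs[[i]]$t_start[evs[[i]]$state == target_state]
    for (t0 in onsets) {
      i0 <- which.min(abs(fm$times - t0))
      if (i0 - nb < 1 || i0 + na_ > nrow(fm$values)) {
        excluded <- excluded + 1L
        next
      }
      traces[[length(traces) + 1L]] <-
        fm$values[(i0 - nb):(i0 + na_), , drop = FALSE]
    }
  }
  if (!length(traces))
    return(list(empty = TRUE, n_events = 0L, n_excluded = excluded))
  arr <- simplify2array(traces)
  list(time = seq(-nb, na_) / rate,
       mean = apply(arr, 1:2, mean),
       sd = apply(arr, 1:2, sd),
       n_events = length(traces), n_excluded = excluded, empty = FALSE)
}

#' Joint importance ranking across the linear and embedding models
#'
#' Pairs each feature's importance under both models and assigns a
#' combined rank. The default combination is the maximum (worse) of the
#' two ranks, a conservative reading of "consistently high-scoring";
#' `"mean"` is available.
#'
#' @param imp_linear,imp_embedding importance tables
#'   (`feature`/`importance`/`rank`) over the same feature vocabulary.
#' @param method `"max"` or `"mean"` rank combination.
#' @return data.frame sorted by combined rank.
#' @export
joint_ranking <- function(imp_linear, imp_embedding,
                          method = c("max", "mean")) {
  method <- match.arg(method)
  if (!setequal(imp_linear$feature, imp_embedding$feature))
    abort2("importance tables cover different features",
           "phenogait_config_error")
  m <- merge(imp_linear[, c("feature", "importance", "rank")],
             imp_embedding[, c("feature", "importance", "rank")],
             by = "feature", suffixes = c("_linear", "_embedding"))
  comb <- if (method == "max") pmax(m$rank_linear, m$rank_embedding)
  else (m$rank_linear + m$rank_embedding) / 2
  m$combined_rank <- rank(comb, ties.method = "first")
  m[order(m$combined_rank), ]
}

#' Paired state-contrast tests for selected features
#'
#' Paired two-sided t-tests across subjects for every state pair and
#' feature (3 state pairs x 4 features = 12 tests by default), with a
#' Holm adjustment over all tests.
#'
#' @param means data.frame with columns `subject`, `state`, then one
#'   column per tested feature holding per-subject per-state means.
#' @param features feature columns to test (default: all non-key columns).
#' @param alpha significance level (reported).
#' @return data.frame with one row per (state pair, feature): mean
#'   difference, t, raw and Holm-adjusted p, significance.
#' @export
state_feature_tests <- function(means, features = NULL, alpha = 0.05) {
  features <- features %||% setdiff(names(means), c("subject", "state"))
  states <- sort(unique(means$state))
  pairs <- utils::combn(states, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) for (ft in features) {
    a <- means[means$state == pr[1], c("subject", ft)]
    b <- means[means$state == pr[2], c("subject", ft)]
    mm <- merge(a, b, by = "subject", suffixes = c("_a", "_b"))
    d <- mm[[paste0(ft, "_a")]] - mm[[paste0(ft, "_b")]]
    tt <- if (length(d) >= 2 && sd(d) > 0) t.test(d) else
      list(statistic = c(t = NA_real_), p.value = 1)
    rows[[length(rows) + 1L]] <- data.frame(
      state_a = pr[1], state_b = pr[2], feature = ft,
      n_subjects = length(d), mean_diff = mean(d),
      t = unname(tt$statistic), p_raw = tt$p.value)
  }
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  out$significant <- out$p_holm < alpha
  out
}

#' Bin a feature time series into fixed-duration bins
#'
#' Per-bin feature means; each bin is labeled by the majority of its
#' sample labels. The trailing partial bin is dropped.
#'
#' @param features a [feature_matrix] with labels.
#' @param bin bin length in seconds.
#' @return list `values` (bins x features), `labels`, `t_start` of each
#'   bin; `skipped = TRUE` when the run is shorter than one bin.
#' @export
bin_episodes <- function(features, bin = 1) {
  rate <- features$rate
  per <- round(bin * rate)
  n <- nrow(features$values)
  nb <- n %/% per
  if (nb < 1) return(list(skipped = TRUE))
  idx <- rep(seq_len(nb), each = per)
  keep <- seq_len(nb * per)
  vals <- apply(features$values[keep, , drop = FALSE], 2,
                function(x) tapply(x, idx, mean))
  vals <- matrix(vals, nrow = nb,
                 dimnames = list(NULL, features$feature_names))
  labs <- vapply(seq_len(nb), function(i) {
    tb <- table(features$labels[keep][idx == i])
    names(tb)[which.max(tb)]
  }, character(1))
  list(values = vals, labels = labs,
       t_start = features$times[seq(1, nb * per, by = per)],
       skipped = FALSE)
}

#' Principal components of binned features
#'
#' Standard PCA on z-scored bins with a deterministic sign convention
#' (the largest-magnitude loading of each component is positive).
#'
#' @param binned bins x features matrix.
#' @param n_components components to return.
#' @return list `scores`, `loadings`, `variance_ratio`.
#' @export
pca_project <- function(binned, n_components = 2) {
  if (nrow(binned) <= n_components)
    abort2("need more bins than components", "phenogait_config_error")
  keep <- apply(binned, 2, sd) > 0
  pr <- prcomp(binned[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  nc <- min(n_components, ncol(pr$rotation))
  if (nc < n_components)
    warning("rank-deficient input; returning ", nc, " components")
  L <- pr$rotation[, seq_len(nc), drop = FALSE]
  S <- pr$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    s <- sign(L[which.max(abs(L[, j])), j])
    if (s < 0) {
      L[, j] <- -L[, j]
      S[, j] <- -S[, j]
    }
  }
  list(scores = S, loadings = L,
       variance_ratio = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(nc)])
}

#' Features most correlated with a binary state indicator
#'
#' Point-biserial correlation of each feature with the indicator (1 for
#' `positive_state`), ranked by |r| with the sign retained.
#'
#' @param binned bins x features matrix.
#' @param labels per-bin labels with exactly two classes present.
#' @param positive_state state coded 1.
#' @param n number of features to return.
#' @return data.frame `feature`, `r`, sorted by |r| descending.
#' @export
top_correlated_features <- function(binned, labels, positive_state,
                                    n = 10) {
  if (length(unique(labels)) < 2)
    abort2("both classes must be present", "phenogait_undefined_error")
  ind <- as.numeric(labels == positive_state)
  r <- apply(binned, 2, function(x)
    if (sd(x) > 0) cor(x, ind) else 0)
  out <- data.frame(feature = colnames(binned), r = unname(r))
  out <- out[order(-abs(out$r)), ]
  if (n > nrow(out)) {
    warning("n exceeds feature count; returning all features")
    n <- nrow(out)
  }
  head(out, n)
}

#' Episode table
#'
#' Per-episode feature means with episode label and session key, the unit
#' of the human freezing-of-gait statistics.
#'
#' @param fms list of per-run [feature_matrix] objects (labeled).
#' @param evs matching list of [event_table]s.
#' @param session_ids session key per run (permutation stratum).
#' @return data.frame: `episode`, `session`, `label`, `t_start`, `t_end`,
#'   one column per feature (episode mean).
#' @export
episode_table <- function(fms, evs, session_ids = seq_along(fms)) {
  rows <- list()
  eid <- 0L
  for (i in seq_along(fms)) {
    fm <- fms[[i]]
    ev <- evs[[i]]
    for (j in seq_len(nrow(ev))) {
      sel <- fm$times >= ev$t_start[j] & fm$times < ev$t_end[j]
      if (!any(sel)) next
      eid <- eid + 1L
      mu <- colMeans(fm$values[sel, , drop = FALSE])
      rows[[eid]] <- cbind(
        data.frame(episode = eid, session = session_ids[i],
                   label = ev$state[j], t_start = ev$t_start[j],
                   t_end = ev$t_end[j]),
        as.data.frame(as.list(mu), check.names = FALSE))
    }
  }
  do.call(rbind, rows)
}

#' Channel with the strongest band modulation between episode classes
#'
#' Selects the channel maximizing the absolute difference of label-wise
#' mean band feature across episodes. Ties go to the first channel in
#' stable order (logged in the result).
#'
#' @param episodes an [episode_table()] result.
#' @param band_features named character vector: channel id -> feature
#'   column holding that channel's band amplitude.
#' @param labels the two episode classes compared.
#' @return list `channel`, `modulation` (named vector), `tie`.
#' @export
select_channel_by_band_modulation <- function(episodes, band_features,
                                              labels = c("fog", "gait")) {
  if (!all(labels %in% episodes$label))
    abort2("both episode classes must be present",
           "phenogait_insufficient_data_error")
  mod <- vapply(band_features, function(ft)
    abs(mean(episodes[episodes$label == labels[1], ft]) -
          mean(episodes[episodes$label == labels[2], ft])), numeric(1))
  names(mod) <- names(band_features)
  best <- which(mod == max(mod))
  list(channel = names(band_features)[best[1]], modulation = mod,
       tie = length(best) > 1)
}

#' Within-session (trial-constrained) episode permutation test
#'
#' Statistic: difference of label-wise means of per-episode feature means.
#' The null distribution permutes episode labels only within each session
#' stratum; two-sided p = (1 + #\{|T_perm| >= |T_obs|\}) / (1 + n_perm).
#'
#' @param episodes an [episode_table()] result.
#' @param feature feature column to test.
#' @param labels the two classes; statistic is mean(first) - mean(second).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list `statistic`, `p`, `n_perm`.
#' @export
episode_permutation_test <- function(episodes, feature,
                                     labels = c("fog", "gait"),
                                     n_perm = 10000, seed = 1) {
  v <- episodes[[feature]]
  lab <- episodes$label
  strat <- episodes$session
  if (sum(lab == labels[1]) < 1 || sum(lab == labels[2]) < 1)
    abort2("need episodes of both classes", "phenogait_insufficient_data_error")
  # strata with a single class contribute no label exchanges
  mixed <- names(which(vapply(split(lab, strat),
                              function(l) length(unique(l)) > 1,
                              logical(1))))
  if (!length(mixed))
    abort2("all strata are single-class; test undefined",
           "phenogait_undefined_error")
  stat <- function(l) mean(v[l == labels[1]]) - mean(v[l == labels[2]])
  t_obs <- stat(lab)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx_by_strat <- split(seq_along(lab), strat)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    lp <- lab
    for (s in mixed) {
      ii <- idx_by_strat[[s]]
      lp[ii] <- lab[ii][sample.int(length(ii))]
    }
    if (abs(stat(lp)) >= abs(t_obs) - 1e-12) exceed <- exceed + 1L
  }
  list(statistic = t_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Permutation tests for a feature panel with Bonferroni correction
#'
#' @param episodes an [episode_table()] result.
#' @param features feature columns tested (the correction factor equals
#'   their number, default the 4-feature panel).
#' @param labels,n_perm,seed as in [episode_permutation_test()].
#' @return data.frame `feature`, `statistic`, `p_raw`, `p_bonferroni`.
#' @export
episode_feature_tests <- function(episodes, features,
                                  labels = c("fog", "gait"),
                                  n_perm = 10000, seed = 1) {
  res <- lapply(seq_along(features), function(i) {
    r <- episode_permutation_test(episodes, features[i], labels, n_perm,
                                  seed + i)
    data.frame(feature = features[i], statistic = r$statistic,
               p_raw = r$p)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_raw * length(features))
  out
}
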