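# End-to-end workflows. Each stage is wrapped so a failure marks the
# bundle partial (with the failing stage recorded) instead of aborting.

stage <- function(bundle, name, expr) {
  if (!is.null(bundle$failed_stage)) return(bundle)
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) {
    bundle$failed_stage <- name
    bundle$error <- conditionMessage(res)
    bundle$partial <- TRUE
  } else {
    bundle[[name]] <- res
  }
  bundle
}

#' Compute the multimodal feature set of one session
#'
#' Kinematic features at the frame rate, neural features at the same
#' rate from the (decimated) recording, trimmed to a common timeline,
#' labeled from the event table.
#'
#' @param session a loaded/generated session (`trajectory`, `neural`,
#'   `events`).
#' @param skeleton a [skeleton_config()].
#' @param bands neural band definitions.
#' @param est_window neural estimation window, s.
#' @param burst_threshold_pct burst envelope percentile (`NULL` disables).
#' @return list `features` (combined [feature_matrix] with labels),
#'   `kinematic_names`, `neural_names`.
#' @export
session_features <- function(session, skeleton = rodent_skeleton(),
                             bands = rodent_bands(), est_window = 1.0,
                             burst_threshold_pct = 75) {
  kin <- compute_kinematic_features(session$trajectory, skeleton)
  rec <- session$neural
  if (rec$fs > 1200) rec <- decimate_recording(rec)
  neu <- extract_neural_features(rec, bands,
                                 feature_rate = session$trajectory$frame_rate,
                                 est_window = est_window,
                                 burst_threshold_pct = burst_threshold_pct)
  n <- min(nrow(kin$values), nrow(neu$values))
  trim <- function(fm) feature_matrix(
    fm$values[seq_len(n), , drop = FALSE], fm$times[seq_len(n)], fm$rate,
    run_id = kin$run_id[1], subject_id = kin$subject_id[1],
    day_id = kin$day_id[1])
  both <- fm_cbind(trim(kin), trim(neu))
  both$labels <- align_events_to_samples(session$events,
                                         both$times)
  list(features = both, kinematic_names = kin$feature_names,
       neural_names = neu$feature_names)
}

#' Run the rodent deep-phenotyping workflow
#'
#' Executes: session generation/loading, feature extraction, occupancy
#' statistics (sham vs. lesioned), multimodal assembly with grouped
#' cross-validation, the LDA branch (kinematic: gait vs. non-gait;
#' neural: akinesia vs. active) with permutation importance, the
#' contrastive-embedding branch with embedding importance, the joint
#' importance ranking, peri-onset curves around akinesia onsets, and the
#' 12-test state-feature table.
#'
#' @param spec a [cohort_spec()] (used when `manifest` is `NULL`).
#' @param manifest optional manifest path for on-disk sessions.
#' @param k cross-validation folds over lesioned runs.
#' @param embedding_cfg an [embedding_config()].
#' @param embedding_folds fold indices evaluated by the embedding branch.
#' @param embedding_eval_hop evaluate every n-th embedded window position
#'   (keeps the KNN evaluation and importance scan tractable).
#' @param importance_repeats permutation repeats for LDA importance.
#' @param peri_features features shown in the peri-onset summary
#'   (default: the four biomarker candidates).
#' @param seed seed for split plan and importance permutations.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return results bundle (list); `partial = TRUE` with `failed_stage`
#'   on error.
#' @export
run_rodent_pipeline <- function(spec = cohort_spec(), manifest = NULL,
                                k = 11, embedding_cfg = embedding_config(),
                                embedding_folds = 1,
                                embedding_eval_hop = 5,
                                importance_repeats = 5,
                                peri_features = NULL, seed = 1,
                                out_dir = NULL) {
  bundle <- list(partial = FALSE, seed = seed)
  bundle <- stage(bundle, "sessions", {
    if (!is.null(manifest)) {
      loaded <- load_sessions(read_manifest(manifest))
      lapply(loaded$sessions, function(s) {
        s$group <- "lesioned"
        s$run_id <- s$trajectory$run_id
        s$subject_id <- s$trajectory$subject_id
        s
      })
    } else {
      generate_cohort(spec)$sessions
    }
  })
  bundle <- stage(bundle, "features", {
    lapply(bundle$sessions, function(s) {
      f <- session_features(s)
      f$group <- s$group
      f$events <- s$events
      f
    })
  })
  bundle <- stage(bundle, "occupancy", {
    fr <- do.call(rbind, lapply(seq_along(bundle$sessions), function(i) {
      s <- bundle$sessions[[i]]
      f <- state_time_fractions(s$events)
      cbind(data.frame(subject = s$subject_id, group = s$group),
            as.data.frame(as.list(f)))
    }))
    subj <- aggregate(fr[RODENT_STATES], fr[c("subject", "group")], mean)
    tests <- if (length(unique(subj$group)) == 2)
      compare_group_fractions(subj) else NULL
    list(per_subject = subj, tests = tests)
  })
  bundle <- stage(bundle, "dataset", {
    les <- vapply(bundle$features, function(f) f$group == "lesioned",
                  logical(1))
    fms <- lapply(bundle$features[les], `[[`, "features")
    ds <- assemble_dataset(fms)
    ds$kinematic_block <- intersect(bundle$features[[1]]$kinematic_names,
                                    ds$feature_names)
    ds$neural_block <- intersect(bundle$features[[1]]$neural_names,
                                 ds$feature_names)
    ds
  })
  bundle <- stage(bundle, "plan", {
    group_kfold(bundle$dataset$run_id,
                k = min(k, length(unique(bundle$dataset$run_id))),
                seed = seed)
  })
  bundle <- stage(bundle, "lda_kinematic", {
    cv_lda(bundle$dataset, bundle$plan,
           feature_subset = bundle$dataset$kinematic_block,
           positive_class = "gait",
           class_mapping = c(gait = "gait", stationary = "nonGait",
                             akinesia = "nonGait"),
           n_repeats = importance_repeats, seed = seed)
  })
  bundle <- stage(bundle, "lda_neural", {
    cv_lda(bundle$dataset, bundle$plan,
           feature_subset = bundle$dataset$neural_block,
           positive_class = "akinesia",
           class_mapping = c(gait = "active", stationary = "active",
                             akinesia = "akinesia"),
           n_repeats = importance_repeats, seed = seed)
  })
  bundle <- stage(bundle, "embedding_neural", {
    nd <- bundle$dataset
    cv_embedding(nd, bundle$plan, embedding_cfg,
                 feature_subset = nd$neural_block,
                 folds = embedding_folds, importance = TRUE,
                 eval_hop = embedding_eval_hop)
  })
  bundle <- stage(bundle, "joint_ranking", {
    joint_ranking(bundle$lda_neural$importance,
                  bundle$embedding_neural$importance)
  })
  bundle <- stage(bundle, "peri_onset", {
    les <- vapply(bundle$features, function(f) f$group == "lesioned",
                  logical(1))
    fms <- lapply(bundle$features[les], `[[`, "features")
    evs <- lapply(bundle$features[les], `[[`, "events")
    peri_onset_cohort(fms, evs, "akinesia")
  })
  bundle <- stage(bundle, "state_tests", {
    feats <- peri_features %||%
      intersect(c("Hjorth Complexity (L)", "Hjorth Mobility (R)",
                  "HB-LG Amplitude (L)", "gamma Amplitude (R)"),
                bundle$dataset$feature_names)
    les <- vapply(bundle$features, function(f) f$group == "lesioned",
                  logical(1))
    rows <- list()
    for (f in bundle$features[les]) {
      lab <- f$features$labels
      for (st in RODENT_STATES) {
        sel <- lab == st
        if (sum(sel) < 2) next
        mu <- colMeans(f$features$values[sel, feats, drop = FALSE])
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(subject = f$features$subject_id[1], state = st),
          as.data.frame(as.list(mu), check.names = FALSE))
      }
    }
    pm <- do.call(rbind, rows)
    pm <- aggregate(pm[feats], pm[c("subject", "state")], mean)
    state_feature_tests(pm, feats)
  })
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Run the human freezing-of-gait workflow
#'
#' Executes: session generation/loading, kinematic features with 1-s
#' binning, PCA and top-correlated features for the gait/FoG contrast;
#' neural features, per-episode means, selection of the channel with the
#' strongest beta modulation, and within-session permutation tests for
#' the four biomarker features with Bonferroni correction.
#'
#' @param sessions list of sessions (default: two generated FoG runs).
#' @param neural_rate neural feature rate, Hz.
#' @param n_perm permutations per test.
#' @param seed RNG seed.
#' @param out_dir optional output directory.
#' @return results bundle.
#' @export
run_human_pipeline <- function(sessions = NULL, neural_rate = 100,
                               n_perm = 2000, seed = 1, out_dir = NULL) {
  bundle <- list(partial = FALSE, seed = seed)
  bundle <- stage(bundle, "sessions", {
    sessions %||% list(generate_fog_session(seed = seed),
                       generate_fog_session(seed = seed + 1))
  })
  bundle <- stage(bundle, "kinematic", {
    skel <- skeleton_config(
      markers = c("condyle_L", "shank_L", "meta5_L", "toe_L"),
      angles = list(ankle_L = c("shank_L", "meta5_L", "toe_L")),
      reference_marker = "toe_L",
      features = c("speed", "acceleration", "tangential_acceleration",
                   "angle", "angle_velocity", "angle_acceleration",
                   "height", "forward_movement"))
    binned_all <- NULL
    labels_all <- NULL
    for (s in bundle$sessions) {
      kin <- compute_kinematic_features(s$trajectory, skel)
      kin$labels <- align_events_to_samples(s$events, kin$times)
      kin$values <- normalization_apply(normalization_fit(kin$values),
                                        kin$values)
      kin$feature_names <- colnames(kin$values)
      b <- bin_episodes(kin, bin = 1)
      if (isTRUE(b$skipped)) next
      binned_all <- rbind(binned_all, b$values)
      labels_all <- c(labels_all, b$labels)
    }
    pca <- pca_project(binned_all, 2)
    topf <- top_correlated_features(binned_all, labels_all, "gait", n = 10)
    list(binned = binned_all, labels = labels_all, pca = pca,
         top_features = topf)
  })
  bundle <- stage(bundle, "neural", {
    fms <- list(); evs <- list()
    for (i in seq_along(bundle$sessions)) {
      s <- bundle$sessions[[i]]
      fm <- extract_neural_features(s$neural, human_bands(),
                                    feature_rate = neural_rate,
                                    est_window = 1.0,
                                    burst_threshold_pct = NULL)
      fm$labels <- align_events_to_samples(s$events, fm$times)
      fms[[i]] <- fm
      evs[[i]] <- s$events
    }
    ep <- episode_table(fms, evs, session_ids = seq_along(fms))
    chans <- bundle$sessions[[1]]$neural$channel_names
    hemis <- bundle$sessions[[1]]$neural$hemisphere
    band_feats <- setNames(sprintf("beta Amplitude %s (%s)", chans, hemis),
                           chans)
    sel <- select_channel_by_band_modulation(ep, band_feats)
    tag <- sprintf(" %s (%s)", sel$channel,
                   hemis[match(sel$channel, chans)])
    panel <- paste0(c("Hjorth Complexity", "Hjorth Mobility",
                      "beta Amplitude", "gamma Amplitude"), tag)
    tests <- episode_feature_tests(ep, panel, labels = c("fog", "gait"),
                                   n_perm = n_perm, seed = seed)
    list(episodes = ep, channel = sel, tests = tests)
  })
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Write the tabular parts of a results bundle as CSV/JSON.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  put_csv <- function(x, nm)
    if (!is.null(x)) write.csv(x, file.path(out_dir, nm), row.names = FALSE)
  put_csv(bundle$occupancy$tests, "occupancy_tests.csv")
  put_csv(bundle$lda_kinematic$importance, "lda_kinematic_importance.csv")
  put_csv(bundle$lda_neural$importance, "lda_neural_importance.csv")
  put_csv(bundle$embedding_neural$importance, "embedding_importance.csv")
  put_csv(bundle$joint_ranking, "joint_ranking.csv")
  put_csv(bundle$state_tests, "state_feature_tests.csv")
  put_csv(bundle$neural$tests, "episode_tests.csv")
  if (!is.null(bundle$lda_kinematic))
    jsonlite::write_json(
      list(kinematic = bundle$lda_kinematic$metrics,
           neural = bundle$lda_neural$metrics,
           embedding = bundle$embedding_neural$metrics),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
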