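# File formats
#
# Trajectory CSV dialect: one metadata comment line `# frame_rate_hz=<fs>`,
# then a header of `marker.axis` columns (axis in x/y/z), one row per frame.
# Gaps are the literal string NA. Units are mm.
#
# Neural CSV: header of channel names, one row per sample, microvolts; a
# sidecar JSON `<stem>.meta.json` holds fs_hz and per-channel hemisphere.
#
# Event CSV: metadata line `# trial_duration_s=<T>`, header
# `state,t_start,t_end`, times in seconds.

read_meta_line <- function(path, key) {
  l1 <- readLines(path, n = 1L)
  if (!grepl(paste0("^#\\s*", key, "="), l1))
    abort2(sprintf("expected metadata line '# %s=...' in %s", key, path),
           "phenogait_format_error")
  as.numeric(sub(paste0("^#\\s*", key, "="), "", l1))
}

#' Read marker trajectories from CSV (or C3D via conversion)
#'
#' The CSV dialect is documented in the package vignette: a metadata line
#' with the frame rate, a `marker.axis` header, one row per frame, gaps as
#' `NA`. Only the CSV dialect is parsed natively; C3D files should be
#' converted upstream (the acquisition software exports both).
#'
#' @param path file path.
#' @param run_id,subject_id,day_id identifiers attached to the result.
#' @return a [marker_trajectories] object with markers in file order.
#' @export
read_marker_trajectories <- function(path, run_id = "run",
                                     subject_id = "subject", day_id = "day") {
  if (!file.exists(path))
    abort2(paste("file not found:", path), "phenogait_format_error")
  fr <- read_meta_line(path, "frame_rate_hz")
  df <- tryCatch(
    read.csv(path, comment.char = "#", check.names = FALSE),
    error = function(e) abort2(paste("unreadable trajectory file:", path),
                               "phenogait_format_error"))
  cols <- names(df)
  parts <- strsplit(cols, ".", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) != 2L))
    abort2("trajectory header must be marker.axis columns",
           "phenogait_structure_error")
  markers <- unique(vapply(parts, `[[`, "", 1L))
  pos <- lapply(markers, function(m) {
    need <- paste(m, c("x", "y", "z"), sep = ".")
    if (!all(need %in% cols))
      abort2(paste("marker", m, "lacks x/y/z columns"),
             "phenogait_structure_error")
    as.matrix(df[, need])
  })
  names(pos) <- markers
  marker_trajectories(pos, fr, run_id, subject_id, day_id)
}

#' Write marker trajectories to the CSV dialect
#'
#' @param traj a [marker_trajectories] object.
#' @param path output path.
#' @export
write_marker_trajectories <- function(traj, path) {
  mat <- do.call(cbind, traj$positions)
  colnames(mat) <- unlist(lapply(traj$marker_names,
                                 function(m) paste(m, c("x", "y", "z"),
                                                   sep = ".")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate_hz=%.10g", traj$frame_rate), con)
  write.csv(as.data.frame(mat), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event-label table
#'
#' @param path CSV path (metadata line with trial duration, then
#'   `state,t_start,t_end` rows in seconds).
#' @param states allowed state vocabulary.
#' @return a validated [event_table], sorted by start time.
#' @export
read_event_table <- function(path, states = RODENT_STATES) {
  if (!file.exists(path))
    abort2(paste("file not found:", path), "phenogait_format_error")
  dur <- read_meta_line(path, "trial_duration_s")
  df <- read.csv(path, comment.char = "#")
  event_table(df, trial_duration = dur, states = states)
}

#' Write an event table
#' @param events an [event_table].
#' @param path output path.
#' @export
write_event_table <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trial_duration_s=%.10g", attr(events, "trial_duration")),
             con)
  write.csv(as.data.frame(events), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a neural recording (CSV + JSON sidecar)
#'
#' @param path CSV with one column per channel; `<stem>.meta.json` must
#'   exist with fields `fs_hz`, `channels` (names) and `hemisphere`.
#' @param run_id identifier.
#' @return a [neural_recording].
#' @export
read_neural_recording <- function(path, run_id = "run") {
  meta_path <- paste0(sub("\\.csv$", "", path), ".meta.json")
  if (!file.exists(path) || !file.exists(meta_path))
    abort2(paste("missing signal or sidecar for", path),
           "phenogait_format_error")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  sig <- as.matrix(read.csv(path, check.names = FALSE))
  neural_recording(sig, fs = meta$fs_hz, channel_names = meta$channels,
                   hemisphere = meta$hemisphere, run_id = run_id)
}

#' Write a neural recording (CSV + JSON sidecar)
#' @param rec a [neural_recording].
#' @param path output CSV path.
#' @export
write_neural_recording <- function(rec, path) {
  write.csv(as.data.frame(rec$signal), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs_hz = rec$fs, channels = rec$channel_names,
         hemisphere = rec$hemisphere),
    paste0(sub("\\.csv$", "", path), ".meta.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session manifest (YAML)
#'
#' A manifest lists sessions, each with `trajectory`, `neural`, `events`
#' paths plus `run_id`, `subject_id`, `day_id` and optional `group`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path YAML file.
#' @return list with elements `sessions` (list of session entries) and
#'   `states` (vocabulary, default rodent).
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  m$sessions <- lapply(m$sessions, function(s) {
    for (k in c("trajectory", "neural", "events"))
      if (!grepl("^/", s[[k]])) s[[k]] <- file.path(root, s[[k]])
    for (k in c("run_id", "subject_id", "day_id"))
      if (is.null(s[[k]]) || !nzchar(s[[k]]))
        abort2(paste("manifest session lacks", k), "phenogait_validation_error")
    s
  })
  m$states <- m$states %||% RODENT_STATES
  m
}

#' Load and synchronize one session
#'
#' Kinematic recordings occasionally carry a few extra frames at the start
#' relative to the neural recording. If the kinematic length exceeds the
#' neural-implied expectation by at most `mismatch_tolerance` frames, the
#' excess is trimmed from the start of the kinematic file and logged; a
#' larger mismatch rejects the session with a discard record rather than an
#' error, so batch loading continues. A kinematic file shorter than expected
#' (within tolerance) trims the neural recording's end instead.
#'
#' @param session one manifest session entry (paths + ids).
#' @param mismatch_tolerance maximum trimmable mismatch, in kinematic frames.
#' @param states state vocabulary for the event table.
#' @return list with `ok` (logical), and on success `trajectory`, `neural`,
#'   `events`, `trim` (frames trimmed); on failure a `discard` record.
#' @export
load_session <- function(session, mismatch_tolerance = 5,
                         states = RODENT_STATES) {
  traj <- read_marker_trajectories(session$trajectory, session$run_id,
                                   session$subject_id, session$day_id)
  rec <- read_neural_recording(session$neural, session$run_id)
  ev <- read_event_table(session$events, states = states)
  sync_session(traj, rec, ev, mismatch_tolerance)
}

#' Synchronize already-loaded session components
#'
#' @inheritParams load_session
#' @param traj a [marker_trajectories]; `rec` a [neural_recording];
#'   `ev` an [event_table].
#' @param rec,ev see above.
#' @export
sync_session <- function(traj, rec, ev, mismatch_tolerance = 5) {
  expected <- round(nrow(rec$signal) / rec$fs * traj$frame_rate)
  mismatch <- traj$n_frames - expected
  if (abs(mismatch) > mismatch_tolerance) {
    return(list(ok = FALSE,
                discard = list(run_id = traj$run_id, mismatch = mismatch,
                               tolerance = mismatch_tolerance)))
  }
  trim <- 0L
  if (mismatch > 0) {
    # extra kinematic frames appear at the beginning: trim from the start
    keep <- (mismatch + 1L):traj$n_frames
    traj$positions <- lapply(traj$positions, function(p) p[keep, , drop = FALSE])
    traj$n_frames <- length(keep)
    trim <- mismatch
  } else if (mismatch < 0) {
    ns <- round(traj$n_frames / traj$frame_rate * rec$fs)
    rec$signal <- rec$signal[seq_len(ns), , drop = FALSE]
    trim <- mismatch
  }
  list(ok = TRUE, trajectory = traj, neural = rec, events = ev, trim = trim)
}

#' Load all sessions of a manifest
#'
#' @param manifest result of [read_manifest()].
#' @param mismatch_tolerance see [load_session()].
#' @return list with `sessions` (successfully loaded) and `discarded`
#'   (discard records).
#' @export
load_sessions <- function(manifest, mismatch_tolerance = 5) {
  out <- list(sessions = list(), discarded = list())
  for (s in manifest$sessions) {
    r <- load_session(s, mismatch_tolerance, states = manifest$states)
    if (r$ok) out$sessions[[length(out$sessions) + 1L]] <- r
    else out$discarded[[length(out$discarded) + 1L]] <- r$discard
  }
  out
}
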