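#' Marker trajectory container
#'
#' Holds time-indexed 3D positions (mm) for a set of named markers recorded
#' at a fixed frame rate. Positions are stored as a list of T x 3 matrices
#' (columns x, y, z); missing samples are explicit `NA` rows, never dropped.
#'
#' @param positions named list of numeric T x 3 matrices, one per marker.
#' @param frame_rate frames per second (> 0).
#' @param run_id,subject_id,day_id identifiers carried through the pipeline.
#' @return an object of class `marker_trajectories`.
#' @export
marker_trajectories <- function(positions, frame_rate,
                                run_id = "run", subject_id = "subject",
                                day_id = "day") {
  stopifnot(is.list(positions), length(positions) >= 1, frame_rate > 0)
  if (is.null(names(positions)) || any(names(positions) == ""))
    abort2("all markers must be named", "phenogait_structure_error")
  nf <- vapply(positions, nrow, integer(1))
  if (length(unique(nf)) != 1L)
    abort2("all markers must have the same number of frames",
           "phenogait_structure_error")
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("x", "y", "z")
    p
  })
  structure(list(positions = positions, marker_names = names(positions),
                 frame_rate = frame_rate, n_frames = nf[[1]],
                 run_id = run_id, subject_id = subject_id, day_id = day_id),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("<marker_trajectories> %d markers x %d frames @ %g Hz (run %s)\n",
              length(x$marker_names), x$n_frames, x$frame_rate, x$run_id))
  invisible(x)
}

#' Multichannel neural recording container
#'
#' @param signal numeric T x C matrix, one column per channel, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one per channel.
#' @param hemisphere character vector of "L"/"R", one per channel.
#' @param run_id run identifier.
#' @return an object of class `neural_recording`.
#' @export
neural_recording <- function(signal, fs, channel_names = colnames(signal),
                             hemisphere, run_id = "run") {
  signal <- as.matrix(signal)
  stopifnot(fs > 0)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(signal)))
  if (length(channel_names) != ncol(signal))
    abort2("one channel name per column required", "phenogait_structure_error")
  if (missing(hemisphere) || length(hemisphere) != ncol(signal) ||
      !all(hemisphere %in% c("L", "R")))
    abort2("hemisphere ('L'/'R') must be defined for every channel",
           "phenogait_structure_error")
  colnames(signal) <- channel_names
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 hemisphere = hemisphere, run_id = run_id),
            class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("<neural_recording> %d channels x %d samples @ %g Hz (run %s)\n",
              ncol(x$signal), nrow(x$signal), x$fs, x$run_id))
  invisible(x)
}

#' Labeled state-interval table for one run
#'
#' Intervals are half-open `[t_start, t_end)` in seconds, pairwise
#' non-overlapping, and contained in `[0, trial_duration]`.
#'
#' @param events data.frame with columns `state`, `t_start`, `t_end`.
#' @param trial_duration trial length in seconds.
#' @param states allowed state vocabulary.
#' @return an object of class `event_table` (a validated, sorted data.frame
#'   plus attributes).
#' @export
event_table <- function(events, trial_duration,
                        states = RODENT_STATES) {
  events <- as.data.frame(events)
  stopifnot(all(c("state", "t_start", "t_end") %in% names(events)),
            trial_duration > 0)
  events$state <- as.character(events$state)
  bad <- setdiff(unique(events$state), states)
  if (length(bad))
    abort2(paste0("unknown state label(s): ", paste(bad, collapse = ", ")),
           "phenogait_validation_error")
  if (any(events$t_start >= events$t_end))
    abort2("every event must satisfy t_start < t_end",
           "phenogait_validation_error")
  if (any(events$t_start < 0) || any(events$t_end > trial_duration + 1e-9))
    abort2("events must lie within [0, trial_duration]",
           "phenogait_validation_error")
  events <- events[order(events$t_start), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) > 1 &&
      any(events$t_start[-1] < events$t_end[-nrow(events)] - 1e-9))
    abort2("events overlap", "phenogait_validation_error")
  structure(events, trial_duration = trial_duration, states = states,
            class = c("event_table", "data.frame"))
}

#' Feature matrix at the common feature rate
#'
#' @param values numeric T x F matrix with unique column names.
#' @param times sample times in seconds.
#' @param rate feature rate in Hz.
#' @param labels optional per-sample state label.
#' @param run_id,subject_id,day_id grouping keys (scalar or per-sample).
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, times, rate, labels = NULL,
                           run_id = "run", subject_id = "subject",
                           day_id = "day") {
  values <- as.matrix(values)
  if (anyNA(values))
    abort2("feature matrix contains NA after assembly", "phenogait_nan_error")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    abort2("feature names must be present and unique",
           "phenogait_structure_error")
  stopifnot(length(times) == nrow(values), rate > 0)
  if (!is.null(labels) && length(labels) != nrow(values))
    abort2("labels length must equal sample count", "phenogait_structure_error")
  rep_key <- function(k) if (length(k) == 1L) rep(k, nrow(values)) else k
  structure(list(values = values, times = times, rate = rate,
                 feature_names = colnames(values), labels = labels,
                 run_id = rep_key(run_id), subject_id = rep_key(subject_id),
                 day_id = rep_key(day_id)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$rate))
  invisible(x)
}

#' Column-bind two feature matrices sharing a timeline
#'
#' @param a,b `feature_matrix` objects with equal sample counts.
#' @return combined `feature_matrix`; labels/keys taken from `a`.
#' @export
fm_cbind <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (nrow(a$values) != nrow(b$values))
    abort2("feature matrices must share the timeline", "phenogait_structure_error")
  feature_matrix(cbind(a$values, b$values), a$times, a$rate,
                 labels = a$labels %||% b$labels,
                 run_id = a$run_id, subject_id = a$subject_id,
                 day_id = a$day_id)
}

#' Row-bind feature matrices from several runs
#'
#' @param fms list of `feature_matrix` objects with identical feature names.
#' @return concatenated `feature_matrix`.
#' @export
fm_rbind <- function(fms) {
  stopifnot(length(fms) >= 1)
  nm <- fms[[1]]$feature_names
  for (f in fms) if (!identical(f$feature_names, nm))
    abort2("feature names differ across runs", "phenogait_structure_error")
  feature_matrix(do.call(rbind, lapply(fms, `[[`, "values")),
                 unlist(lapply(fms, `[[`, "times")),
                 fms[[1]]$rate,
                 labels = if (all(vapply(fms, function(f) !is.null(f$labels),
                                         logical(1))))
                   unlist(lapply(fms, `[[`, "labels")) else NULL,
                 run_id = unlist(lapply(fms, `[[`, "run_id")),
                 subject_id = unlist(lapply(fms, `[[`, "subject_id")),
                 day_id = unlist(lapply(fms, `[[`, "day_id")))
}
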