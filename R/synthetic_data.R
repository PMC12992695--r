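# Synthetic cohort generator. Encodes the documented effect structure of
# the hemiparkinsonian runway experiment: lesioned animals dwell longer in
# akinesia; akinesia carries elevated 20-42 Hz (HB-LG) power and Hjorth
# complexity with reduced mobility; gait carries elevated gamma power and
# mobility; gait kinematics oscillate and drift forward while akinetic
# markers barely move.

#' Cohort specification for the synthetic generator
#'
#' Defaults are the package's reference study conditions: 8 sham and 6
#' lesioned subjects, 55 lesioned runs in total, 200 Hz kinematics, a
#' 1000 Hz two-channel neural signal, exponential state dwells truncated
#' to [0.5 s, run duration], and state-gated spectral profiles calibrated
#' so akinesia raises HB-LG power and Hjorth complexity and lowers
#' mobility relative to gait.
#'
#' @param n_sham,n_lesioned subjects per group.
#' @param runs_sham runs per sham subject.
#' @param runs_lesioned integer vector of runs per lesioned subject
#'   (default sums to 55).
#' @param run_duration seconds per run.
#' @param frame_rate kinematic rate, Hz.
#' @param neural_fs neural rate, Hz (post-decimation equivalent).
#' @param dwell_sham,dwell_lesioned named mean dwell times (s) per state.
#' @param entry_sham,entry_lesioned state entry weights.
#' @param gait_amp oscillation amplitude during gait, mm.
#' @param gait_freq stride frequency, Hz.
#' @param gait_drift forward drift during gait, mm/s.
#' @param jitter_stationary,jitter_akinesia marker jitter sd, mm.
#' @param neural_profiles per-state list of `hblg`, `gamma`, `broadband`
#'   amplitudes (left hemisphere; the right hemisphere swaps the lesion
#'   emphasis).
#' @param transition_smooth_s state-gate smoothing, s.
#' @param seed base RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sham = 8, n_lesioned = 6, runs_sham = 5,
                        runs_lesioned = c(10, 9, 9, 9, 9, 9),
                        run_duration = 20, frame_rate = 200,
                        neural_fs = 1000,
                        dwell_sham = c(gait = 4, stationary = 2.5,
                                       akinesia = 0.8),
                        dwell_lesioned = c(gait = 2, stationary = 2,
                                           akinesia = 4),
                        entry_sham = c(gait = 0.5, stationary = 0.35,
                                       akinesia = 0.15),
                        entry_lesioned = c(gait = 0.35, stationary = 0.3,
                                           akinesia = 0.35),
                        gait_amp = 15, gait_freq = 5, gait_drift = 300,
                        jitter_stationary = 2, jitter_akinesia = 0.1,
                        neural_profiles = list(
                          gait = c(hblg = 0, gamma = 1.8, broadband = 0.5),
                          stationary = c(hblg = 0.5, gamma = 0.5,
                                         broadband = 0.35),
                          akinesia = c(hblg = 2.2, gamma = 0,
                                       broadband = 0.35)),
                        transition_smooth_s = 0.1, seed = 1) {
  stopifnot(all(dwell_sham > 0), all(dwell_lesioned > 0),
            dwell_lesioned["akinesia"] > dwell_sham["akinesia"])
  structure(as.list(environment()), class = "cohort_spec")
}

truncexp <- function(mean, lo, hi) min(max(rexp(1, 1 / mean), lo), hi)

#' Generate a semi-Markov locomotor state sequence
#'
#' Alternating states with exponential dwells truncated to
#' `[0.5, duration]`; the sequence covers the whole run (no unlabeled
#' residual).
#'
#' @param spec a [cohort_spec()].
#' @param group `"sham"` or `"lesioned"`.
#' @param duration run duration, s.
#' @param seed RNG seed.
#' @return an [event_table].
#' @export
generate_state_sequence <- function(spec, group = "lesioned",
                                    duration = spec$run_duration, seed = 1) {
  dwell <- if (group == "sham") spec$dwell_sham else spec$dwell_lesioned
  entry <- if (group == "sham") spec$entry_sham else spec$entry_lesioned
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  states <- names(dwell)
  cur <- sample(states, 1, prob = entry)
  t <- 0
  rows <- list()
  while (t < duration) {
    d <- truncexp(dwell[[cur]], 0.5, duration)
    end <- min(t + d, duration)
    rows[[length(rows) + 1L]] <- data.frame(state = cur, t_start = t,
                                            t_end = end)
    t <- end
    others <- setdiff(states, cur)
    cur <- sample(others, 1, prob = entry[others])
  }
  event_table(do.call(rbind, rows), trial_duration = duration)
}

pink_noise <- function(n, fs, beta = 1) {
  w <- rnorm(n)
  W <- fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  f[1] <- f[2]
  x <- Re(fft(W / f^(beta / 2), inverse = TRUE)) / n
  x / sd(x)
}

band_noise <- function(n, fs, lo, hi) {
  b <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(b, rnorm(n))
  x / sd(x)
}

smooth_gate <- function(ind, fs, smooth_s) {
  w <- max(1L, round(smooth_s * fs))
  as.numeric(stats::filter(ind, rep(1 / w, w), sides = 2) |>
               (\(x) { x[is.na(x)] <- ind[is.na(x)]; x })())
}

state_gates <- function(events, n, fs, smooth_s) {
  times <- (seq_len(n) - 1) / fs
  lab <- align_events_to_samples(events, times)
  states <- attr(events, "states")
  g <- lapply(states, function(s)
    smooth_gate(as.numeric(lab == s), fs, smooth_s))
  names(g) <- states
  g
}

#' Generate one synthetic session (kinematics + neural + events)
#'
#' During gait, hindlimb markers oscillate sinusoidally with per-marker
#' phase offsets on top of a forward drift; stationary and akinetic
#' segments are jitter with no drift (akinetic jitter far smaller). Each
#' neural channel is 1/f background noise plus state-gated band
#' oscillators: akinesia gates the 20-42 Hz oscillator on (left hemisphere
#' emphasized), gait gates the 60-90 Hz oscillator on (right hemisphere
#' emphasized); a state-dependent broadband admixture controls Hjorth
#' complexity. State transitions are smoothed over 100 ms.
#'
#' @param spec a [cohort_spec()].
#' @param group `"sham"` or `"lesioned"`.
#' @param run_id,subject_id,day_id identifiers.
#' @param seed RNG seed.
#' @return list `trajectory`, `neural`, `events`, `group`.
#' @export
generate_session <- function(spec, group = "lesioned", run_id = "run1",
                             subject_id = "s1", day_id = "d1", seed = 1) {
  events <- generate_state_sequence(spec, group, spec$run_duration, seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  fr <- spec$frame_rate
  nk <- round(spec$run_duration * fr)
  tk <- (seq_len(nk) - 1) / fr
  gk <- state_gates(events, nk, fr, spec$transition_smooth_s)
  # forward position integrates drift gated by gait
  xdrift <- cumsum(spec$gait_drift * gk$gait) / fr
  jitter_sd <- gk$stationary * spec$jitter_stationary +
    gk$akinesia * spec$jitter_akinesia + gk$gait * 1.0
  lp <- signal::butter(2, 10 / (fr / 2), type = "low")
  base_z <- c(crest = 80, hip = 60, knee = 40, ankle = 20, mtp = 5)
  pos <- list()
  for (side in c("L", "R")) {
    ysign <- if (side == "L") -1 else 1
    side_phase <- if (side == "L") 0 else pi   # alternating stepping
    for (mi in seq_along(base_z)) {
      m <- names(base_z)[mi]
      phase <- side_phase + (mi - 1) * 0.6
      osc_amp <- spec$gait_amp * (mi - 1) / (length(base_z) - 1)
      jit <- function() signal::filtfilt(lp, rnorm(nk)) * jitter_sd
      x <- 50 * mi + xdrift + gk$gait * osc_amp *
        sin(2 * pi * spec$gait_freq * tk + phase) + jit()
      y <- ysign * 15 + 0.2 * jit()
      z <- base_z[[m]] + gk$gait * 0.5 * osc_amp *
        pmax(0, sin(2 * pi * spec$gait_freq * tk + phase)) + 0.2 * jit()
      pos[[paste(m, side, sep = "_")]] <- cbind(x = x, y = y, z = z)
    }
  }
  traj <- marker_trajectories(pos, fr, run_id, subject_id, day_id)
  # neural: two channels; the lesioned hemisphere (left) carries the
  # stronger HB-LG gating, the right the stronger gamma gating
  fs <- spec$neural_fs
  nn <- round(spec$run_duration * fs)
  gn <- state_gates(events, nn, fs, spec$transition_smooth_s)
  prof <- spec$neural_profiles
  chan <- function(hemi) {
    wts <- if (hemi == "L") c(hblg = 1, gamma = 0.6)
    else c(hblg = 0.6, gamma = 1)
    hb <- band_noise(nn, fs, 20, 42)
    gm <- band_noise(nn, fs, 60, 90)
    wh <- rnorm(nn)
    x <- pink_noise(nn, fs)
    for (s in names(prof)) {
      x <- x + gn[[s]] * (prof[[s]][["hblg"]] * wts[["hblg"]] * hb +
                            prof[[s]][["gamma"]] * wts[["gamma"]] * gm +
                            prof[[s]][["broadband"]] * wh)
    }
    x * 50   # microvolt scale
  }
  rec <- neural_recording(cbind(ECoG_L = chan("L"), ECoG_R = chan("R")),
                          fs = fs, hemisphere = c("L", "R"),
                          run_id = run_id)
  list(trajectory = traj, neural = rec, events = events, group = group)
}

#' Generate the full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param events_only generate only the event tables (fast path for
#'   occupancy analyses).
#' @param write_dir optional directory; when given, every session is
#'   written in the package CSV formats together with a YAML manifest.
#' @return list `sessions` (each as [generate_session()] plus ids),
#'   `table` (data.frame of run/subject/group), and `manifest_path` when
#'   written.
#' @export
generate_cohort <- function(spec = cohort_spec(), events_only = FALSE,
                            write_dir = NULL) {
  subjects <- c(paste0("sham", seq_len(spec$n_sham)),
                paste0("pd", seq_len(spec$n_lesioned)))
  groups <- rep(c("sham", "lesioned"), c(spec$n_sham, spec$n_lesioned))
  runs_per <- c(rep(spec$runs_sham, spec$n_sham), spec$runs_lesioned)
  sessions <- list()
  tab <- list()
  for (si in seq_along(subjects)) {
    for (ri in seq_len(runs_per[si])) {
      run_id <- sprintf("%s_r%02d", subjects[si], ri)
      seed_i <- spec$seed + si * 1009L + ri * 13L
      if (events_only) {
        s <- list(events = generate_state_sequence(
          spec, groups[si], spec$run_duration, seed_i),
          group = groups[si])
      } else {
        s <- generate_session(spec, groups[si], run_id, subjects[si],
                              day_id = sprintf("d%02d", ri), seed = seed_i)
      }
      s$run_id <- run_id
      s$subject_id <- subjects[si]
      sessions[[length(sessions) + 1L]] <- s
      tab[[length(tab) + 1L]] <- data.frame(
        run_id = run_id, subject_id = subjects[si], group = groups[si])
    }
  }
  out <- list(sessions = sessions, table = do.call(rbind, tab))
  if (!is.null(write_dir) && !events_only) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    man <- list(states = RODENT_STATES, sessions = list())
    for (s in out$sessions) {
      stem <- file.path(write_dir, s$run_id)
      write_marker_trajectories(s$trajectory, paste0(stem, "_traj.csv"))
      write_neural_recording(s$neural, paste0(stem, "_neural.csv"))
      write_event_table(s$events, paste0(stem, "_events.csv"))
      man$sessions[[length(man$sessions) + 1L]] <- list(
        trajectory = paste0(s$run_id, "_traj.csv"),
        neural = paste0(s$run_id, "_neural.csv"),
        events = paste0(s$run_id, "_events.csv"),
        run_id = s$run_id, subject_id = s$subject_id,
        day_id = s$trajectory$day_id, group = s$group)
    }
    out$manifest_path <- file.path(write_dir, "manifest.yaml")
    yaml::write_yaml(man, out$manifest_path)
  }
  out
}

#' Generate a synthetic human walking session with freezing of gait
#'
#' Gait/FoG event sequence at 100 Hz kinematics and 250 Hz six-channel
#' STN-like LFP. One channel (default `LFP_L2`) carries the injected FoG
#' modulation: beta (13-20 Hz) and broadband power rise (raising Hjorth
#' complexity, lowering mobility) and gamma rises, while gait carries a
#' gamma-dominated spectrum; the remaining channels are unmodulated
#' background.
#'
#' @param duration run duration, s.
#' @param seed RNG seed.
#' @param modulated_channel channel carrying the FoG effect.
#' @param fog_dwell,gait_dwell mean dwell times, s.
#' @return list `trajectory`, `neural`, `events`.
#' @export
generate_fog_session <- function(duration = 60, seed = 1,
                                 modulated_channel = "LFP_L2",
                                 fog_dwell = 4, gait_dwell = 6) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # alternating gait/fog sequence
  rows <- list()
  t <- 0
  cur <- "gait"
  while (t < duration) {
    d <- truncexp(if (cur == "gait") gait_dwell else fog_dwell, 1, duration)
    end <- min(t + d, duration)
    rows[[length(rows) + 1L]] <- data.frame(state = cur, t_start = t,
                                            t_end = end)
    t <- end
    cur <- if (cur == "gait") "fog" else "gait"
  }
  events <- event_table(do.call(rbind, rows), duration,
                        states = HUMAN_STATES)
  fr <- 100
  nk <- round(duration * fr)
  tk <- (seq_len(nk) - 1) / fr
  gait_ind <- smooth_gate(
    as.numeric(align_events_to_samples(events, tk) == "gait"), fr, 0.1)
  lp <- signal::butter(2, 8 / (fr / 2), type = "low")
  pos <- list()
  for (m in c("condyle_L", "shank_L", "meta5_L", "toe_L")) {
    ph <- runif(1, 0, 2 * pi)
    osc <- gait_ind * 40 * sin(2 * pi * 1.8 * tk + ph)
    drift <- cumsum(800 * gait_ind) / fr
    jit <- function() signal::filtfilt(lp, rnorm(nk)) * 3
    pos[[m]] <- cbind(x = drift + osc + jit(), y = jit(),
                      z = 50 + pmax(0, osc) * 0.5 + jit())
  }
  traj <- marker_trajectories(pos, fr, run_id = "human_run")
  fs <- 250
  nn <- round(duration * fs)
  gaten <- state_gates(events, nn, fs, 0.1)
  channels <- paste0("LFP_", rep(c("L", "R"), each = 3), 1:3)
  sig <- sapply(channels, function(ch) {
    x <- pink_noise(nn, fs) + 0.4 * band_noise(nn, fs, 60, 90) +
      0.3 * rnorm(nn)
    if (ch == modulated_channel) {
      # FoG: beta-dominated with a gamma rise (complexity up, mobility
      # down, beta up, gamma up); gait: mild broadband
      x <- x + gaten$fog * (2.2 * band_noise(nn, fs, 13, 20) +
                              0.9 * band_noise(nn, fs, 60, 90) +
                              0.3 * rnorm(nn)) +
        gaten$gait * (0.2 * band_noise(nn, fs, 60, 90) + 0.5 * rnorm(nn))
    }
    x * 20
  })
  rec <- neural_recording(sig, fs = fs, channel_names = channels,
                          hemisphere = rep(c("L", "R"), each = 3),
                          run_id = "human_run")
  list(trajectory = traj, neural = rec, events = events)
}
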