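#' Frequency band definition
#'
#' @param name band name (e.g. "HB-LG").
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return object of class `band_definition`.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo < f_hi))
    abort2("band must satisfy 0 < f_lo < f_hi", "phenogait_config_error")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' Default rodent bands
#'
#' High-beta/low-gamma (HB-LG, 20-42 Hz) is the established pathological
#' oscillation band in hemiparkinsonian rats; gamma defaults to 60-90 Hz.
#' @return list of [band_definition]s.
#' @export
rodent_bands <- function() {
  list(band_definition("HB-LG", 20, 42), band_definition("gamma", 60, 90))
}

#' Default human bands (beta 13-20 Hz, gamma 60-90 Hz)
#' @return list of [band_definition]s.
#' @export
human_bands <- function() {
  list(band_definition("beta", 13, 20), band_definition("gamma", 60, 90))
}

#' Hjorth parameters of a signal segment
#'
#' Activity is the signal variance; mobility the square root of the ratio
#' of the first difference's variance to the signal variance (a discrete
#' estimate of mean frequency content, dimensionless); complexity the
#' mobility of the first difference divided by the mobility of the signal
#' (deviation from a pure sinusoid; 1 for a pure sine).
#'
#' @param x numeric vector, length >= 3, finite.
#' @return named list `activity`, `mobility`, `complexity`.
#' @export
hjorth_parameters <- function(x) {
  if (length(x) < 3 || any(!is.finite(x)))
    abort2("window must be finite with length >= 3",
           "phenogait_insufficient_data_error")
  d <- diff(x)
  v0 <- var(x); v1 <- var(d)
  if (v0 <= 0 || v1 <= 0)
    abort2("degenerate (constant or linear) signal",
           "phenogait_degenerate_signal_error")
  v2 <- var(diff(d))
  mob <- sqrt(v1 / v0)
  list(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Log band amplitude from a Hann-windowed periodogram
#'
#' @param x signal segment.
#' @param band a [band_definition] (must lie below Nyquist).
#' @param fs sampling rate, Hz.
#' @param eps floor guarding `log(0)`.
#' @return log of the mean periodogram power over `[f_lo, f_hi]`.
#' @export
band_amplitude <- function(x, band, fs, eps = 1e-12) {
  if (band$f_hi >= fs / 2)
    abort2("band exceeds Nyquist frequency", "phenogait_config_error")
  n <- length(x)
  w <- hann(n)
  p <- Mod(fft((x - mean(x)) * w))^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band$f_lo & f <= band$f_hi
  log(mean(p[sel]) + eps)
}

# analytic signal via FFT (for band-limited envelopes)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

band_envelope <- function(x, band, fs) {
  b <- signal::butter(4, c(band$f_lo, band$f_hi) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(b, x)
  Mod(analytic_signal(xf))
}

#' Burst rate and mean duration of band-limited amplitude excursions
#'
#' The band-filtered amplitude envelope is thresholded at a run-level
#' percentile (default 75th); every supra-threshold excursion of at least
#' one envelope sample is a burst.
#'
#' @param x signal segment (or full run).
#' @param band a [band_definition].
#' @param fs sampling rate, Hz.
#' @param threshold_pct percentile in (0, 100) used when `threshold` is not
#'   supplied.
#' @param threshold optional precomputed run-level envelope threshold.
#' @return list `rate` (bursts/s) and `mean_duration` (s; 0 when no burst).
#' @export
burst_metrics <- function(x, band, fs, threshold_pct = 75, threshold = NULL) {
  if (threshold_pct <= 0 || threshold_pct >= 100)
    abort2("threshold_pct must lie in (0, 100)", "phenogait_config_error")
  env <- band_envelope(x, band, fs)
  thr <- threshold %||% quantile(env, threshold_pct / 100, names = FALSE)
  above <- env > thr
  r <- rle(above)
  nb <- sum(r$values)
  dur <- if (nb) mean(r$lengths[r$values]) / fs else 0
  list(rate = nb / (length(x) / fs), mean_duration = dur)
}

# rolling variance over trailing windows of length w at positions `pos`
# (pos are window end indices); via cumulative sums
roll_var <- function(x, w, pos) {
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  s <- cs[pos] - cs[pos - w + 1] + x[pos - w + 1]
  s2 <- cs2[pos] - cs2[pos - w + 1] + x[pos - w + 1]^2
  (s2 - s^2 / w) / (w - 1)
}

#' Sliding-window neural feature extraction
#'
#' For each channel, features are computed on the trailing (causal)
#' estimation window ending at each output sample, at the requested feature
#' rate. The panel comprises the three Hjorth parameters, log band
#' amplitudes for each configured band, and band burst rate/duration
#' (envelope thresholded at a run-level percentile). Output samples whose
#' trailing window would start before the recording are back-filled with
#' the first valid value so the feature timeline matches the recording.
#' Feature names carry the channel hemisphere, e.g. `"Hjorth Complexity (L)"`.
#'
#' @param rec a [neural_recording].
#' @param bands list of [band_definition]s.
#' @param feature_rate output rate, Hz (must divide `fs` evenly).
#' @param est_window trailing estimation window, seconds.
#' @param burst_threshold_pct run-level envelope percentile for bursts;
#'   `NULL` disables burst features.
#' @return a [feature_matrix] at `feature_rate`.
#' @export
extract_neural_features <- function(rec, bands = rodent_bands(),
                                    feature_rate = 200, est_window = 1.0,
                                    burst_threshold_pct = 75) {
  fs <- rec$fs
  n <- nrow(rec$signal)
  w <- round(est_window * fs)
  if (w < 3) abort2("est_window too short", "phenogait_config_error")
  if (n < w) abort2("recording shorter than est_window",
                    "phenogait_insufficient_data_error")
  hop <- fs / feature_rate
  out_pos <- unique(pmin(n, round(seq(hop, n, by = hop))))  # window ends
  valid <- out_pos >= w
  pos_v <- out_pos[valid]
  n_out <- length(out_pos)
  # two channels (one per hemisphere) are tagged by hemisphere alone;
  # larger montages carry the channel name too
  hemi_tag <- function(i)
    if (ncol(rec$signal) <= 2) sprintf(" (%s)", rec$hemisphere[i])
    else sprintf(" %s (%s)", rec$channel_names[i], rec$hemisphere[i])
  feats <- list()
  for (ci in seq_len(ncol(rec$signal))) {
    x <- rec$signal[, ci]
    tag <- hemi_tag(ci)
    # Hjorth via rolling variances of x, dx, ddx
    dx <- c(0, diff(x))
    ddx <- c(0, diff(dx))
    v0 <- roll_var(x, w, pos_v)
    v1 <- roll_var(dx[-1], w - 1, pos_v - 1)
    v2 <- roll_var(ddx[-(1:2)], w - 2, pos_v - 2)
    v0 <- pmax(v0, 1e-300); v1 <- pmax(v1, 1e-300); v2 <- pmax(v2, 1e-300)
    mob <- sqrt(v1 / v0)
    backfill <- function(vals) {
      full <- numeric(n_out)
      full[valid] <- vals
      if (any(!valid)) full[!valid] <- vals[1]
      full
    }
    feats[[paste0("Hjorth Activity", tag)]] <- backfill(v0)
    feats[[paste0("Hjorth Mobility", tag)]] <- backfill(mob)
    feats[[paste0("Hjorth Complexity", tag)]] <- backfill(sqrt(v2 / v1) / mob)
    # band amplitudes: Hann periodogram on every trailing window (chunked)
    if (length(bands)) {
      wn <- hann(w)
      f <- (seq_len(w) - 1) * fs / w
      sels <- lapply(bands, function(b) f >= b$f_lo & f <= b$f_hi)
      bp <- matrix(0, length(pos_v), length(bands))
      chunk <- 2048L
      for (s0 in seq(1, length(pos_v), by = chunk)) {
        ii <- s0:min(s0 + chunk - 1L, length(pos_v))
        wm <- matrix(x[outer((-w + 1):0, pos_v[ii], `+`)], nrow = w)
        wm <- (wm - rep(colMeans(wm), each = w)) * wn
        P <- Mod(stats::mvfft(wm))^2
        for (bi in seq_along(bands))
          bp[ii, bi] <- colMeans(P[sels[[bi]], , drop = FALSE])
      }
      for (bi in seq_along(bands))
        feats[[paste0(bands[[bi]]$name, " Amplitude", tag)]] <-
          backfill(log(bp[, bi] + 1e-12))
    }
    # burst metrics from run-level thresholded envelopes
    if (!is.null(burst_threshold_pct)) {
      for (b in bands) {
        env <- band_envelope(x, b, fs)
        thr <- quantile(env, burst_threshold_pct / 100, names = FALSE)
        above <- env > thr
        starts <- cumsum(c(above[1], diff(above) > 0))
        cs_above <- cumsum(above)
        # bursts overlapping the window: starts strictly inside it, plus an
        # ongoing burst covering the window's first sample
        n_start <- starts[pos_v] - starts[pos_v - w + 1] + above[pos_v - w + 1]
        supra <- cs_above[pos_v] - cs_above[pos_v - w + 1] + above[pos_v - w + 1]
        rate <- n_start / (w / fs)
        mdur <- ifelse(n_start > 0, supra / pmax(n_start, 1) / fs, 0)
        feats[[paste0(b$name, " Burst Rate", tag)]] <- backfill(rate)
        feats[[paste0(b$name, " Burst Duration", tag)]] <- backfill(mdur)
      }
    }
  }
  vals <- do.call(cbind, feats)
  colnames(vals) <- names(feats)
  feature_matrix(vals, times = out_pos / fs, rate = feature_rate,
                 run_id = rec$run_id)
}

#' Welch power spectral density
#'
#' Mean of Hann-windowed, detrended periodograms over 50%-overlapping
#' segments; one-sided density scaling so that the integral over frequency
#' approximates the signal variance.
#'
#' @param x signal.
#' @param fs sampling rate, Hz.
#' @param seg_s segment length, s.
#' @param overlap fractional overlap between segments.
#' @return list `freq` (Hz), `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 0.5, overlap = 0.5) {
  nseg <- round(seg_s * fs)
  nseg <- min(nseg, length(x))
  hopw <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = hopw)
  w <- hann(nseg)
  u <- sum(w^2)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg))^2
  }
  acc <- acc / length(starts) / (fs * u)
  nh <- floor(nseg / 2) + 1
  psd <- acc[seq_len(nh)]
  dbl <- if (nseg %% 2 == 0) 2:(nh - 1) else 2:nh  # no Nyquist bin when odd
  psd[dbl] <- 2 * psd[dbl]                 # one-sided doubling
  list(freq = (seq_len(nh) - 1) * fs / nseg, psd = psd)
}

#' State-specific PSD summary
#'
#' Welch PSD on the first `occurrence_window` seconds of each state
#' occurrence at least that long, averaged within state over the 5-100 Hz
#' grid (configurable); shorter occurrences are excluded and counted. The
#' HB-LG (20-42 Hz) band mean is reported per state.
#'
#' @param rec a [neural_recording] (first channel used unless `channel`
#'   given).
#' @param events an [event_table].
#' @param occurrence_window seconds analyzed from each occurrence start.
#' @param f_range analysis range, Hz.
#' @param band_range band summarized per state, Hz.
#' @param channel channel index.
#' @param seg_s Welch segment length, s.
#' @return list with `freq`, per-state `psd` (list), `n_occurrences`,
#'   `n_excluded`, `band_mean`, and `empty` flag.
#' @export
state_psd <- function(rec, events, occurrence_window = 1.5,
                      f_range = c(5, 100), band_range = c(20, 42),
                      channel = 1, seg_s = 0.5) {
  x <- rec$signal[, channel]
  fs <- rec$fs
  states <- attr(events, "states")
  out <- list(psd = list(), n_occurrences = integer(0),
              n_excluded = integer(0), band_mean = numeric(0))
  freq <- NULL
  for (st in states) {
    ev <- events[events$state == st, , drop = FALSE]
    durs <- ev$t_end - ev$t_start
    qual <- which(durs >= occurrence_window)
    out$n_excluded[st] <- nrow(ev) - length(qual)
    out$n_occurrences[st] <- length(qual)
    if (!length(qual)) next
    acc <- NULL
    for (i in qual) {
      i0 <- floor(ev$t_start[i] * fs) + 1
      seg <- x[i0:min(i0 + round(occurrence_window * fs) - 1, length(x))]
      ww <- welch_psd(seg, fs, seg_s = seg_s)
      keep <- ww$freq >= f_range[1] & ww$freq <= f_range[2]
      freq <- ww$freq[keep]
      acc <- if (is.null(acc)) ww$psd[keep] else acc + ww$psd[keep]
    }
    out$psd[[st]] <- acc / length(qual)
    bsel <- freq >= band_range[1] & freq <= band_range[2]
    out$band_mean[st] <- mean(out$psd[[st]][bsel])
  }
  out$freq <- freq
  out$empty <- length(out$psd) == 0
  out
}

#' Decimate a recording with an anti-alias filter
#'
#' High-rate acquisition (e.g. 24414.1 Hz) is reduced to a working rate
#' (default 1000 Hz) before feature extraction, since all analysis bands
#' lie below 100 Hz.
#'
#' @param rec a [neural_recording].
#' @param target_fs target sampling rate, Hz.
#' @return decimated [neural_recording].
#' @export
decimate_recording <- function(rec, target_fs = 1000) {
  q <- rec$fs / target_fs
  qi <- max(1L, round(q))
  if (qi == 1L) return(rec)
  sig <- apply(rec$signal, 2, function(x)
    signal::decimate(x, qi, ftype = "fir"))
  neural_recording(sig, fs = rec$fs / qi, channel_names = rec$channel_names,
                   hemisphere = rec$hemisphere, run_id = rec$run_id)
}
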