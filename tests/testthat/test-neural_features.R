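test_that("Hjorth parameters match sinusoid closed forms", {
  fs <- 200
  t <- seq(1 / fs, 10, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  h <- hjorth_parameters(x)
  expect_lt(abs(h$complexity - 1), 1e-3)
  expect_lt(abs(h$mobility - 2 * sin(pi * 10 / fs)), 1e-3)
  expect_equal(h$activity, var(x))
  expect_error(hjorth_parameters(rep(1, 100)),
               class = "phenogait_degenerate_signal_error")
})

test_that("mobility/complexity are scale invariant, activity scales as c^2", {
  set.seed(5)
  x <- rnorm(2000)
  h1 <- hjorth_parameters(x)
  h2 <- hjorth_parameters(-7.5 * x)
  expect_equal(h2$mobility, h1$mobility, tolerance = 1e-12)
  expect_equal(h2$complexity, h1$complexity, tolerance = 1e-12)
  expect_equal(h2$activity, 7.5^2 * h1$activity, tolerance = 1e-9)
})

test_that("mobility increases strictly with sinusoid frequency", {
  fs <- 200
  t <- seq(1 / fs, 5, by = 1 / fs)
  mob <- vapply(c(5, 10, 20, 40, 80),
                function(f) hjorth_parameters(sin(2 * pi * f * t))$mobility,
                numeric(1))
  expect_true(all(diff(mob) > 0))
})

test_that("band amplitude separates in-band from out-of-band power", {
  fs <- 1000
  t <- seq(1 / fs, 1, by = 1 / fs)
  x <- sin(2 * pi * 30 * t)
  inband <- band_amplitude(x, band_definition("HB-LG", 20, 42), fs)
  outband <- band_amplitude(x, band_definition("gamma", 60, 90), fs)
  # > 20 dB margin (log-power difference > 20/10*log(10))
  expect_gt((inband - outband) * 10 / log(10), 20)
  # cross-check the in-band estimate against a direct FFT oracle
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  p <- Mod(stats::fft((x - mean(x)) * w))^2
  f <- (seq_len(n) - 1) * fs / n
  oracle <- log(mean(p[f >= 20 & f <= 42]) + 1e-12)
  expect_equal(inband, oracle, tolerance = 1e-12)
})

test_that("white noise has near-equal per-Hz power across bands", {
  set.seed(8)
  fs <- 1000
  x <- rnorm(fs * 30)
  b1 <- band_amplitude(x, band_definition("a", 20, 42), fs)
  b2 <- band_amplitude(x, band_definition("b", 60, 90), fs)
  expect_lt(abs(exp(b1) / exp(b2) - 1), 0.2)
})

test_that("all-zero window hits the log floor; Nyquist violation errors", {
  expect_equal(band_amplitude(numeric(100), band_definition("a", 5, 20), 100),
               log(1e-12))
  expect_error(
    band_amplitude(rnorm(100), band_definition("a", 40, 60), 100),
    class = "phenogait_config_error")
})

test_that("band amplitude of an in-band sinusoid is phase invariant", {
  fs <- 1000
  t <- seq(1 / fs, 1, by = 1 / fs)
  vals <- vapply(seq(0, 2 * pi, length.out = 8), function(ph)
    band_amplitude(sin(2 * pi * 30 * t + ph),
                   band_definition("HB-LG", 20, 42), fs), numeric(1))
  expect_lt(diff(range(exp(vals))) / mean(exp(vals)), 0.01)
})

test_that("burst metrics recover injected bursts and reject bad config", {
  fs <- 1000
  n <- 10 * fs
  set.seed(9)
  x <- 0.1 * rnorm(n)
  # five 100 ms 70 Hz bursts over 10 s -> 0.5 bursts/s
  starts <- round(seq(1, n - fs, length.out = 5))
  t <- seq_len(round(0.1 * fs)) / fs
  for (s in starts) x[s + seq_along(t) - 1] <-
    x[s + seq_along(t) - 1] + 3 * sin(2 * pi * 70 * t)
  # run-level threshold between the noise floor and the burst amplitude
  bm <- burst_metrics(x, band_definition("gamma", 60, 90), fs,
                      threshold = 1.5)
  expect_lt(abs(bm$rate - 0.5) / 0.5, 0.2)
  expect_gt(bm$mean_duration, 0.03)
  expect_error(burst_metrics(x, band_definition("gamma", 60, 90), fs,
                             threshold_pct = 0),
               class = "phenogait_config_error")
})

test_that("sub-threshold envelope reports zero bursts", {
  fs <- 500
  x <- sin(2 * pi * 30 * seq(1, fs * 2) / fs) * 0.01
  bm <- burst_metrics(x, band_definition("b", 20, 42), fs,
                      threshold = 10)
  expect_equal(bm$rate, 0)
  expect_equal(bm$mean_duration, 0)
})

test_that("neural feature extraction has correct windowing arithmetic", {
  set.seed(10)
  fs <- 1000
  rec <- neural_recording(cbind(a = rnorm(10 * fs)), fs = fs,
                          hemisphere = "L")
  fm <- extract_neural_features(rec, rodent_bands(), feature_rate = 200,
                                est_window = 1, burst_threshold_pct = NULL)
  expect_equal(nrow(fm$values), 10 * 200)
  expect_equal(fm$rate, 200)
  # back-filled rows equal the first valid value
  first_valid <- which(fm$times >= 1)[1]
  expect_equal(fm$values[1, ], fm$values[first_valid, ])
  expect_error(extract_neural_features(
    neural_recording(cbind(a = rnorm(100)), fs = fs, hemisphere = "L"),
    rodent_bands(), 200, est_window = 1),
    class = "phenogait_insufficient_data_error")
})

test_that("stationary sinusoid gives a constant in-band amplitude", {
  fs <- 1000
  t <- seq(1 / fs, 10, by = 1 / fs)
  rec <- neural_recording(cbind(a = sin(2 * pi * 30 * t)), fs = fs,
                          hemisphere = "L")
  fm <- extract_neural_features(rec, list(band_definition("HB-LG", 20, 42)),
                                feature_rate = 200, est_window = 1,
                                burst_threshold_pct = NULL)
  v <- exp(fm$values[fm$times >= 1, "HB-LG Amplitude (L)"])
  expect_lt(diff(range(v)) / mean(v), 0.01)
})

test_that("a spectral splice shows up within one causal estimation window", {
  fs <- 1000
  t1 <- seq(1 / fs, 5, by = 1 / fs)
  x <- c(sin(2 * pi * 75 * t1), sin(2 * pi * 30 * t1))
  rec <- neural_recording(cbind(a = x), fs = fs, hemisphere = "L")
  fm <- extract_neural_features(rec, list(band_definition("HB-LG", 20, 42)),
                                feature_rate = 200, est_window = 1,
                                burst_threshold_pct = NULL)
  hb <- fm$values[, "HB-LG Amplitude (L)"]
  before <- mean(hb[fm$times > 3 & fm$times <= 5])
  after <- mean(hb[fm$times > 6 & fm$times <= 7])
  expect_gt(after, before + 3)
  # causal: no rise before the splice
  expect_lt(max(hb[fm$times > 2 & fm$times <= 5]) - before, 1)
})

test_that("Welch PSD integral matches the variance (Parseval)", {
  set.seed(12)
  fs <- 1000
  x <- rnorm(fs * 20)
  ps <- welch_psd(x, fs)
  integral <- sum(ps$psd) * (ps$freq[2] - ps$freq[1])
  expect_lt(abs(integral - var(x)) / var(x), 0.05)
})

test_that("state PSD averages qualifying occurrences and counts exclusions", {
  fs <- 1000
  dur <- 12
  set.seed(13)
  t <- seq(1 / fs, dur, by = 1 / fs)
  ev <- event_table(data.frame(
    state = c("akinesia", "gait", "akinesia", "gait"),
    t_start = c(0, 2, 5, 9),
    t_end = c(2, 5, 6, 12)), dur)   # one akinesia occurrence only 1 s
  gate <- align_events_to_samples(ev, t)
  x <- rnorm(length(t)) + ifelse(gate == "akinesia",
                                 3 * sin(2 * pi * 30 * t), 0)
  rec <- neural_recording(cbind(a = x), fs = fs, hemisphere = "L")
  ps <- state_psd(rec, ev)
  expect_equal(unname(ps$n_excluded["akinesia"]), 1L)
  expect_equal(unname(ps$n_occurrences["akinesia"]), 1L)
  expect_gt(ps$band_mean[["akinesia"]], ps$band_mean[["gait"]])
  expect_true(all(ps$freq >= 5 & ps$freq <= 100))
})

test_that("state PSD averaging is invariant to occurrence order", {
  fs <- 500
  set.seed(14)
  x <- rnorm(10 * fs)
  rec <- neural_recording(cbind(a = x), fs = fs, hemisphere = "L")
  ev1 <- event_table(data.frame(state = c("gait", "gait"),
                                t_start = c(0, 5), t_end = c(2, 7)), 10)
  ev2 <- event_table(data.frame(state = c("gait", "gait"),
                                t_start = c(5, 0), t_end = c(7, 2)), 10)
  expect_equal(state_psd(rec, ev1)$psd$gait, state_psd(rec, ev2)$psd$gait)
})
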