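# Windowing, the Table-style time/frequency statistics, and fusion.

test_that("window grid arithmetic and majority labeling", {
  tr <- label_track(0, 240, "roll")
  w <- make_windows(tr, 240)
  expect_equal(nrow(w), 22)  # floor((240-30)/10)+1
  expect_true(all(w$label == "roll"))

  tr2 <- label_track(c(0, 100), c(100, 240), c("takeoff", "stall"))
  w2 <- make_windows(tr2, 240)
  straddle <- w2[w2$start_s == 80, ]  # 20 s takeoff vs 10 s stall
  expect_identical(straddle$label, "takeoff")

  expect_equal(nrow(make_windows(tr, 20)), 0)

  rej <- data.frame(start_s = 30, end_s = 60)
  w3 <- make_windows(tr, 240, rejected = rej)
  expect_false(any(rej$start_s < w3$end_s & rej$end_s > w3$start_s))
  expect_equal(nrow(w3), 22 - 5)  # starts 0..50 overlap [30,60)
})

test_that("basic statistics match their definitions and oracle", {
  expect_equal(stat_features(c(3, 3, 3)), list(mean = 3, std = 0, rms = 3))
  expect_equal(stat_features(c(1, -1)), list(mean = 0, std = 1, rms = 1))
  s <- stat_features(c(800, 810, 790, 805))
  expect_equal(s$mean, 801.25)
  expect_equal(s$std, bf_pop_sd(c(800, 810, 790, 805)), tolerance = 1e-12)
  expect_equal(s$rms, bf_rms(c(800, 810, 790, 805)), tolerance = 1e-12)
})

test_that("time-domain HRV features: closed forms and strictness", {
  h <- hrv_time_features(c(800, 800, 800))
  expect_equal(h[c("nn", "hr", "sdnn", "rmssd", "pnn50")],
               list(nn = 800, hr = 75, sdnn = 0, rmssd = 0, pnn50 = 0))
  h2 <- hrv_time_features(c(800, 860, 800))
  expect_equal(h2$rmssd, 60)
  expect_equal(h2$pnn50, 100)
  expect_equal(h2$sdsd, 60)
  # a successive difference of exactly 20 ms is NOT > 20 (strict)
  h3 <- hrv_time_features(c(790, 810))
  expect_equal(h3$pnn20, 0)
  expect_equal(h3$pnn50, 0)
  expect_true(all(is.na(unlist(hrv_time_features(800)))))
})

test_that("pNN50 <= pNN20 and SDSD tracks RMSSD on random tachograms", {
  set.seed(10)
  for (i in 1:25) {
    rr <- 800 + cumsum(rnorm(60, 0, 15))
    h <- hrv_time_features(rr)
    expect_lte(h$pnn50, h$pnn20)
    # SDSD^2 = RMSSD^2 - mean(diff)^2, so they agree when drift is small
    expect_equal(h$sdsd^2 + mean(diff(rr))^2, h$rmssd^2, tolerance = 1e-9)
  }
})

test_that("spectral HRV concentrates power in the stimulated band", {
  t <- seq(0.8, 240, by = 0.8)
  rr_lf <- 800 + 40 * sin(2 * pi * 0.1 * t)
  f <- hrv_freq_features(t, rr_lf)
  total <- f$ulf + f$vlf + f$lf + f$hf
  expect_gt(f$lf / total, 0.90)

  rr_hf <- 800 + 40 * sin(2 * pi * 0.25 * t)
  f2 <- hrv_freq_features(t, rr_hf)
  expect_gt(f2$hf / (f2$ulf + f2$vlf + f2$lf + f2$hf), 0.85)
  expect_lt(f2$lf_hf, 0.2)

  # short buffer: slow bands missing, LF/HF still estimable
  sel <- t <= min(t) + 90
  f3 <- hrv_freq_features(t[sel], rr_lf[sel])
  expect_true(is.na(f3$ulf) && is.na(f3$vlf))
  expect_false(is.na(f3$lf_hf))
})

test_that("EMG features: integral arithmetic, tone localization, oracle", {
  x <- rep(c(2, -2), 1024 * 15)  # |x| = 2 for 30 s at 1024 Hz
  e <- emg_features(x, 1024)
  expect_equal(e$iemg, 60, tolerance = 1e-9)
  expect_equal(e$mean, 2)
  expect_equal(e$std, 0)
  expect_equal(e$rms, 2)

  t <- (0:(1024 * 30 - 1)) / 1024
  tone <- sin(2 * pi * 120 * t)
  e2 <- emg_features(tone, 1024)
  expect_lt(abs(e2$mf - 120), 1024 / 4096 + 0.3)
  expect_lt(abs(e2$mpf - 120), 1)

  set.seed(11)
  x3 <- rnorm(1024 * 30)
  e3 <- emg_features(x3, 1024)
  spec <- welch_psd(x3, 1024, segment_s = 4, overlap = 0.5)
  expect_equal(e3$mf, bf_median_frequency(spec$freq, spec$psd),
               tolerance = 1e-9)
  expect_equal(e3$mpf, bf_mean_power_frequency(spec$freq, spec$psd),
               tolerance = 1e-9)
})

test_that("respiration features find the breathing frequency", {
  t <- (0:(64 * 30 - 1)) / 64
  x <- 5 + sin(2 * pi * 0.3 * t)
  r <- resp_features(x, 64)
  expect_lt(abs(r$freq - 0.3), 0.02)
  expect_equal(r$mean, mean(x))
  expect_true(is.na(resp_features(rep(1, 64 * 30), 64)$freq))
})

test_that("band powers match the loop oracle on random spectra", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(1000)
    spec <- welch_psd(x, 4, segment_s = 60)
    for (band in list(c(0, 0.003), c(0.003, 0.04), c(0.04, 0.15),
                      c(0.15, 0.4))) {
      expect_equal(band_power(spec, band[1], band[2]),
                   bf_band_power(spec$freq, spec$psd, spec$df,
                                 band[1], band[2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("fusion emits 28 features per window with consistent bookkeeping", {
  fm <- mini_fm()
  df <- as.data.frame(fm)
  expect_identical(setdiff(names(df), c("subject", "window_start_s", "label")),
                   feature_names())
  cl <- mini_clean()
  wins <- make_windows(cl$label_track,
                       length(cl$channels$ECG) / cl$rates[["ECG"]],
                       rejected = cl$rejected)
  expect_equal(nrow(df), nrow(wins))
  expect_false(anyDuplicated(paste(df$subject, df$window_start_s)) > 0)
  # percentages bounded, dispersion/powers non-negative on non-missing rows
  expect_true(all(df$pnn50 >= 0 & df$pnn50 <= 100, na.rm = TRUE))
  expect_true(all(df$pnn20 >= 0 & df$pnn20 <= 100, na.rm = TRUE))
  for (f in c("sdnn", "rmssd", "sdsd", "ulf", "vlf", "lf", "hf", "lf_hf")) {
    expect_true(all(df[[f]] >= 0, na.rm = TRUE), info = f)
  }
})

test_that("generator band structure is recovered through the full chain", {
  # only a 0.1 Hz modulator -> LF dominates; only slow drift -> ULF+VLF win
  base <- behavior_profile("takeoff", 3, mean_rr_ms = 800, rr_sd_ms = 0,
                           ulf_amp_ms = 0, lf_amp_ms = 30, hf_amp_ms = 0)
  set.seed(13)
  ch <- simulate_ecg(base, 240, noise_sd = 0)
  x <- filter_channel(zscore_normalize(ch$samples), "ECG", 512)
  b <- detect_r_peaks(as.numeric(x), 512)
  f <- hrv_freq_features(b$r_peak_times_s[-1], b$rr_intervals_ms)
  expect_gt(f$lf, f$hf)
  expect_gt(f$lf, f$ulf + f$vlf)

  slow <- behavior_profile("takeoff", 3, mean_rr_ms = 800, rr_sd_ms = 0,
                           ulf_amp_ms = 40, lf_amp_ms = 0, hf_amp_ms = 0)
  set.seed(14)
  ch2 <- simulate_ecg(slow, 240, noise_sd = 0)
  x2 <- filter_channel(zscore_normalize(ch2$samples), "ECG", 512)
  b2 <- detect_r_peaks(as.numeric(x2), 512)
  f2 <- hrv_freq_features(b2$r_peak_times_s[-1], b2$rr_intervals_ms)
  expect_gt(f2$ulf + f2$vlf, f2$lf + f2$hf)
})
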