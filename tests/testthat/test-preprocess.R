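# Normalization, the percentage artifact rule, tile rejection, imputation,
# the filter bank, beat detection and downsampling.

test_that("z-score normalization matches its closed form and invariances", {
  expect_equal(zscore_normalize(c(1, 2, 3)),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(500, 7, 3)
  z <- zscore_normalize(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  expect_equal(zscore_normalize(z), z, tolerance = 1e-9)          # idempotent
  expect_equal(zscore_normalize(2.5 * x - 4), z, tolerance = 1e-9) # affine inv
  expect_error(zscore_normalize(c(5, 5, 5)), "constant signal")
})

test_that("percentage-rule ectopic detection uses the accepted reference", {
  expect_identical(detect_ectopic(c(100, 110, 100), 0.20),
                   c(FALSE, FALSE, FALSE))
  expect_identical(detect_ectopic(c(100, 130, 100), 0.20),
                   c(FALSE, TRUE, FALSE))
  # 121 vs 100 is 21% -> flagged; 100 is then compared to the accepted 100
  expect_identical(detect_ectopic(c(100, 121, 100), 0.20),
                   c(FALSE, TRUE, FALSE))
  # exactly 20% is not ectopic (strict >)
  expect_identical(detect_ectopic(c(100, 120), 0.20), c(FALSE, FALSE))
  # zero reference makes the next comparison undefined -> flagged
  expect_identical(detect_ectopic(c(0, 1, 1), 0.20),
                   c(FALSE, TRUE, TRUE))
  # non-finite samples are missing and do not move the reference
  expect_identical(detect_ectopic(c(100, NA, 105), 0.20),
                   c(FALSE, TRUE, FALSE))
})

test_that("tile rejection applies the strict 20% rule on a t=0 grid", {
  rate <- 10
  n <- rate * 90  # three 30-s tiles
  mask <- rep(FALSE, n)
  mask[1:(0.25 * 300)] <- TRUE               # tile 1: 25% flagged
  mask[301:360] <- TRUE                      # tile 2: exactly 20%
  res <- reject_windows(seq_len(n), mask, rate)
  expect_equal(res$rejected$start_s, 0)
  expect_equal(res$rejected$end_s, 30)
  expect_equal(sum(!res$keep), 300)
  res2 <- reject_windows(seq_len(n), rep(FALSE, n), rate)
  expect_equal(nrow(res2$rejected), 0)
  expect_true(all(res2$keep))
})

test_that("neighborhood-mean imputation follows the centered-window rule", {
  ramp <- as.numeric(1:100)
  mask <- rep(FALSE, 100)
  mask[50] <- TRUE
  expect_equal(impute_flagged(ramp, mask)[50], 50)  # symmetric mean on a ramp

  mask0 <- rep(FALSE, 100)
  mask0[1] <- TRUE
  expect_equal(impute_flagged(ramp, mask0)[1], mean(2:6))  # boundary shrink

  expect_identical(impute_flagged(ramp, rep(FALSE, 100)), ramp)

  # all neighbors flagged -> nearest unflagged value
  mask2 <- rep(FALSE, 100)
  mask2[40:52] <- TRUE
  out <- impute_flagged(ramp, mask2, w = 5)
  expect_equal(out[46], ramp[39])  # window 44:48 fully flagged; nearest is 39
  expect_true(all(is.finite(out)))
})

test_that("imputation leaves no non-finite values behind", {
  set.seed(2)
  x <- rnorm(2000) + 50
  x[sample(2000, 60)] <- NA
  mask <- detect_ectopic(x, 0.2)
  out <- impute_flagged(x, mask)
  expect_true(all(is.finite(out)))
})

test_that("the filter bank respects the Nyquist guard and the published
           cutoffs", {
  set.seed(3)
  x <- rnorm(64 * 40)
  y <- filter_channel(x, "GSR", 64)
  log <- attr(y, "filter_log")
  expect_true(any(grepl("bandstop:skipped-nyquist", log)))
  expect_true(any(grepl("lowpass:5Hz", log)))
  expect_length(y, length(x))

  y2 <- filter_channel(rnorm(32 * 40), "SKT", 32)
  log2 <- attr(y2, "filter_log")
  expect_true(any(grepl("highpass:skipped", log2)))
  expect_true(any(grepl("lowpass:skipped-nyquist", log2)))

  # Nyquist guard across all channels: no applied stage at/above rate/2
  for (kind in channel_kinds()) {
    rate <- channel_native_rate(kind)
    lg <- attr(filter_channel(rnorm(rate * 10), kind, rate), "filter_log")
    applied <- regmatches(lg, regexpr("[0-9.]+(?=Hz)", lg, perl = TRUE))
    if (length(applied) > 0) {
      expect_true(all(as.numeric(applied) < rate / 2), info = kind)
    }
  }
})

test_that("the ECG chain notches a 50 Hz tone by at least 20 dB and removes
           DC", {
  fs <- 512
  t <- (0:(fs * 20 - 1)) / fs
  tone <- sin(2 * pi * 50 * t)
  y <- filter_channel(tone, "ECG", fs)
  mid <- (2 * fs):(18 * fs)
  atten_db <- 20 * log10(sqrt(mean(y[mid]^2)) / sqrt(mean(tone[mid]^2)))
  expect_lt(atten_db, -20)

  z <- filter_channel(rep(1, fs * 20) + 0.01 * sin(2 * pi * 10 * t), "ECG", fs)
  expect_lt(abs(mean(z[mid])), 0.01)
})

test_that("beat detection meets the generator ground truth", {
  # white RR jitter only: slow modulators would bias the 60-s mean RR
  prof <- behavior_profile("takeoff", 3, mean_rr_ms = 800, rr_sd_ms = 15,
                           ulf_amp_ms = 0, lf_amp_ms = 0, hf_amp_ms = 0)
  set.seed(9)
  ch <- simulate_ecg(prof, 60, noise_sd = 0)
  x <- filter_channel(zscore_normalize(ch$samples), "ECG", ch$rate)
  beats <- detect_r_peaks(as.numeric(x), ch$rate)
  truth <- attr(ch, "r_peak_times_s")
  expect_gte(length(beats$r_peak_times_s), length(truth) - 1)
  expect_lte(length(beats$r_peak_times_s), length(truth) + 1)
  expect_lt(abs(mean(beats$rr_intervals_ms[beats$rr_valid]) - 800), 5)
  expect_true(all(diff(beats$r_peak_times_s) > 0))

  none <- detect_r_peaks(rep(0, 512 * 10), 512)
  expect_length(none$r_peak_times_s, 0)
  expect_true(all(is.na(unlist(hrv_time_features(none$rr_intervals_ms)))))
})

test_that("downsampling is bin-mean averaging", {
  expect_equal(downsample(rep(3, 5120), 512, 2), rep(3, 20))
  expect_equal(downsample(as.numeric(0:639), 64, 2)[1], mean(0:31))
  expect_length(downsample(as.numeric(0:639), 64, 2), 20)
  expect_length(downsample(numeric(0), 64, 2), 0)
})

test_that("preprocessing is bit-identical on reruns and tracks imputation", {
  s <- mini_set()
  a <- preprocess_recording_set(s)
  b <- preprocess_recording_set(s)
  for (k in channel_kinds()) expect_identical(a$channels[[k]], b$channels[[k]])
  expect_identical(a$beats$r_peak_times_s, b$beats$r_peak_times_s)
  expect_true(all(vapply(a$channels, function(x) all(is.finite(x)),
                         logical(1))))
  expect_true(all(a$imputed_counts >= 0))
})
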