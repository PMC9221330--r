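# Sliding-window (30 s / 10 s) extraction of the 28-dimensional fused feature
# vector: 13 ECG/HRV features, 3 skin-conductance, 7 EMG, 4 respiration, 1
# skin temperature. Spectral HRV uses a rolling tachogram buffer (up to 5 min,
# truncated at the current behavior segment) because ULF/VLF are not estimable
# from 30 s of data.

#' Canonical fused feature names (fixed order)
#'
#' ECG block: instantaneous value, HR, NN, SDNN, SDSD, RMSSD, pNN50, pNN20,
#' ULF, VLF, LF, HF, LF/HF. GSR block: value, mean, SD. EMG block: value,
#' mean, SD, RMS, iEMG, median frequency, mean power frequency (amplitude
#' statistics on the rectified waveform; see vignette). RESP block: value,
#' mean, SD, dominant frequency. SKT block: value.
#'
#' @return character vector of 28 names.
#' @export
feature_names <- function() {
  c("ecg_value", "hr", "nn", "sdnn", "sdsd", "rmssd", "pnn50", "pnn20",
    "ulf", "vlf", "lf", "hf", "lf_hf",
    "sc_value", "sc_mean", "sc_std",
    "emg_value", "emg_mean", "emg_std", "emg_rms", "iemg", "emg_mf", "emg_mpf",
    "resp_value", "resp_mean", "resp_std", "resp_freq",
    "skt_value")
}

#' The retained 19-feature subset used after importance screening
#' @return character vector of 19 names.
#' @export
selected_feature_names <- function() {
  c("nn", "sdnn", "pnn50", "pnn20", "vlf", "lf", "hf",
    "resp_value", "resp_mean", "resp_std",
    "sc_value", "sc_mean", "sc_std",
    "emg_mean", "emg_std", "emg_rms", "iemg", "emg_mf", "emg_mpf")
}

#' Feature matrix container
#'
#' @param df data.frame with columns `subject`, `window_start_s`, the 28
#'   canonical features, `label`.
#' @return object of class `pf_feature_matrix`.
#' @export
feature_matrix <- function(df) {
  need <- c("subject", "window_start_s", feature_names(), "label")
  stopifnot(all(need %in% names(df)))
  df <- df[, need]
  key <- paste(df$subject, df$window_start_s)
  if (anyDuplicated(key)) stop("duplicated (subject, window_start) keys")
  structure(list(df = df, feature_names = feature_names()),
            class = "pf_feature_matrix")
}

#' @export
as.data.frame.pf_feature_matrix <- function(x, ...) x$df

#' @export
print.pf_feature_matrix <- function(x, ...) {
  cat(sprintf("<pf_feature_matrix %d windows x %d features, %d subjects, complete rows: %d>\n",
              nrow(x$df), length(x$feature_names),
              length(unique(x$df$subject)), sum(stats::complete.cases(
                x$df[, x$feature_names]))))
  invisible(x)
}

#' Rows with no missing feature values
#' @param fm a `pf_feature_matrix`.
#' @param features feature subset to require completeness on.
#' @return data.frame subset.
#' @export
complete_rows <- function(fm, features = feature_names()) {
  df <- as.data.frame(fm)
  df[stats::complete.cases(df[, features, drop = FALSE]), , drop = FALSE]
}

#' Sliding feature-window grid
#'
#' Windows of `window_s` advance by `step_s` from t = 0; a window's label is
#' the behavior covering the majority of its span. Windows overlapping a label
#' gap or a rejected preprocessing tile are dropped.
#'
#' @param track a [label_track()].
#' @param duration_s recording duration.
#' @param window_s,step_s window geometry, seconds.
#' @param rejected optional data.frame (`start_s`, `end_s`) of rejected tiles.
#' @return data.frame with `start_s`, `end_s`, `label`.
#' @export
make_windows <- function(track, duration_s, window_s = 30, step_s = 10,
                         rejected = NULL) {
  if (duration_s < window_s) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0)))
  }
  starts <- seq(0, duration_s - window_s, by = step_s)
  lab <- vapply(starts, function(s) majority_label(track, s, s + window_s),
                character(1))
  keep <- !is.na(lab)
  if (!is.null(rejected) && nrow(rejected) > 0) {
    hits <- vapply(starts, function(s) {
      any(rejected$start_s < s + window_s & rejected$end_s > s)
    }, logical(1))
    keep <- keep & !hits
  }
  data.frame(start_s = starts[keep], end_s = starts[keep] + window_s,
             label = lab[keep], stringsAsFactors = FALSE)
}

#' Basic window statistics (mean, population SD, RMS)
#' @param x numeric window, non-empty.
#' @return named list `mean`, `std`, `rms`.
#' @export
stat_features <- function(x) {
  if (length(x) == 0) return(list(mean = NA_real_, std = NA_real_, rms = NA_real_))
  list(mean = mean(x), std = pop_sd(x), rms = sqrt(mean(x^2)))
}

#' Time-domain heart-rate-variability features
#'
#' @param rr_ms numeric vector of valid NN intervals (ms) within the window.
#' @return named list: `nn` (mean RR, ms), `hr` (60000/NN, bpm), `sdnn`
#'   (population SD), `rmssd`, `sdsd`, `pnn50`, `pnn20` (percentages of
#'   successive differences strictly exceeding 50/20 ms). All `NA` when fewer
#'   than 2 intervals are available.
#' @export
hrv_time_features <- function(rr_ms) {
  if (length(rr_ms) < 2) {
    return(list(nn = NA_real_, hr = NA_real_, sdnn = NA_real_,
                rmssd = NA_real_, sdsd = NA_real_, pnn50 = NA_real_,
                pnn20 = NA_real_))
  }
  d <- diff(rr_ms)
  nn <- mean(rr_ms)
  list(nn = nn, hr = 60000 / nn, sdnn = pop_sd(rr_ms),
       rmssd = sqrt(mean(d^2)), sdsd = pop_sd(d),
       pnn50 = 100 * mean(abs(d) > 50), pnn20 = 100 * mean(abs(d) > 20))
}

#' Frequency-domain HRV features from a tachogram buffer
#'
#' The RR series is resampled to a uniform 4 Hz tachogram and integrated over
#' the standard bands: ULF <= 0.003 Hz, VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz,
#' HF 0.15-0.4 Hz; `lf_hf = lf / hf`. ULF/VLF require at least
#' `min_buffer_s` of buffer; LF/HF/LF-HF require at least 60 s.
#'
#' @param peak_times_s times (seconds) of the closing R-peak of each interval.
#' @param rr_ms RR intervals (ms), same length as `peak_times_s`.
#' @param min_buffer_s minimum buffer for the slow bands (default 120 s).
#' @return named list `ulf`, `vlf`, `lf`, `hf`, `lf_hf`.
#' @export
hrv_freq_features <- function(peak_times_s, rr_ms, min_buffer_s = 120) {
  out <- list(ulf = NA_real_, vlf = NA_real_, lf = NA_real_, hf = NA_real_,
              lf_hf = NA_real_)
  stopifnot(length(peak_times_s) == length(rr_ms))
  if (length(rr_ms) < 8) return(out)
  t <- peak_times_s
  span <- max(t) - min(t)
  if (span < 60) return(out)
  fs <- 4
  grid <- seq(min(t), max(t), by = 1 / fs)
  tach <- approx(t, rr_ms, xout = grid, rule = 2)$y
  spec <- welch_psd(tach, fs, segment_s = min(span, 120), overlap = 0.5,
                    nfft = 4096)
  out$lf <- band_power(spec, 0.04, 0.15)
  out$hf <- band_power(spec, 0.15, 0.4)
  out$lf_hf <- if (out$hf > 0) out$lf / out$hf else NA_real_
  if (span >= min_buffer_s) {
    out$ulf <- band_power(spec, 0, 0.003)
    out$vlf <- band_power(spec, 0.003, 0.04)
  }
  out
}

#' EMG window features
#'
#' Amplitude statistics on the rectified waveform (mean absolute value and its
#' SD), RMS, integrated EMG (`sum |x| * dt`), and Welch-PSD median / mean
#' power frequency.
#'
#' @param x EMG window at native rate (filtered, normalized).
#' @param rate sampling rate, Hz.
#' @return named list `mean`, `std`, `rms`, `iemg`, `mf`, `mpf`.
#' @export
emg_features <- function(x, rate) {
  if (length(x) == 0) {
    return(list(mean = NA_real_, std = NA_real_, rms = NA_real_,
                iemg = NA_real_, mf = NA_real_, mpf = NA_real_))
  }
  ax <- abs(x)
  s <- stat_features(ax)
  out <- list(mean = s$mean, std = s$std, rms = sqrt(mean(x^2)),
              iemg = sum(ax) / rate, mf = NA_real_, mpf = NA_real_)
  if (length(x) >= 16 && any(x != 0)) {
    spec <- welch_psd(x, rate, segment_s = 4, overlap = 0.5)
    out$mf <- median_frequency(spec)
    out$mpf <- mean_power_frequency(spec)
  }
  out
}

#' Respiration window features
#'
#' @param x RESP window (filtered, normalized) at native rate.
#' @param rate sampling rate, Hz.
#' @return named list `mean`, `std`, `freq` (dominant 0.05-1 Hz PSD peak, `NA`
#'   when no peak rises above the noise floor).
#' @export
resp_features <- function(x, rate) {
  if (length(x) == 0) return(list(mean = NA_real_, std = NA_real_, freq = NA_real_))
  s <- stat_features(x)
  freq <- NA_real_
  if (length(x) >= 64) {
    spec <- welch_psd(x, rate, segment_s = min(30, length(x) / rate),
                      nfft = 4096)
    freq <- dominant_frequency(spec, 0.05, 1.0)
  }
  list(mean = s$mean, std = s$std, freq = freq)
}

# value of the 2 Hz stream at the end of a window
ds_value_at <- function(ds, ds_rate, end_s) {
  k <- min(length(ds), max(1, round(end_s * ds_rate)))
  ds[k]
}

#' Fuse all channels into the 28-feature windowed matrix
#'
#' Assembles, for every surviving window of the grid, the 28 canonical
#' features. Instantaneous "value" features are read from the 2 Hz
#' downsampled streams at the window end; HRV/EMG/RESP statistics are computed
#' at native rates. Rows with missing features are kept and flagged via their
#' `NA`s, never silently dropped.
#'
#' @param clean a `pf_clean_set` from [preprocess_recording_set()].
#' @param cfg a [pf_config()] (window geometry and HRV buffer policy).
#' @return a `pf_feature_matrix`.
#' @export
fuse_features <- function(clean, cfg = clean$config) {
  if (is.null(cfg)) cfg <- pf_config()
  duration <- length(clean$channels$ECG) / clean$rates[["ECG"]]
  wins <- make_windows(clean$label_track, duration, cfg$window_s, cfg$step_s,
                       rejected = clean$rejected)
  if (nrow(wins) == 0) stop("no feature windows available")
  beats <- clean$beats
  pt <- beats$r_peak_times_s
  seg_start_of <- function(lab, t_end) {
    segs <- clean$label_track
    cand <- segs[segs$label == lab & segs$start_s < t_end, , drop = FALSE]
    if (nrow(cand) == 0) return(0)
    max(cand$start_s)
  }
  rows <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    s <- wins$start_s[i]
    e <- wins$end_s[i]
    # -- HRV time features: valid RR with both peaks inside the window
    in_win <- which(pt[-1] >= s & pt[-1] < e & pt[-length(pt)] >= s)
    rr_win <- beats$rr_intervals_ms[in_win]
    rr_win <- rr_win[beats$rr_valid[in_win]]
    ht <- hrv_time_features(rr_win)
    # -- HRV spectral features from the rolling in-segment buffer
    buf_start <- max(seg_start_of(wins$label[i], e), e - cfg$hrv_buffer_s)
    in_buf <- which(pt[-1] >= buf_start & pt[-1] < e)
    in_buf <- in_buf[beats$rr_valid[in_buf]]
    hf <- hrv_freq_features(pt[in_buf + 1], beats$rr_intervals_ms[in_buf],
                            min_buffer_s = cfg$hrv_min_buffer_s)
    slice <- function(kind) {
      r <- clean$rates[[kind]]
      clean$channels[[kind]][(floor(s * r) + 1):min(length(clean$channels[[kind]]),
                                                    floor(e * r))]
    }
    gsr <- stat_features(slice("GSR"))
    emg <- emg_features(slice("EMG"), clean$rates[["EMG"]])
    rsp <- resp_features(slice("RESP"), clean$rates[["RESP"]])
    rows[[i]] <- data.frame(
      subject = clean$subject_id, window_start_s = s,
      ecg_value = ds_value_at(clean$ds$ECG, clean$ds_rate, e),
      hr = ht$hr, nn = ht$nn, sdnn = ht$sdnn, sdsd = ht$sdsd,
      rmssd = ht$rmssd, pnn50 = ht$pnn50, pnn20 = ht$pnn20,
      ulf = hf$ulf, vlf = hf$vlf, lf = hf$lf, hf = hf$hf, lf_hf = hf$lf_hf,
      sc_value = ds_value_at(clean$ds$GSR, clean$ds_rate, e),
      sc_mean = gsr$mean, sc_std = gsr$std,
      emg_value = ds_value_at(clean$ds$EMG, clean$ds_rate, e),
      emg_mean = emg$mean, emg_std = emg$std, emg_rms = emg$rms,
      iemg = emg$iemg, emg_mf = emg$mf, emg_mpf = emg$mpf,
      resp_value = ds_value_at(clean$ds$RESP, clean$ds_rate, e),
      resp_mean = rsp$mean, resp_std = rsp$std, resp_freq = rsp$freq,
      skt_value = ds_value_at(clean$ds$SKT, clean$ds_rate, e),
      label = wins$label[i], stringsAsFactors = FALSE)
  }
  feature_matrix(do.call(rbind, rows))
}

#' Fuse a whole preprocessed cohort
#'
#' @param sets list of `pf_recording_set`.
#' @param cfg a [pf_config()].
#' @return a `pf_feature_matrix` covering all subjects.
#' @export
cohort_features <- function(sets, cfg = pf_config()) {
  mats <- lapply(sets, function(s) {
    as.data.frame(fuse_features(preprocess_recording_set(s, cfg), cfg))
  })
  feature_matrix(do.call(rbind, mats))
}
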