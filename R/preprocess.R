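# Preprocessing chain: artifact detection on the native sensor scale, 30-s
# tile rejection, neighborhood-mean imputation, per-subject z-scoring, the
# per-channel filter bank, R-peak detection and downsampling to the common
# 2 Hz clock. See the methods vignette for the ordering rationale.

#' Z-score normalization (population SD)
#'
#' `(x - mean) / sd_pop`; applied per subject and per channel so every channel
#' reaches the feature stage on a comparable scale.
#'
#' @param x numeric vector, length >= 2.
#' @return normalized vector with mean 0 and population SD 1.
#' @export
zscore_normalize <- function(x) {
  stopifnot(length(x) >= 2)
  s <- pop_sd(x)
  if (!is.finite(s) || s == 0) stop("constant signal")
  (x - mean(x)) / s
}

# population standard deviation (1/N)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Percentage-rule artifact detection
#'
#' Flags any sample whose relative change from the previous *accepted* sample
#' exceeds `threshold` (strict `>`). Non-finite samples are flagged as missing.
#' The first finite sample is never flagged; a zero reference makes the next
#' comparison undefined, so that point is flagged.
#'
#' @param x numeric vector (native sensor scale).
#' @param threshold relative-change threshold in (0,1); default 0.20.
#' @return logical mask, `TRUE` = ectopic/missing.
#' @export
detect_ectopic <- function(x, threshold = 0.20) {
  stopifnot(threshold > 0, threshold < 1)
  cpp_detect_ectopic(as.numeric(x), threshold)
}

#' Reject 30-s tiles with too many flagged samples
#'
#' Tiles are anchored at t = 0, non-overlapping, `window_s` long; a tile is
#' removed iff its flagged fraction strictly exceeds `reject_fraction`.
#'
#' @param x numeric samples.
#' @param mask logical flag mask from [detect_ectopic()].
#' @param rate sampling rate, Hz.
#' @param window_s tile length, seconds.
#' @param reject_fraction rejection threshold on the flagged fraction.
#' @return list with `x` (samples outside rejected tiles), `keep` (per-sample
#'   logical), and `rejected` (data.frame of `start_s`, `end_s`).
#' @export
reject_windows <- function(x, mask, rate, window_s = 30,
                           reject_fraction = 0.20) {
  n <- length(x)
  tile <- floor((seq_len(n) - 1) / (rate * window_s))
  flagged <- rowsum(as.numeric(mask), tile)
  sizes <- tabulate(tile + 1L)
  frac <- as.numeric(flagged) / sizes
  bad <- as.numeric(rownames(flagged))[frac > reject_fraction]
  keep <- !(tile %in% bad)
  rejected <- data.frame(start_s = bad * window_s,
                         end_s = (bad + 1) * window_s)
  list(x = x[keep], keep = keep, rejected = rejected)
}

#' Neighborhood-mean imputation of flagged samples
#'
#' Each flagged point is replaced by the mean of the up-to-`w`-wide centered
#' neighborhood, excluding flagged neighbors; the neighborhood shrinks at the
#' boundaries. If every neighbor is flagged, the nearest unflagged value is
#' used.
#'
#' @param x numeric samples.
#' @param mask logical flag mask.
#' @param w odd neighborhood width (default 11).
#' @return numeric vector with all flagged points replaced (finite everywhere
#'   provided at least one unflagged finite sample exists).
#' @export
impute_flagged <- function(x, mask, w = 11) {
  stopifnot(w %% 2 == 1)
  n <- length(x)
  if (!any(mask)) return(x)
  if (all(mask)) stop("cannot impute: all samples flagged")
  h <- (w - 1) %/% 2
  good_idx <- which(!mask)
  out <- x
  for (i in which(mask)) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    nb <- lo:hi
    nb <- nb[!mask[nb]]
    if (length(nb) > 0) {
      out[i] <- mean(x[nb])
    } else {
      nearest <- good_idx[which.min(abs(good_idx - i))]
      out[i] <- x[nearest]
    }
  }
  out
}

#' Default per-channel filter bank
#'
#' Denoise method plus high-pass / band-stop (50 Hz notch) / low-pass cutoffs
#' per channel. Any stage whose cutoff reaches the channel's Nyquist frequency
#' is skipped and logged; the skin-temperature high-pass is additionally
#' skipped as physically implausible for a quasi-DC channel (see vignette).
#'
#' @return named list of per-channel stage settings.
#' @export
default_filter_bank <- function() {
  list(
    ECG = list(denoise = "wavelet", highpass = 1, bandstop = 50, lowpass = 40),
    GSR = list(denoise = "gaussian", highpass = NA, bandstop = 50, lowpass = 5),
    EMG = list(denoise = "wavelet", highpass = 5, bandstop = 50, lowpass = 500),
    RESP = list(denoise = "wavelet", highpass = NA, bandstop = 50, lowpass = 20),
    SKT = list(denoise = "sliding", highpass = 5, bandstop = 50, lowpass = 200))
}

#' Apply the per-channel filter chain
#'
#' Order: denoise, high-pass, 50 Hz band-stop, low-pass. Output length equals
#' input length; the applied/skipped stages are recorded in
#' `attr(out, "filter_log")`.
#'
#' @param x numeric samples (normalized).
#' @param kind channel kind.
#' @param rate sampling rate, Hz.
#' @param bank filter bank (default [default_filter_bank()]).
#' @return filtered samples with a `filter_log` attribute.
#' @export
filter_channel <- function(x, kind, rate, bank = default_filter_bank()) {
  kind <- match.arg(kind, channel_kinds())
  cfg <- bank[[kind]]
  log <- character(0)
  nyq <- rate / 2
  wmode <- if (kind == "EMG") "baseline" else "threshold"
  x <- switch(cfg$denoise,
    wavelet = wavelet_denoise(x, rate, mode = wmode),
    gaussian = gaussian_smooth(x, rate, sigma_s = 0.25),
    sliding = sliding_average(x, rate, width_s = 1),
    x)
  log <- c(log, paste0("denoise:", cfg$denoise,
                       if (cfg$denoise == "wavelet") paste0("-", wmode) else ""))
  apply_stage <- function(x, type, f0, stage_name) {
    if (is.na(f0)) {
      log <<- c(log, paste0(stage_name, ":none"))
      return(x)
    }
    if (f0 >= nyq) {
      log <<- c(log, paste0(stage_name, ":skipped-nyquist(", f0, ">=", nyq, ")"))
      return(x)
    }
    if (kind == "SKT" && type == "highpass") {
      log <<- c(log, paste0(stage_name, ":skipped-implausible-for-SKT"))
      return(x)
    }
    log <<- c(log, paste0(stage_name, ":", f0, "Hz"))
    filtfilt_biquad(biquad(type, f0, rate), x)
  }
  x <- apply_stage(x, "highpass", cfg$highpass, "highpass")
  x <- apply_stage(x, "notch", cfg$bandstop, "bandstop")
  x <- apply_stage(x, "lowpass", cfg$lowpass, "lowpass")
  attr(x, "filter_log") <- log
  x
}

#' R-peak detection (derivative / square / moving-window integration)
#'
#' Pan-Tompkins-family detector on the filtered, normalized ECG: five-point
#' derivative, squaring, 150 ms integration, adaptive amplitude threshold,
#' 250 ms refractory, and peak refinement to the ECG maximum within 100 ms.
#' RR intervals outside the 300-2000 ms physiologic gate are flagged invalid.
#'
#' @param x filtered, normalized ECG samples.
#' @param rate sampling rate, Hz.
#' @return An object of class `pf_beats`: list with `r_peak_times_s`,
#'   `rr_intervals_ms`, and `rr_valid` (physiologic gate mask).
#' @export
detect_r_peaks <- function(x, rate) {
  n <- length(x)
  if (n < rate) {
    return(structure(list(r_peak_times_s = numeric(0),
                          rr_intervals_ms = numeric(0),
                          rr_valid = logical(0)), class = "pf_beats"))
  }
  d <- c(0, 0, diff(x, lag = 4), 0, 0)[seq_len(n)] * rate / 4
  sq <- d * d
  wi <- max(3, round(0.150 * rate))
  integ <- as.numeric(stats::filter(sq, rep(1 / wi, wi), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.2 * quantile(integ, 0.99, names = FALSE)
  if (!is.finite(thr) || thr <= 0) {
    return(structure(list(r_peak_times_s = numeric(0),
                          rr_intervals_ms = numeric(0),
                          rr_valid = logical(0)), class = "pf_beats"))
  }
  above <- integ > thr
  # rising edges of the above-threshold regions
  starts <- which(diff(c(FALSE, above)) == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  half <- round(0.100 * rate)
  peaks <- integer(0)
  for (k in seq_along(starts)) {
    lo <- max(1, starts[k] - half)
    hi <- min(n, ends[k] + half)
    peaks <- c(peaks, lo - 1 + which.max(x[lo:hi]))
  }
  if (length(peaks) > 1) {
    peaks <- sort(unique(peaks))
    refractory <- round(0.250 * rate)
    keep <- rep(TRUE, length(peaks))
    last <- peaks[1]
    for (k in 2:length(peaks)) {
      if (peaks[k] - last < refractory) {
        if (x[peaks[k]] > x[last]) {
          keep[which(peaks == last)] <- FALSE
          last <- peaks[k]
        } else keep[k] <- FALSE
      } else last <- peaks[k]
    }
    peaks <- peaks[keep]
  }
  times <- (peaks - 1) / rate
  rr <- diff(times) * 1000
  structure(list(r_peak_times_s = times, rr_intervals_ms = rr,
                 rr_valid = rr >= 300 & rr <= 2000), class = "pf_beats")
}

#' Downsample by bin averaging
#'
#' Output sample `k` is the mean of all source samples in
#' `[(k-1)/target, k/target)`; works for non-integer rate ratios.
#'
#' @param x numeric samples.
#' @param rate source rate, Hz.
#' @param target_rate_hz target rate (default 2 Hz).
#' @return downsampled vector of length `floor(n / rate * target)`.
#' @export
downsample <- function(x, rate, target_rate_hz = 2) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  n_out <- floor(n / rate * target_rate_hz + 1e-9)
  if (n_out == 0) return(numeric(0))
  bin <- floor((seq_len(n) - 1) / rate * target_rate_hz + 1e-9)
  sel <- bin < n_out
  sums <- rowsum(x[sel], bin[sel])
  counts <- tabulate(bin[sel] + 1L, nbins = n_out)
  as.numeric(sums) / counts
}

#' Run the full preprocessing chain on a labeled recording set
#'
#' Per channel: artifact/missing detection on the native scale (only for the
#' channels in `cfg$ectopic_channels`; missing-value detection always applies),
#' 30-s tile rejection, neighborhood imputation, z-scoring, filter bank. The
#' ECG additionally yields a beat series, and every channel a 2 Hz stream.
#'
#' @param set a [labeled_recording_set()].
#' @param cfg a [pf_config()].
#' @return An object of class `pf_clean_set`: `channels` (filtered native-rate
#'   numeric vectors), `ds` (2 Hz streams), `beats`, `rejected` (union of
#'   rejected tiles across channels), `imputed_counts`, `label_track`,
#'   `subject_id`, `log`.
#' @export
preprocess_recording_set <- function(set, cfg = pf_config()) {
  stopifnot(inherits(set, "pf_recording_set"))
  channels <- list()
  ds <- list()
  rejected_all <- data.frame(start_s = numeric(0), end_s = numeric(0))
  imputed <- integer(0)
  logs <- list()
  for (kind in channel_kinds()) {
    ch <- set$channels[[kind]]
    x <- ch$samples
    if (kind %in% cfg$ectopic_channels) {
      mask <- detect_ectopic(x, cfg$ectopic_threshold)
    } else {
      mask <- !is.finite(x)
    }
    rej <- reject_windows(x, mask, ch$rate, window_s = cfg$window_s,
                          reject_fraction = cfg$window_reject_fraction)
    imputed[kind] <- sum(mask & rej$keep)
    x <- impute_flagged(x, mask, cfg$impute_width)
    x <- zscore_normalize(x)
    x <- filter_channel(x, kind, ch$rate, cfg$filter_bank)
    logs[[kind]] <- c(sprintf("flagged=%d imputed=%d rejected_tiles=%d",
                              sum(mask), imputed[[kind]], nrow(rej$rejected)),
                      attr(x, "filter_log"))
    rejected_all <- rbind(rejected_all, rej$rejected)
    channels[[kind]] <- as.numeric(x)
    ds[[kind]] <- downsample(as.numeric(x), ch$rate, cfg$target_rate_hz)
  }
  rejected_all <- unique(rejected_all)
  rejected_all <- rejected_all[order(rejected_all$start_s), , drop = FALSE]
  beats <- detect_r_peaks(channels$ECG, set$channels$ECG$rate)
  structure(list(subject_id = set$subject_id, channels = channels,
                 rates = vapply(set$channels, function(c) c$rate, numeric(1)),
                 ds = ds, ds_rate = cfg$target_rate_hz, beats = beats,
                 rejected = rejected_all, imputed_counts = imputed,
                 label_track = set$label_track, log = logs, config = cfg),
            class = "pf_clean_set")
}
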