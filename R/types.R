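# Core domain vocabulary: channel kinds, behavior labels, recording containers.

#' Physiological channel kinds and native sampling rates
#'
#' The five wearable channels handled by the pipeline, with the acquisition
#' rates of the recorder they emulate: ECG 512 Hz (chest Ag/AgCl), GSR 64 Hz
#' (palm), EMG 1024 Hz (forearm extensor), RESP 64 Hz (chest strap),
#' SKT 32 Hz (skin thermistor).
#'
#' @return `channel_kinds()`: character vector of the five kinds.
#' @export
channel_kinds <- function() c("ECG", "GSR", "EMG", "RESP", "SKT")

#' @rdname channel_kinds
#' @param kind one of `channel_kinds()`.
#' @return `channel_native_rate()`: sampling rate in Hz.
#' @export
channel_native_rate <- function(kind) {
  rates <- c(ECG = 512, GSR = 64, EMG = 1024, RESP = 64, SKT = 32)
  kind <- match.arg(kind, channel_kinds())
  unname(rates[[kind]])
}

#' Behavior labels and their integer codebook
#'
#' Six maneuvers in the fixed pipeline order; integer codes 0-5 follow this
#' order everywhere (serialization always uses the names, never bare codes).
#'
#' @return `behavior_labels()`: character vector of six labels.
#' @export
behavior_labels <- function() {
  c("takeoff", "level_flight", "turn_and_hover", "roll", "somersault", "stall")
}

#' @rdname behavior_labels
#' @param label character vector of behavior labels.
#' @return `behavior_code()`: integer codes 0-5.
#' @export
behavior_code <- function(label) {
  idx <- match(label, behavior_labels())
  if (anyNA(idx)) {
    stop("unknown behavior: ", paste(label[is.na(idx)], collapse = ", "))
  }
  idx - 1L
}

#' @rdname behavior_labels
#' @param code integer vector of codes 0-5.
#' @return `behavior_from_code()`: character labels.
#' @export
behavior_from_code <- function(code) {
  stopifnot(all(code %in% 0:5))
  behavior_labels()[code + 1L]
}

#' Single-channel recording container
#'
#' @param samples numeric vector of raw sensor samples.
#' @param rate sampling rate in Hz (> 0).
#' @param kind one of [channel_kinds()].
#' @param subject_id subject identifier (coerced to character).
#' @param start_time recording start, seconds (default 0).
#' @return An object of class `pf_channel` with fields `samples`, `rate`,
#'   `kind`, `subject_id`, `start_time`.
#' @export
channel_recording <- function(samples, rate, kind, subject_id = "S1",
                              start_time = 0) {
  kind <- match.arg(kind, channel_kinds())
  stopifnot(is.numeric(samples), length(samples) >= 1, rate > 0)
  structure(
    list(samples = as.numeric(samples), rate = rate, kind = kind,
         subject_id = as.character(subject_id), start_time = start_time),
    class = "pf_channel")
}

#' @export
print.pf_channel <- function(x, ...) {
  cat(sprintf("<pf_channel %s subject=%s rate=%g Hz n=%d dur=%.1f s>\n",
              x$kind, x$subject_id, x$rate, length(x$samples),
              channel_duration(x)))
  invisible(x)
}

#' @rdname channel_recording
#' @param x a `pf_channel`.
#' @return `channel_duration()`: duration in seconds.
#' @export
channel_duration <- function(x) length(x$samples) / x$rate

#' Behavior label track
#'
#' An ordered set of non-overlapping, half-open `[start, end)` segments, each
#' carrying one behavior label.
#'
#' @param start_s,end_s numeric vectors of segment bounds in seconds.
#' @param label character vector of behavior labels.
#' @return An object of class `pf_label_track` (a data.frame).
#' @export
label_track <- function(start_s, end_s, label) {
  stopifnot(length(start_s) == length(end_s), length(end_s) == length(label))
  behavior_code(label)  # validates names
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   label = as.character(label), stringsAsFactors = FALSE)
  df <- df[order(df$start_s), , drop = FALSE]
  if (any(df$end_s <= df$start_s)) stop("invalid label track: empty segment")
  if (nrow(df) > 1 && any(df$start_s[-1] < df$end_s[-nrow(df)])) {
    stop("invalid label track: overlapping segments")
  }
  rownames(df) <- NULL
  class(df) <- c("pf_label_track", "data.frame")
  df
}

#' Look up the label covering the majority of a time interval
#'
#' @param track a [label_track()].
#' @param start_s,end_s interval bounds (seconds, half-open).
#' @return the majority label, or `NA_character_` if less than the full
#'   interval is covered by the track (label gap).
#' @export
majority_label <- function(track, start_s, end_s) {
  cover <- pmax(0, pmin(track$end_s, end_s) - pmax(track$start_s, start_s))
  if (abs(sum(cover) - (end_s - start_s)) > 1e-9) return(NA_character_)
  track$label[which.max(cover)]  # ties: earliest segment wins
}

#' Multi-channel labeled recording for one subject
#'
#' @param channels named list with one [channel_recording()] per channel kind
#'   (all five of [channel_kinds()] must be present).
#' @param track a [label_track()].
#' @param subject_id subject identifier; defaults to the channels' id.
#' @return An object of class `pf_recording_set`.
#' @export
labeled_recording_set <- function(channels, track, subject_id = NULL) {
  missing_k <- setdiff(channel_kinds(), names(channels))
  if (length(missing_k) > 0) {
    stop("incomplete modality set: missing ", paste(missing_k, collapse = ", "))
  }
  channels <- channels[channel_kinds()]
  if (is.null(subject_id)) subject_id <- channels[[1]]$subject_id
  span_end <- max(track$end_s)
  for (ch in channels) {
    if (ch$start_time > min(track$start_s) + 1e-9 ||
        ch$start_time + channel_duration(ch) < span_end - 1e-9) {
      stop("channel ", ch$kind, " does not cover the label track span")
    }
  }
  structure(list(subject_id = as.character(subject_id), channels = channels,
                 label_track = track),
            class = "pf_recording_set")
}

#' @export
print.pf_recording_set <- function(x, ...) {
  cat(sprintf("<pf_recording_set subject=%s, %d channels, %d label segments, %.0f s>\n",
              x$subject_id, length(x$channels), nrow(x$label_track),
              max(x$label_track$end_s)))
  invisible(x)
}

#' Pipeline configuration
#'
#' All tunables of the processing chain in one validated list; defaults are the
#' published protocol values (30 s window / 10 s step, 2 Hz common clock, 20%
#' ectopic threshold, 11-point imputation neighborhood, 20% tile rejection).
#'
#' @param window_s feature window length, seconds.
#' @param step_s feature window step, seconds.
#' @param target_rate_hz common downsampled clock, Hz.
#' @param ectopic_threshold relative-change threshold for artifact flagging.
#' @param impute_width odd neighborhood width for mean imputation.
#' @param window_reject_fraction flagged fraction above which a 30-s tile is
#'   dropped.
#' @param random_seed integer seed recorded in run manifests.
#' @param ectopic_channels channels the percentage artifact rule is applied to
#'   (slowly-varying positive channels by default; see vignette).
#' @param hrv_buffer_s rolling tachogram buffer for spectral HRV, seconds.
#' @param hrv_min_buffer_s minimum buffer for ULF/VLF estimation, seconds.
#' @param ... overrides for individual filter-bank settings (see
#'   [default_filter_bank()]).
#' @return An object of class `pf_config`.
#' @export
pf_config <- function(window_s = 30, step_s = 10, target_rate_hz = 2,
                      ectopic_threshold = 0.20, impute_width = 11,
                      window_reject_fraction = 0.20, random_seed = 1L,
                      ectopic_channels = c("GSR", "RESP", "SKT"),
                      hrv_buffer_s = 300, hrv_min_buffer_s = 120, ...) {
  stopifnot(window_s > step_s, step_s > 0,
            impute_width %% 2 == 1, impute_width > 0,
            ectopic_threshold > 0, ectopic_threshold < 1,
            window_reject_fraction > 0, window_reject_fraction < 1,
            target_rate_hz > 0)
  cfg <- list(window_s = window_s, step_s = step_s,
              target_rate_hz = target_rate_hz,
              ectopic_threshold = ectopic_threshold,
              impute_width = as.integer(impute_width),
              window_reject_fraction = window_reject_fraction,
              random_seed = as.integer(random_seed),
              ectopic_channels = ectopic_channels,
              hrv_buffer_s = hrv_buffer_s,
              hrv_min_buffer_s = hrv_min_buffer_s,
              filter_bank = default_filter_bank())
  extra <- list(...)
  cfg[names(extra)] <- extra
  class(cfg) <- "pf_config"
  cfg
}

#' Hash of a configuration (provenance tag written into run manifests)
#' @param cfg a [pf_config()].
#' @return md5 string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(capture.output(str(unclass(cfg))), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' @importFrom utils capture.output str
NULL
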