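# Delimited-text readers and writers. One CSV per channel with a '#' header
# carrying the channel kind and rate; labels as (start_s, end_s, label); the
# fused feature matrix as TSV. All formats round-trip.

#' Write one channel recording to CSV
#'
#' Format: a comment header `# kind=<KIND> rate=<Hz> subject=<id> start=<s>`
#' followed by `time_s,value` rows.
#'
#' @param ch a [channel_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_channel_csv <- function(ch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s rate=%.10g subject=%s start=%.10g",
                     ch$kind, ch$rate, ch$subject_id, ch$start_time), con)
  writeLines("time_s,value", con)
  t <- ch$start_time + (seq_along(ch$samples) - 1) / ch$rate
  writeLines(paste(formatC(t, format = "g", digits = 12),
                   formatC(ch$samples, format = "g", digits = 12), sep = ","),
             con)
  invisible(path)
}

#' @rdname write_channel_csv
#' @export
read_channel_csv <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#")) stop("missing channel header in ", path)
  kv <- regmatches(header, gregexpr("[a-z]+=[^ ]+", header))[[1]]
  meta <- setNames(sub("^[a-z]+=", "", kv), sub("=.*$", "", kv))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  channel_recording(df$value, rate = as.numeric(meta[["rate"]]),
                    kind = meta[["kind"]], subject_id = meta[["subject"]],
                    start_time = as.numeric(meta[["start"]]))
}

#' Write / read a behavior label track as CSV
#' @param track a [label_track()].
#' @param path file path.
#' @return the path / the track.
#' @export
write_labels_csv <- function(track, path) {
  write.csv(as.data.frame(unclass(track))[c("start_s", "end_s", "label")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  label_track(df$start_s, df$end_s, df$label)
}

#' Write / read a full labeled recording set as a directory of CSV files
#'
#' The directory holds `ecg.csv`, `gsr.csv`, `emg.csv`, `resp.csv`, `skt.csv`
#' and `labels.csv`.
#'
#' @param set a [labeled_recording_set()].
#' @param dir directory (created if absent).
#' @return the directory / the recording set.
#' @export
write_recording_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (kind in channel_kinds()) {
    write_channel_csv(set$channels[[kind]],
                      file.path(dir, paste0(tolower(kind), ".csv")))
  }
  write_labels_csv(set$label_track, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' @rdname write_recording_set
#' @param paths optional named character vector of per-channel file paths
#'   (names = channel kinds); defaults to the standard layout in `dir`.
#' @param labels_path optional labels CSV path.
#' @export
read_recording_set <- function(dir, paths = NULL, labels_path = NULL) {
  if (is.null(paths)) {
    paths <- setNames(file.path(dir, paste0(tolower(channel_kinds()), ".csv")),
                      channel_kinds())
  }
  if (is.null(labels_path)) labels_path <- file.path(dir, "labels.csv")
  missing_k <- names(paths)[!file.exists(paths)]
  if (length(missing_k) > 0 || length(setdiff(channel_kinds(), names(paths)))) {
    stop("incomplete modality set: missing ",
         paste(union(missing_k, setdiff(channel_kinds(), names(paths))),
               collapse = ", "))
  }
  channels <- lapply(paths[channel_kinds()], read_channel_csv)
  names(channels) <- channel_kinds()
  labeled_recording_set(channels, read_labels_csv(labels_path))
}

#' Write / read a fused feature matrix as TSV
#'
#' Columns: `subject`, `window_start_s`, the 28 canonical feature names (see
#' [feature_names()]), `label`. Values survive a round trip to 12 significant
#' digits.
#'
#' @param fm a `pf_feature_matrix` (see [fuse_features()]).
#' @param path output TSV.
#' @return the path / the matrix.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm)
  if (nrow(df) == 0) stop("empty matrix")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) {
    ifelse(is.na(col), "NA", formatC(col, format = "g", digits = 12))
  })
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  feats <- setdiff(names(df), c("subject", "window_start_s", "label"))
  if (!identical(feats, feature_names())) {
    stop("feature matrix columns do not match the canonical feature set")
  }
  df$subject <- as.character(df$subject)
  feature_matrix(df)
}

#' Packaged per-subject difficulty ratings
#'
#' Loads the built-in 14-subject x 6-behavior table of subjective difficulty
#' ratings (integers 1-10) collected after simulator flights.
#'
#' @param path optional override of the packaged CSV.
#' @return An object of class `pf_difficulty`: an integer matrix with subjects
#'   as rows (`"1"`..`"14"`) and [behavior_labels()] as columns.
#' @export
load_difficulty_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "difficulty_ratings.csv",
                        package = "physiofuse", mustWork = TRUE)
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, behavior_labels()])
  rownames(m) <- as.character(df$subject)
  storage.mode(m) <- "integer"
  if (any(m < 1 | m > 10)) stop("difficulty ratings must be in [1,10]")
  class(m) <- c("pf_difficulty", class(m))
  m
}
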