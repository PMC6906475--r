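#' Bundle a synchronized neural + audio recording
#'
#' A recording bundle holds a multichannel broadband voltage trace (channels
#' in rows, microvolts) together with the mono audio captured synchronously
#' at the same sample rate, the convention of wireless multielectrode-array
#' acquisition where audio is logged on an auxiliary analog input.
#'
#' @param neural channel x sample numeric matrix (microvolts).
#' @param audio numeric vector, same number of samples as `neural` columns,
#'   nominally in -1..1.
#' @param fs shared sample rate (samples/s, nominally 30000).
#' @param channel_ids optional character vector of channel labels.
#' @param array_label free-text array label (e.g. "RPB", "CPB").
#' @return An object of class `recording_bundle`.
#' @export
recording_bundle <- function(neural, audio, fs,
                             channel_ids = NULL, array_label = "synthetic") {
  neural <- as.matrix(neural)
  storage.mode(neural) <- "double"
  audio <- as.numeric(audio)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (nrow(neural) < 1L) stop("at least one neural channel is required")
  if (ncol(neural) != length(audio)) {
    stop("neural sample count (", ncol(neural),
         ") must equal audio sample count (", length(audio), ")")
  }
  if (anyNA(neural) || anyNA(audio)) stop("missing values are not allowed")
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%03d", seq_len(nrow(neural)))
  }
  if (length(channel_ids) != nrow(neural)) {
    stop("channel_ids length must match channel count")
  }
  structure(
    list(neural = neural, audio = audio, fs = fs,
         channel_ids = as.character(channel_ids),
         array_label = as.character(array_label)[1]),
    class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf(
    "<recording_bundle> %d channels x %d samples @ %g S/s (%.1f s), array %s\n",
    nrow(x$neural), ncol(x$neural), x$fs, ncol(x$neural) / x$fs,
    x$array_label))
  invisible(x)
}

#' Write a recording bundle to disk
#'
#' The neural trace is stored as flat channel-major 32-bit little-endian
#' floats (`neural.f32`) with a JSON sidecar (`recording.json`) describing
#' its shape, and the audio as a 32-bit float WAV (`audio.wav`) — a simple,
#' language-neutral container.
#'
#' @param bundle A [recording_bundle()].
#' @param path Directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
write_recording <- function(bundle, path) {
  stopifnot(inherits(bundle, "recording_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  con <- file(file.path(path, "neural.f32"), "wb")
  # channel-major: all samples of channel 1, then channel 2, ...
  writeBin(as.numeric(t(bundle$neural)), con, size = 4, endian = "little")
  close(con)
  meta <- list(
    n_channels = nrow(bundle$neural),
    n_samples = ncol(bundle$neural),
    fs = bundle$fs,
    channel_ids = bundle$channel_ids,
    array_label = bundle$array_label)
  jsonlite::write_json(meta, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA)
  write_wav(bundle$audio, bundle$fs, file.path(path, "audio.wav"))
  invisible(path)
}

#' Read a recording bundle written by [write_recording()]
#'
#' @param path Directory containing `neural.f32`, `recording.json`,
#'   `audio.wav`.
#' @return A [recording_bundle()].
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "recording.json"),
                              simplifyVector = TRUE)
  payload <- file.path(path, "neural.f32")
  expected <- as.numeric(meta$n_channels) * as.numeric(meta$n_samples) * 4
  actual <- file.info(payload)$size
  if (is.na(actual) || actual != expected) {
    stop("neural payload size mismatch: expected ", expected,
         " bytes, found ", actual)
  }
  con <- file(payload, "rb")
  flat <- readBin(con, "double", meta$n_channels * meta$n_samples,
                  size = 4, endian = "little")
  close(con)
  neural <- matrix(flat, nrow = meta$n_channels, byrow = TRUE)
  wav <- read_wav(file.path(path, "audio.wav"))
  if (wav$fs != meta$fs) {
    stop("WAV sample rate (", wav$fs, ") does not match sidecar fs (",
         meta$fs, ")")
  }
  if (length(wav$audio) != meta$n_samples) {
    stop("audio length (", length(wav$audio),
         ") does not match sidecar n_samples (", meta$n_samples, ")")
  }
  recording_bundle(neural, wav$audio, meta$fs,
                   channel_ids = meta$channel_ids,
                   array_label = meta$array_label)
}

#' Construct a trial table
#'
#' Labeled sound presentations as half-open, 0-based sample spans
#' `[begin_sample, end_sample)`. Spans must be sorted and non-overlapping.
#' The `keep` flag marks trials accepted for analysis (artifact-contaminated
#' presentations are dropped by setting it to `FALSE`).
#'
#' @param begin_sample,end_sample integer vectors of span bounds (0-based,
#'   half-open).
#' @param label character vector of sound names.
#' @param keep logical vector; defaults to all `TRUE`.
#' @return A `data.frame` of class `trial_table`.
#' @export
trial_table <- function(begin_sample, end_sample, label,
                        keep = rep(TRUE, length(label))) {
  begin_sample <- as.numeric(begin_sample)
  end_sample <- as.numeric(end_sample)
  n <- length(begin_sample)
  if (length(end_sample) != n || length(label) != n || length(keep) != n) {
    stop("all columns must have the same length")
  }
  if (any(begin_sample >= end_sample)) {
    stop("every trial must satisfy begin_sample < end_sample")
  }
  if (n > 1L) {
    o <- order(begin_sample)
    if (any(diff(begin_sample) < 0)) {
      stop("trial spans must be sorted by begin_sample")
    }
    if (any(end_sample[-n] > begin_sample[-1L])) {
      stop("trial spans must not overlap")
    }
  }
  structure(
    data.frame(begin_sample = begin_sample, end_sample = end_sample,
               label = as.character(label), keep = as.logical(keep),
               stringsAsFactors = FALSE),
    class = c("trial_table", "data.frame"))
}

#' Read / write trial tables as TSV
#'
#' Columns: `begin_sample`, `end_sample`, `label`, `keep` (0/1). Rows
#' violating the span invariants are rejected with an error, never silently
#' dropped.
#'
#' @param path TSV file path.
#' @return [read_trials()]: a `trial_table`; [write_trials()]: `path`,
#'   invisibly.
#' @export
read_trials <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("begin_sample", "end_sample", "label", "keep")
  if (!all(need %in% names(df))) {
    stop("trial table must have columns: ", paste(need, collapse = ", "))
  }
  keep <- df$keep
  if (is.character(keep) || is.numeric(keep)) keep <- as.integer(keep) != 0L
  trial_table(df$begin_sample, df$end_sample, df$label, keep)
}

#' @param trials A [trial_table()].
#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "trial_table"))
  out <- data.frame(begin_sample = trials$begin_sample,
                    end_sample = trials$end_sample,
                    label = trials$label,
                    keep = as.integer(trials$keep))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
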