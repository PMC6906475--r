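# Multiunit feature extraction: bandpass filtering, MAD noise estimation,
# negative threshold-crossing detection, binning, channel ranking, and
# centered feature windows.

#' Design the spike-band elliptic filter
#'
#' 2nd-order bandpass elliptic filter used before threshold-based multiunit
#' spike extraction. Passband ripple 0.1 dB and stopband attenuation 40 dB
#' (design constants of this package); applied zero-phase
#' (forward-backward) so crossing times are not latency-shifted.
#'
#' @param low_hz,high_hz Cutoff frequencies; `0 < low_hz < high_hz < fs/2`.
#' @param fs Sample rate.
#' @param ripple_db Passband ripple (dB).
#' @param atten_db Stopband attenuation (dB).
#' @return An object of class `bandpass_filter`.
#' @export
design_bandpass <- function(low_hz, high_hz, fs,
                            ripple_db = 0.1, atten_db = 40) {
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (high_hz >= fs / 2) stop("high_hz must be below the Nyquist frequency")
  ba <- signal::ellip(2, ripple_db, atten_db, c(low_hz, high_hz) / (fs / 2),
                      type = "pass")
  structure(list(b = ba$b, a = ba$a, low_hz = low_hz, high_hz = high_hz,
                 fs = fs, order = 2L,
                 ripple_db = ripple_db, atten_db = atten_db),
            class = "bandpass_filter")
}

#' @export
print.bandpass_filter <- function(x, ...) {
  cat(sprintf("<bandpass_filter> elliptic order %d, %g-%g Hz @ %g S/s\n",
              x$order, x$low_hz, x$high_hz, x$fs))
  invisible(x)
}

#' Apply a bandpass filter zero-phase
#'
#' @param x Numeric vector, or channel x sample matrix (filtered per row).
#' @param filt A [design_bandpass()] filter.
#' @return Filtered signal, same shape as `x`.
#' @export
apply_bandpass <- function(x, filt) {
  stopifnot(inherits(filt, "bandpass_filter"))
  f1 <- function(v) signal::filtfilt(filt$b, filt$a, v)
  if (is.matrix(x)) t(apply(x, 1L, f1)) else f1(x)
}

#' Enumerate the bandpass cutoff grid
#'
#' Cartesian product of low and high cutoffs restricted to `low < high`,
#' sorted lexicographically. With lows 100..1000 (step 100) and highs
#' 1000..10000 (step 1000) this yields the 99 filters of the search grid.
#'
#' @param lows,highs Numeric vectors of candidate cutoffs (Hz).
#' @return data.frame with columns `low_hz`, `high_hz`.
#' @export
enumerate_filter_grid <- function(lows = seq(100, 1000, by = 100),
                                  highs = seq(1000, 10000, by = 1000)) {
  g <- expand.grid(high_hz = sort(highs), low_hz = sort(lows))
  g <- g[g$low_hz < g$high_hz, c("low_hz", "high_hz")]
  g <- g[order(g$low_hz, g$high_hz), ]
  rownames(g) <- NULL
  g
}

#' Robust noise level via median absolute deviation
#'
#' `sigma = median(|x - median(x)|) / 0.6745`, the MAD estimate of the
#' noise standard deviation, used instead of the plain SD to minimize the
#' interference of spikes. Must be estimated on training-set samples only.
#'
#' @param trace Numeric vector (one channel's filtered samples), or a
#'   channel x sample matrix (per-channel estimates).
#' @return Numeric sigma (vector of per-channel sigmas for matrix input).
#' @export
estimate_noise <- function(trace) {
  if (is.matrix(trace)) return(apply(trace, 1L, estimate_noise))
  if (length(trace) == 0L) stop("empty trace")
  stats::median(abs(trace - stats::median(trace))) / 0.6745
}

#' Detect negative threshold crossings
#'
#' The per-channel threshold is `-threshold_factor * sigma`. A crossing is
#' the first sample where the trace passes from above threshold to at or
#' below it; subsequent crossings within the dead time are suppressed.
#'
#' @param trace Numeric vector of filtered samples.
#' @param sigma Noise level for this channel (from [estimate_noise()]).
#' @param threshold_factor Positive scalar (grid values 2, 3, 4, 5).
#' @param fs Sample rate.
#' @param dead_time Minimum separation between crossings, seconds
#'   (default 1 ms).
#' @return Integer vector of 0-based crossing sample indices, strictly
#'   increasing.
#' @export
detect_crossings <- function(trace, sigma, threshold_factor, fs,
                             dead_time = 0.001) {
  if (threshold_factor <= 0) stop("threshold_factor must be > 0")
  if (dead_time <= 0) stop("dead_time must be > 0")
  thr <- -threshold_factor * sigma
  below <- trace <= thr
  n <- length(trace)
  if (n < 2L) return(integer(0))
  # onset: sample i with trace[i] <= thr and trace[i-1] > thr
  onset <- which(below[-1L] & !below[-n]) + 1L
  if (trace[1L] <= thr) onset <- c(1L, onset)
  if (length(onset) == 0L) return(integer(0))
  dead <- max(1L, as.integer(round(dead_time * fs)))
  keep <- logical(length(onset))
  last <- -Inf
  for (i in seq_along(onset)) {
    if (onset[i] - last >= dead) {
      keep[i] <- TRUE
      last <- onset[i]
    }
  }
  as.integer(onset[keep] - 1L)  # 0-based
}

#' Bin crossing times into spike counts
#'
#' Non-overlapping bins aligned with the audio target sampling: bin `b`
#' (0-based) counts crossings with sample index in
#' `[b*hop*fs, (b+1)*hop*fs)`.
#'
#' @param crossings Integer vector of 0-based crossing indices, or a list of
#'   such vectors (one per channel).
#' @param fs Sample rate.
#' @param hop Bin width in seconds; `hop*fs` must be an integer.
#' @param n_frames Number of bins.
#' @return frame x channel integer count matrix (single-channel input gives
#'   one column).
#' @export
bin_counts <- function(crossings, fs, hop, n_frames) {
  hs <- hop_samples(hop, fs)
  if (!is.list(crossings)) crossings <- list(crossings)
  out <- matrix(0L, n_frames, length(crossings))
  for (ch in seq_along(crossings)) {
    b <- crossings[[ch]] %/% hs  # 0-based bin index, half-open bins
    b <- b[b >= 0L & b < n_frames]
    if (length(b)) out[, ch] <- tabulate(b + 1L, nbins = n_frames)
  }
  out
}

#' Rank channels by training-set activity
#'
#' Channels ordered by descending total threshold-crossing count over the
#' training frames; ties broken by ascending channel index. Selecting the
#' top-k channels for any k is taking a prefix of this order.
#'
#' @param train_counts frame x channel count matrix (training frames only).
#' @return Integer vector of channel indices, most active first.
#' @export
rank_channels <- function(train_counts) {
  train_counts <- as.matrix(train_counts)
  if (nrow(train_counts) < 1L) stop("need at least one frame")
  totals <- colSums(train_counts)
  order(-totals, seq_along(totals))
}

#' Build centered feature windows
#'
#' Row `t` concatenates, per channel, the counts at frames
#' `t - span/2 ... t + span/2` (window centered on the current prediction;
#' `span` is the window length excluding the current value, so each channel
#' contributes `span + 1` values). Out-of-range frames contribute zeros.
#'
#' @param counts frame x channel count matrix.
#' @param span Even nonnegative integer (grid values 4, 8, 16).
#' @return frame x (channel * (span+1)) matrix of class `feature_matrix`
#'   with attributes `span` and `n_channels`. Columns are ordered
#'   channel-major: all lags of channel 1, then channel 2, ...
#' @export
window_features <- function(counts, span) {
  counts <- as.matrix(counts)
  if (span %% 2L != 0L || span < 0L) stop("span must be even and >= 0")
  n <- nrow(counts); p <- ncol(counts)
  half <- span %/% 2L
  offs <- (-half):half
  out <- matrix(0, n, p * (span + 1L))
  for (ci in seq_len(p)) {
    for (k in seq_along(offs)) {
      src <- seq_len(n) + offs[k]
      ok <- src >= 1L & src <= n
      col <- (ci - 1L) * (span + 1L) + k
      out[ok, col] <- counts[src[ok], ci]
    }
  }
  structure(out, span = as.integer(span), n_channels = p,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out) && (missing(j) || ncol(out) == ncol(x))) {
    # row subsets keep the window geometry
    attr(out, "span") <- attr(x, "span")
    attr(out, "n_channels") <- attr(x, "n_channels")
    class(out) <- c("feature_matrix", "matrix", "array")
  }
  out
}
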