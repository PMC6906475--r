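# Mel-spectrogram targets and audio reconstruction.
#
# Framing convention throughout: Hann window (periodic), centered frames with
# reflection padding of n_fft/2 on both sides, frame count 1 + floor(n / hop).

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

reflect_pad <- function(x, pad) {
  n <- length(x)
  if (pad >= n) stop("n_fft too large for audio length ", n)
  c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
}

# Complex STFT, chunked over frames to bound memory.
stft_complex <- function(audio, fs, n_fft, hop) {
  hs <- hop_samples(hop, fs)
  n <- length(audio)
  if (n < 2L) stop("audio too short")
  pad <- n_fft %/% 2L
  x <- reflect_pad(audio, pad)
  n_frames <- 1L + n %/% hs
  w <- hann_window(n_fft)
  n_bins <- n_fft %/% 2L + 1L
  out <- matrix(0 + 0i, n_bins, n_frames)
  chunk <- 1024L
  for (start in seq(1L, n_frames, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n_frames)
    idx <- outer(seq_len(n_fft), (cols - 1L) * hs, `+`)
    fr <- matrix(x[idx], n_fft, length(cols)) * w
    ft <- stats::mvfft(fr)
    out[, cols] <- ft[seq_len(n_bins), , drop = FALSE]
  }
  structure(out, fs = fs, hop = hop, n_fft = n_fft)
}

#' Short-time Fourier transform magnitude
#'
#' Hann-windowed, center-padded STFT magnitude with `n_fft/2 + 1` frequency
#' bins and `1 + floor(n/hop)` frames.
#'
#' @param audio Numeric vector.
#' @param fs Sample rate (samples/s).
#' @param n_fft FFT window length in samples (default 2048).
#' @param hop Hop size in seconds; `hop * fs` must be a positive integer.
#' @return bin x frame magnitude matrix with attributes `fs`, `hop`, `n_fft`.
#' @export
stft_magnitude <- function(audio, fs, n_fft = 2048L, hop) {
  s <- stft_complex(audio, fs, n_fft, hop)
  structure(Mod(unclass(s)), fs = fs, hop = hop, n_fft = n_fft)
}

# Inverse STFT via windowed overlap-add with squared-window normalization.
istft <- function(S, fs, n_fft, hop, length_out = NULL) {
  hs <- hop_samples(hop, fs)
  n_bins <- n_fft %/% 2L + 1L
  stopifnot(nrow(S) == n_bins)
  n_frames <- ncol(S)
  # rebuild the full spectrum by conjugate symmetry
  full <- rbind(S, Conj(S[(n_bins - 1L):2, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  w <- hann_window(n_fft)
  total <- n_fft + (n_frames - 1L) * hs
  y <- numeric(total)
  wsum <- numeric(total)
  for (m in seq_len(n_frames)) {
    i <- (m - 1L) * hs + seq_len(n_fft)
    y[i] <- y[i] + frames[, m] * w
    wsum[i] <- wsum[i] + w^2
  }
  y <- y / pmax(wsum, 1e-10)
  pad <- n_fft %/% 2L
  y <- y[(pad + 1L):(total - pad)]
  if (!is.null(length_out)) {
    if (length(y) >= length_out) y <- y[seq_len(length_out)]
    else y <- c(y, numeric(length_out - length(y)))
  }
  y
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters spaced uniformly on the mel scale from 0 Hz to `fs/2`,
#' evaluated on the FFT bin frequencies. With `norm = "area"` each filter is
#' divided by its summed weight so compression does not inflate total energy.
#'
#' @param n_mels Number of mel bands.
#' @param n_fft FFT window length the filterbank applies to.
#' @param fs Sample rate.
#' @param norm `"area"` (default) or `"none"` (peak-normalized triangles).
#' @return n_mels x (n_fft/2 + 1) weight matrix.
#' @export
mel_filterbank <- function(n_mels, n_fft, fs, norm = c("area", "none")) {
  norm <- match.arg(norm)
  if (n_mels < 1L) stop("n_mels must be >= 1")
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * fs / n_fft
  edges <- mel_to_hz(seq(0, hz_to_mel(fs / 2), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (j in seq_len(n_mels)) {
    lo <- edges[j]; ctr <- edges[j + 1L]; hi <- edges[j + 2L]
    up <- (bin_hz - lo) / (ctr - lo)
    down <- (hi - bin_hz) / (hi - ctr)
    fb[j, ] <- pmax(0, pmin(up, down))
    if (norm == "area") {
      s <- sum(fb[j, ])
      if (s > 0) fb[j, ] <- fb[j, ] / s
    }
  }
  fb
}

#' Compress a linear spectrogram onto mel bands
#'
#' Squares the magnitude spectrogram to power and applies the mel
#' filterbank, producing the band x frame target representation used by the
#' decoders.
#'
#' @param spec Magnitude spectrogram from [stft_magnitude()].
#' @param n_mels Number of mel bands (grid values: 32, 64, 128, 256).
#' @param db Optional dB compression of the mel power (default off; targets
#'   are linear mel power).
#' @return An object of class `mel_spec`: list with `values` (band x frame),
#'   `n_mels`, `hop`, `n_fft`, `fs`.
#' @export
mel_compress <- function(spec, n_mels, db = FALSE) {
  fs <- attr(spec, "fs"); hop <- attr(spec, "hop"); n_fft <- attr(spec, "n_fft")
  if (is.null(fs) || is.null(hop) || is.null(n_fft)) {
    stop("spec must carry fs/hop/n_fft attributes (use stft_magnitude)")
  }
  fb <- mel_filterbank(n_mels, n_fft, fs)
  values <- fb %*% (unclass(spec)^2)
  if (db) values <- 10 * log10(pmax(values, 1e-10))
  structure(list(values = values, n_mels = n_mels, hop = hop,
                 n_fft = n_fft, fs = fs, db = db),
            class = "mel_spec")
}

#' @export
print.mel_spec <- function(x, ...) {
  cat(sprintf("<mel_spec> %d bands x %d frames, hop %g ms, n_fft %d, fs %g\n",
              x$n_mels, ncol(x$values), x$hop * 1000, x$n_fft, x$fs))
  invisible(x)
}

#' Zero-mean target standardizer
#'
#' Fits per-band offsets (means over *training* frames only) so decoder
#' targets are zero-mean; validation/test frames are transformed with the
#' training means, never their own.
#'
#' @param train band x frame matrix (or `mel_spec`) of training frames.
#' @return An object of class `target_standardizer`.
#' @export
fit_standardizer <- function(train) {
  if (inherits(train, "mel_spec")) train <- train$values
  train <- as.matrix(train)
  if (ncol(train) < 2L) stop("need at least 2 training frames")
  structure(list(offset = rowMeans(train)), class = "target_standardizer")
}

#' @param x band x frame matrix to transform.
#' @param s A fitted `target_standardizer`.
#' @rdname fit_standardizer
#' @export
apply_standardizer <- function(x, s) {
  if (inherits(x, "mel_spec")) x <- x$values
  stopifnot(inherits(s, "target_standardizer"), nrow(x) == length(s$offset))
  x - s$offset
}

#' @rdname fit_standardizer
#' @export
invert_standardizer <- function(x, s) {
  stopifnot(inherits(s, "target_standardizer"), nrow(x) == length(s$offset))
  x + s$offset
}

#' Invert a mel-spectrogram to a linear power spectrogram
#'
#' Nonnegative pseudo-inverse of the mel filterbank applied per frame:
#' negative input values (as produced by unconstrained decoders) are clipped
#' to zero, the Moore-Penrose pseudo-inverse gives the least-squares frame
#' solution, and negative output bins are clipped to zero (power cannot be
#' negative).
#'
#' @param mel A `mel_spec` (linear power; dB-scaled input is undone first).
#' @return bin x frame nonnegative power spectrogram with `fs`, `hop`,
#'   `n_fft` attributes.
#' @export
mel_invert <- function(mel) {
  stopifnot(inherits(mel, "mel_spec"))
  v <- mel$values
  if (isTRUE(mel$db)) v <- 10^(v / 10)
  v <- pmax(v, 0)
  fb <- mel_filterbank(mel$n_mels, mel$n_fft, mel$fs)
  sv <- svd(fb)
  keep <- sv$d > max(sv$d) * 1e-10
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  out <- pmax(pinv %*% v, 0)
  structure(out, fs = mel$fs, hop = mel$hop, n_fft = mel$n_fft)
}

#' Griffin-Lim phase recovery
#'
#' Recovers a time-domain waveform from a magnitude spectrogram by iterative
#' STFT-consistency projections starting from seeded random phase. The
#' spectral-convergence error is non-increasing across iterations.
#'
#' @param spec Nonnegative magnitude spectrogram (bin x frame) with `fs`,
#'   `hop`, `n_fft` attributes (as from [stft_magnitude()] or
#'   `sqrt(mel_invert(...))` values with attributes preserved).
#' @param n_iter Number of iterations (default 64).
#' @param seed Integer seed for the random phase initialization.
#' @param length_out Optional output length in samples.
#' @return Numeric audio vector; attribute `convergence` holds the
#'   per-iteration spectral error.
#' @export
griffin_lim <- function(spec, n_iter = 64L, seed = NULL, length_out = NULL) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  fs <- attr(spec, "fs"); hop <- attr(spec, "hop"); n_fft <- attr(spec, "n_fft")
  if (is.null(fs) || is.null(hop) || is.null(n_fft)) {
    stop("spec must carry fs/hop/n_fft attributes")
  }
  A <- pmax(unclass(spec), 0)
  with_seed(seed, {
    phase <- matrix(stats::runif(length(A), -pi, pi), nrow(A), ncol(A))
    S <- A * exp(1i * phase)
    err <- numeric(n_iter)
    x <- NULL
    for (it in seq_len(n_iter)) {
      x <- istft(S, fs, n_fft, hop, length_out = length_out)
      Sx <- stft_complex(x, fs, n_fft, hop)
      Sx <- Sx[, seq_len(ncol(A)), drop = FALSE]
      err[it] <- sqrt(sum((Mod(Sx) - A)^2)) / max(sqrt(sum(A^2)), 1e-12)
      S <- A * exp(1i * Arg(Sx))
    }
    x <- istft(S, fs, n_fft, hop, length_out = length_out)
    structure(x, convergence = err)
  })
}

#' Reconstruct audio from (predicted) mel targets
#'
#' Convenience composition used by the pipeline: un-clip, invert the mel
#' filterbank, take the magnitude, and run Griffin-Lim.
#'
#' @inheritParams mel_invert
#' @inheritParams griffin_lim
#' @return Numeric audio vector.
#' @export
mel_to_audio <- function(mel, n_iter = 64L, seed = NULL, length_out = NULL) {
  pw <- mel_invert(mel)
  mag <- structure(sqrt(unclass(pw)), fs = attr(pw, "fs"),
                   hop = attr(pw, "hop"), n_fft = attr(pw, "n_fft"))
  as.numeric(griffin_lim(mag, n_iter = n_iter, seed = seed,
                         length_out = length_out))
}
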