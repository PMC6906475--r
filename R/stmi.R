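# Spectro-temporal modulation index (STMI): degradation of joint
# spectral/temporal modulation content of an auditory (log-frequency)
# spectrogram, measured with a bank of Gaussian modulation filters and
# summarized as 1 - ||T - N||^2 / ||T||^2.

# Log-frequency (constant-Q-style) magnitude spectrogram: triangular
# filters with log2-spaced centers applied to an STFT magnitude.
auditory_spectrogram <- function(audio, fs, n_channels = 128L,
                                 hop = 0.01, n_fft = 1024L,
                                 fmin = 100) {
  fmax <- min(8000, 0.95 * fs / 2)
  mag <- stft_magnitude(audio, fs, n_fft, hop)
  bin_hz <- (seq_len(nrow(mag)) - 1L) * fs / n_fft
  centers <- 2^seq(log2(fmin), log2(fmax), length.out = n_channels)
  edges <- 2^seq(log2(fmin), log2(fmax), length.out = n_channels + 2L)
  E <- matrix(0, n_channels, ncol(mag))
  for (j in seq_len(n_channels)) {
    lo <- edges[j]; ctr <- edges[j + 1L]; hi <- edges[j + 2L]
    w <- pmax(0, pmin((bin_hz - lo) / (ctr - lo), (hi - bin_hz) / (hi - ctr)))
    s <- sum(w)
    if (s > 0) E[j, ] <- (w / s) %*% unclass(mag)
  }
  structure(E, hop = hop,
            delta_oct = (log2(fmax) - log2(fmin)) / (n_channels - 1L))
}

fft_freqs <- function(n, d) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

# Time-averaged modulation content for each (rate, scale) pair: Gaussian
# bandpass along time (rates, Hz) and along the log-frequency axis
# (scales, cycles/octave) applied in the 2-D Fourier domain.
modulation_content <- function(E, rates, scales) {
  hop <- attr(E, "hop")
  delta_oct <- attr(E, "delta_oct")
  C <- nrow(E); Tn <- ncol(E)
  Fc <- stats::mvfft(E)                 # along channels
  F2 <- t(stats::mvfft(t(Fc)))          # then along time
  ft <- abs(fft_freqs(Tn, hop))         # temporal modulation, Hz
  fc <- abs(fft_freqs(C, delta_oct))    # spectral modulation, cyc/oct
  out <- numeric(0)
  for (r in rates) {
    gt <- exp(-(ft - r)^2 / (2 * (r / 2)^2))
    for (s in scales) {
      gs <- exp(-(fc - s)^2 / (2 * (s / 2)^2))
      H <- outer(gs, gt)
      R <- t(stats::mvfft(t(stats::mvfft(F2 * H, inverse = TRUE)),
                          inverse = TRUE)) / (C * Tn)
      out <- c(out, rowMeans(Mod(R)))
    }
  }
  out
}

#' Spectro-temporal modulation index (STMI)
#'
#' Quantifies the joint degradation of spectral and temporal modulations in
#' a reconstruction: both signals are reduced to a 128-channel
#' log-frequency spectrogram, passed through a bank of spectro-temporal
#' modulation filters (rates 2-32 Hz, scales 0.25-8 cyc/oct), time-averaged
#' into template vectors `T` (target) and `N` (reconstruction), and scored
#' as `1 - ||T - N||^2 / ||T||^2`. Identical signals score 1; a silent or
#' doubled reconstruction scores 0.
#'
#' @param target,noisy Equal-length waveforms.
#' @param fs Sample rate.
#' @param rates Temporal modulation centers, Hz.
#' @param scales Spectral modulation centers, cycles/octave.
#' @return Scalar index (<= 1).
#' @export
stmi <- function(target, noisy, fs,
                 rates = c(2, 4, 8, 16, 32),
                 scales = c(0.25, 0.5, 1, 2, 4, 8)) {
  if (length(target) != length(noisy)) stop("length mismatch")
  Tv <- modulation_content(auditory_spectrogram(target, fs), rates, scales)
  if (sum(Tv^2) == 0) stop("silent target")
  Nv <- modulation_content(auditory_spectrogram(noisy, fs), rates, scales)
  1 - sum((Tv - Nv)^2) / sum(Tv^2)
}
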