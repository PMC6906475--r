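# Reconstruction-quality metrics: mel-band correlation, envelope
# correlation, pitch (NCF) and gross pitch error, BS.1770 momentary
# loudness and the loudness factor. ESTOI and STMI live in their own files.

#' Fisher-mean mel-band correlation
#'
#' Pearson correlation per mel band between target and reconstruction,
#' Fisher z-transformed (atanh), averaged across bands, and back-transformed
#' (tanh) — the z-transform imposes additivity on the coefficients so they
#' can be meaningfully averaged. Bands with zero variance in either input
#' are excluded (their count is returned as an attribute).
#'
#' @param y,yhat band x frame matrices (target and reconstruction).
#' @return Scalar mean correlation in -1..1; attributes `band_r`
#'   (per-band correlations) and `n_excluded`.
#' @export
fisher_mean_correlation <- function(y, yhat) {
  if (inherits(y, "mel_spec")) y <- y$values
  if (inherits(yhat, "mel_spec")) yhat <- yhat$values
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  stopifnot(all(dim(y) == dim(yhat)))
  if (ncol(y) < 3L) stop("need at least 3 frames")
  sy <- apply(y, 1L, stats::sd)
  sh <- apply(yhat, 1L, stats::sd)
  ok <- sy > 0 & sh > 0
  if (!any(ok)) stop("all bands have zero variance")
  r <- vapply(which(ok), function(b) stats::cor(y[b, ], yhat[b, ]), 0)
  z <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  structure(tanh(mean(z)), band_r = r, n_excluded = sum(!ok))
}

hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n %/% 2L + 1L] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Temporal envelope of a waveform
#'
#' Magnitude of the analytic signal (Hilbert transform), low-pass filtered
#' at 50 Hz (4th-order Butterworth, applied zero-phase) — the 2-50 Hz
#' envelope band carrying segmental and prosodic speech cues.
#'
#' @param audio Numeric waveform.
#' @param fs Sample rate.
#' @param cutoff Low-pass cutoff, Hz.
#' @return Envelope vector, same length as `audio`.
#' @export
audio_envelope <- function(audio, fs, cutoff = 50) {
  env <- Mod(hilbert_analytic(audio))
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf$b, bf$a, env))
}

#' Envelope correlation between target and reconstruction
#'
#' @param x,y Equal-length waveforms.
#' @inheritParams audio_envelope
#' @return Pearson correlation of the two envelopes.
#' @export
envelope_correlation <- function(x, y, fs) {
  if (length(x) != length(y)) stop("length mismatch")
  stats::cor(audio_envelope(x, fs), audio_envelope(y, fs))
}

#' Pitch tracking by the Normalized Correlation Function
#'
#' Per frame, the lag maximizing the normalized autocorrelation within the
#' F0 search range (with parabolic peak refinement) gives the fundamental;
#' a frame is voiced when the NCF peak is at least `voicing_threshold` and
#' the frame is not silent.
#'
#' @param audio Numeric waveform.
#' @param fs Sample rate.
#' @param f0_range Search range in Hz (default 50-400).
#' @param frame Analysis frame length, seconds (default 40 ms; must cover
#'   two periods of the range minimum).
#' @param hop Frame hop, seconds.
#' @param voicing_threshold NCF peak threshold for voicing (default 0.6).
#' @return Object of class `pitch_track`: list with `f0` (Hz, NA where no
#'   estimate), `voiced` (logical), `ncf_peak`, `hop`.
#' @export
ncf_pitch <- function(audio, fs, f0_range = c(50, 400),
                      frame = 0.04, hop = 0.04, voicing_threshold = 0.6) {
  if (f0_range[2] > fs / 4) stop("f0 range too high for this sample rate")
  L <- round(frame * fs)
  if (L < 2 * fs / f0_range[1]) {
    stop("frame must cover at least two periods of the lowest F0")
  }
  hs <- hop_samples(hop, fs)
  min_lag <- max(2L, floor(fs / f0_range[2]))
  max_lag <- ceiling(fs / f0_range[1])
  n <- length(audio)
  starts <- seq(1L, n - (L + max_lag), by = hs)
  if (length(starts) == 0L) stop("audio too short for one pitch frame")
  nfft <- 2^ceiling(log2(L + max_lag))
  f0 <- rep(NA_real_, length(starts))
  peak <- numeric(length(starts))
  voiced <- logical(length(starts))
  sil_floor <- 1e-6
  for (k in seq_along(starts)) {
    seg <- audio[starts[k]:(starts[k] + L + max_lag - 1L)]
    x1 <- seg[seq_len(L)]
    e0 <- sum(x1^2)
    if (sqrt(e0 / L) < sil_floor) next
    # r[lag] = sum_n x1[n] * seg[n + lag] via FFT cross-correlation
    F1 <- stats::fft(c(x1, numeric(nfft - L)))
    F2 <- stats::fft(c(seg, numeric(nfft - length(seg))))
    cc <- Re(stats::fft(Conj(F1) * F2, inverse = TRUE)) / nfft
    lags <- min_lag:max_lag
    csum <- cumsum(seg^2)
    e_lag <- csum[lags + L] - csum[lags]
    ncf <- cc[lags + 1L] / sqrt(pmax(e0 * e_lag, 1e-24))
    # periodic signals peak at every multiple of the period: take the
    # shortest lag among near-maximal local peaks to avoid octave errors
    cand <- which(ncf >= 0.9 * max(ncf))
    nl <- length(ncf)
    cand <- cand[vapply(cand, function(ii) {
      (ii == 1L || ncf[ii] >= ncf[ii - 1L]) &&
        (ii == nl || ncf[ii] >= ncf[ii + 1L])
    }, TRUE)]
    i <- if (length(cand)) min(cand) else which.max(ncf)
    peak[k] <- ncf[i]
    lag <- lags[i]
    if (i > 1L && i < length(ncf)) {  # parabolic refinement
      a <- ncf[i - 1L]; b <- ncf[i]; cc2 <- ncf[i + 1L]
      den <- a - 2 * b + cc2
      if (abs(den) > 1e-12) lag <- lag + 0.5 * (a - cc2) / den
    }
    f0[k] <- fs / lag
    voiced[k] <- peak[k] >= voicing_threshold
  }
  structure(list(f0 = f0, voiced = voiced, ncf_peak = peak, hop = hop),
            class = "pitch_track")
}

#' Gross pitch error
#'
#' Percentage of target-voiced frames where the relative pitch error
#' exceeds `p` (strict inequality): a frame errs iff
#' `|F0 - F0_hat| > F0 * p`. Frames where the reconstruction has no pitch
#' estimate count as errors.
#'
#' @param f0 Target pitch: a [ncf_pitch()] `pitch_track` or numeric vector
#'   of F0 values.
#' @param f0_hat Reconstruction pitch, same form and length.
#' @param p Relative error threshold (default 0.2).
#' @param voiced Logical vector of target voicing; taken from `f0` when it
#'   is a `pitch_track`.
#' @return GPE in percent (0-100).
#' @export
gross_pitch_error <- function(f0, f0_hat, p = 0.2, voiced = NULL) {
  if (inherits(f0, "pitch_track")) {
    if (is.null(voiced)) voiced <- f0$voiced
    f0 <- f0$f0
  }
  if (inherits(f0_hat, "pitch_track")) f0_hat <- f0_hat$f0
  if (length(f0) != length(f0_hat)) stop("pitch tracks must align")
  if (is.null(voiced)) voiced <- !is.na(f0)
  f0v <- f0[voiced]; fhv <- f0_hat[voiced]
  n <- length(f0v)
  if (n == 0L) stop("no voiced target frames")
  err <- is.na(fhv) | (abs(f0v - fhv) > f0v * p)
  100 * sum(err) / n
}

# BS.1770-4 K-weighting: high-shelf + high-pass biquads designed for an
# arbitrary sample rate from the standard's analog prototypes (tan-prewarped
# bilinear design; reproduces the standard's printed 48 kHz coefficients).
k_weighting_coefs <- function(fs) {
  shelf <- local({
    fc <- 1681.974450955533; G <- 3.999843853973347; Q <- 0.7071752369554196
    K <- tan(pi * fc / fs)
    Vh <- 10^(G / 20)
    Vb <- Vh^0.4996667741545416
    a0 <- 1 + K / Q + K^2
    list(b = c((Vh + Vb * K / Q + K^2) / a0,
               2 * (K^2 - Vh) / a0,
               (Vh - Vb * K / Q + K^2) / a0),
         a = c(1,
               2 * (K^2 - 1) / a0,
               (1 - K / Q + K^2) / a0))
  })
  hp <- local({
    fc <- 38.13547087602444; Q <- 0.5003270373238773
    K <- tan(pi * fc / fs)
    a0 <- 1 + K / Q + K^2
    list(b = c(1, -2, 1),
         a = c(1, 2 * (K^2 - 1) / a0, (1 - K / Q + K^2) / a0))
  })
  list(shelf = shelf, hp = hp)
}

#' Momentary loudness (BS.1770-4 / EBU R 128)
#'
#' K-weighting (high-shelf then high-pass biquads) followed by
#' `-0.691 + 10*log10(mean square)` over 400 ms windows with 75% overlap
#' (100 ms hop). Digital silence is floored at -120 LUFS.
#'
#' @param audio Mono waveform in -1..1 full scale.
#' @param fs Sample rate.
#' @return Numeric vector of momentary loudness values (LUFS; 1 LUFS =
#'   1 dB), attribute `hop` = 0.1 s.
#' @export
momentary_loudness <- function(audio, fs) {
  win <- round(0.4 * fs)
  if (length(audio) < win) stop("audio shorter than one 400 ms window")
  kw <- k_weighting_coefs(fs)
  y <- as.numeric(signal::filter(kw$shelf$b, kw$shelf$a, audio))
  y <- as.numeric(signal::filter(kw$hp$b, kw$hp$a, y))
  hop <- round(0.1 * fs)
  starts <- seq(1L, length(y) - win + 1L, by = hop)
  cs <- c(0, cumsum(y^2))
  msq <- (cs[starts + win] - cs[starts]) / win
  l <- -0.691 + 10 * log10(pmax(msq, 1e-12))
  structure(pmax(l, -120), hop = 0.1)
}

#' Loudness factor
#'
#' Perceptual penalty for a momentary loudness error: `2^(|dl|/10)`, so a
#' 10 dB error doubles (or halves) perceived loudness and scores 2; equal
#' loudness scores 1.
#'
#' @param delta_db Absolute momentary loudness difference(s), dB.
#' @return Factor(s) >= 1.
#' @export
loudness_factor <- function(delta_db) 2^(abs(delta_db) / 10)

#' Mean loudness factor between target and reconstruction
#'
#' @param l,l_hat Aligned momentary loudness series (LUFS), as from
#'   [momentary_loudness()].
#' @return Time-mean loudness factor (>= 1; closer to 1 is better).
#' @export
mean_loudness_factor <- function(l, l_hat) {
  if (length(l) != length(l_hat)) stop("length mismatch")
  mean(loudness_factor(as.numeric(l) - as.numeric(l_hat)))
}

#' Evaluate all six reconstruction metrics
#'
#' @param target_audio,recon_audio Equal-length waveforms.
#' @param fs Sample rate.
#' @param y,yhat Optional band x frame mel matrices for the mel-band
#'   correlation; when omitted, 128-band 40 ms mel-spectrograms are computed
#'   from the two waveforms.
#' @param hop Mel hop used when computing spectrograms internally.
#' @return A one-row data.frame with columns `fisher_mean_r`, `envelope_r`,
#'   `gpe_percent`, `mean_loudness_factor`, `estoi`, `stmi`.
#' @export
metric_report <- function(target_audio, recon_audio, fs,
                          y = NULL, yhat = NULL, hop = 0.04) {
  if (length(target_audio) != length(recon_audio)) stop("length mismatch")
  if (is.null(y) || is.null(yhat)) {
    y <- mel_compress(stft_magnitude(target_audio, fs, 2048L, hop), 128L)
    yhat <- mel_compress(stft_magnitude(recon_audio, fs, 2048L, hop), 128L)
  }
  pt <- ncf_pitch(target_audio, fs)
  pr <- ncf_pitch(recon_audio, fs)
  data.frame(
    fisher_mean_r = as.numeric(fisher_mean_correlation(y, yhat)),
    envelope_r = envelope_correlation(target_audio, recon_audio, fs),
    gpe_percent = gross_pitch_error(pt, pr),
    mean_loudness_factor = mean_loudness_factor(
      momentary_loudness(target_audio, fs),
      momentary_loudness(recon_audio, fs)),
    estoi = estoi(target_audio, recon_audio, fs),
    stmi = stmi(target_audio, recon_audio, fs))
}
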