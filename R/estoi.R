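# Extended short-time objective intelligibility (ESTOI), following the
# reference construction: 10 kHz internal rate, clean-driven silent-frame
# removal with a 40 dB dynamic range, 15 one-third-octave bands from 150 Hz,
# and intermediate scores over 384 ms (30-frame) segments.

estoi_fs <- 10000L
estoi_frame <- 256L
estoi_hop <- 128L
estoi_nfft <- 512L
estoi_seg <- 30L

resample_to <- function(x, fs_from, fs_to) {
  if (fs_from == fs_to) return(x)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(fs_to, fs_from)
  as.numeric(signal::resample(x, fs_to / d, fs_from / d))
}

estoi_frames <- function(x) {
  n <- length(x)
  starts <- seq(1L, n - estoi_frame + 1L, by = estoi_hop)
  w <- hann_window(estoi_frame)
  sapply(starts, function(s) x[s:(s + estoi_frame - 1L)] * w)
}

# Drop frames whose clean-signal energy is > 40 dB below the loudest frame;
# both signals are rebuilt by overlap-add of the retained windowed frames.
remove_silent_frames <- function(clean, noisy, range_db = 40) {
  Fc <- estoi_frames(clean)
  Fn <- estoi_frames(noisy)
  e <- 20 * log10(pmax(sqrt(colSums(Fc^2)), 1e-20))
  keep <- e > max(e) - range_db
  if (!any(keep)) stop("clean signal is entirely silent")
  Fc <- Fc[, keep, drop = FALSE]
  Fn <- Fn[, keep, drop = FALSE]
  n_out <- estoi_frame + (ncol(Fc) - 1L) * estoi_hop
  ola <- function(Fr) {
    y <- numeric(n_out)
    for (m in seq_len(ncol(Fr))) {
      i <- (m - 1L) * estoi_hop + seq_len(estoi_frame)
      y[i] <- y[i] + Fr[, m]
    }
    y
  }
  list(clean = ola(Fc), noisy = ola(Fn))
}

third_octave_bands <- function() {
  cf <- 150 * 2^((0:14) / 3)
  data.frame(lo = cf / 2^(1 / 6), hi = cf * 2^(1 / 6))
}

subband_envelopes <- function(x) {
  Fr <- estoi_frames(x)
  Fr <- rbind(Fr, matrix(0, estoi_nfft - estoi_frame, ncol(Fr)))
  S <- stats::mvfft(Fr)[seq_len(estoi_nfft %/% 2L + 1L), , drop = FALSE]
  P <- Mod(S)^2
  freqs <- (seq_len(nrow(P)) - 1L) * estoi_fs / estoi_nfft
  bands <- third_octave_bands()
  out <- matrix(0, nrow(bands), ncol(P))
  for (j in seq_len(nrow(bands))) {
    sel <- freqs >= bands$lo[j] & freqs < bands$hi[j]
    out[j, ] <- sqrt(colSums(P[sel, , drop = FALSE]))
  }
  out
}

#' Extended short-time objective intelligibility (ESTOI)
#'
#' Estimates the intelligibility of a degraded ("noisy") signal against its
#' clean reference: both are resampled to 10 kHz, silent clean frames are
#' removed (40 dB range), one-third-octave subband envelopes are computed,
#' and for every 384 ms segment the rows and then columns of the
#' envelope matrices are mean/norm-normalized and correlated; the score is
#' the mean over segments of the mean column projection.
#'
#' @param clean,noisy Equal-length waveforms (target, reconstruction).
#' @param fs Their sample rate.
#' @return Scalar score (1 for identical signals; near 0 for unrelated
#'   ones).
#' @export
estoi <- function(clean, noisy, fs) {
  if (length(clean) != length(noisy)) stop("length mismatch")
  clean <- resample_to(clean, fs, estoi_fs)
  noisy <- resample_to(noisy, fs, estoi_fs)
  if (length(clean) < round(0.384 * estoi_fs) + estoi_frame) {
    stop("need at least 384 ms of audio")
  }
  sig <- remove_silent_frames(clean, noisy)
  X <- subband_envelopes(sig$clean)
  Y <- subband_envelopes(sig$noisy)
  M <- ncol(X)
  if (M < estoi_seg) stop("fewer than 30 non-silent frames")
  eps <- 1e-20
  norm2 <- function(v) sqrt(sum(v^2))
  d <- numeric(M - estoi_seg + 1L)
  for (m in seq_along(d)) {
    cols <- m:(m + estoi_seg - 1L)
    Xs <- X[, cols, drop = FALSE]
    Ys <- Y[, cols, drop = FALSE]
    rn <- function(A) {
      A <- A - rowMeans(A)
      A / pmax(apply(A, 1L, norm2), eps)
    }
    cn <- function(A) {
      A <- sweep(A, 2L, colMeans(A))
      sweep(A, 2L, pmax(apply(A, 2L, norm2), eps), `/`)
    }
    Xn <- cn(rn(Xs))
    Yn <- cn(rn(Ys))
    d[m] <- sum(Xn * Yn) / estoi_seg
  }
  mean(d)
}
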