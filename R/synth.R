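# Synthetic sessions: word-like audio tokens and audio-driven broadband
# neural traces with a known spectrotemporal encoding, so the whole decoding
# pipeline is testable without animal recordings.

#' Specify a word-like audio token
#'
#' Tokens are harmonic (voiced) sounds with a fixed fundamental and a small
#' set of formant-like resonances whose centers sweep linearly over the
#' token, emulating computer-synthesized words of different lengths and
#' distinct spectral content.
#'
#' @param name Token label.
#' @param duration Seconds (> 0).
#' @param f0 Fundamental frequency, Hz.
#' @param formant_tracks List of length-2 numeric vectors `c(start_hz,
#'   end_hz)`; one resonance per element.
#' @param attack,decay Amplitude envelope ramp times, seconds.
#' @return An object of class `token_spec`.
#' @export
token_spec <- function(name, duration, f0, formant_tracks,
                       attack = 0.03, decay = 0.08) {
  if (duration <= 0) stop("duration must be > 0")
  if (f0 <= 0) stop("f0 must be > 0")
  stopifnot(is.list(formant_tracks), length(formant_tracks) >= 1L)
  structure(list(name = as.character(name), duration = duration, f0 = f0,
                 formant_tracks = lapply(formant_tracks, as.numeric),
                 attack = attack, decay = decay),
            class = "token_spec")
}

#' Default three-token vocabulary
#'
#' Three word-like tokens of different durations occupying disjoint formant
#' regions (low / mid / high), so their mel-spectrograms are clearly
#' distinct.
#'
#' @return List of [token_spec()] objects.
#' @export
default_vocabulary <- function() {
  list(
    token_spec("lowa",  0.35, 120, list(c(300, 500),  c(900, 700))),
    token_spec("midu",  0.45, 150, list(c(1300, 1900), c(2600, 2100))),
    token_spec("highe", 0.55, 185, list(c(3200, 4300), c(5400, 6200)))
  )
}

#' Synthesize one token waveform
#'
#' Additive harmonic synthesis: harmonics of `f0` with time-varying
#' amplitudes given by Gaussian formant envelopes evaluated at each
#' harmonic frequency, plus a small seeded aspiration-noise floor, shaped by
#' an attack/decay envelope and RMS-normalized to 0.1. Deterministic given
#' the seed.
#'
#' @param spec A [token_spec()].
#' @param fs Sample rate.
#' @param seed Integer seed (harmonic phases and aspiration noise).
#' @return Numeric waveform of `round(duration * fs)` samples.
#' @export
synth_token_audio <- function(spec, fs, seed = 1L) {
  stopifnot(inherits(spec, "token_spec"))
  for (tr in spec$formant_tracks) {
    if (any(tr >= fs / 2)) stop("formant center at or above Nyquist")
  }
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  u <- t / spec$duration  # 0..1 position in token
  with_seed(seed, {
    n_harm <- max(1L, floor(0.45 * fs / spec$f0))
    n_harm <- min(n_harm, 120L)
    phases <- stats::runif(n_harm, -pi, pi)
    x <- numeric(n)
    for (k in seq_len(n_harm)) {
      fk <- k * spec$f0
      amp <- rep(1e-3, n)  # broadband floor
      for (tr in spec$formant_tracks) {
        ctr <- tr[1] + (tr[2] - tr[1]) * u
        bw <- pmax(60, 0.06 * ctr)
        amp <- amp + exp(-(fk - ctr)^2 / (2 * bw^2))
      }
      x <- x + amp * sin(2 * pi * fk * t + phases[k])
    }
    x <- x + 0.02 * stats::rnorm(n)  # aspiration
    env <- pmin(1, t / max(spec$attack, 1e-4),
                (spec$duration - t) / max(spec$decay, 1e-4))
    x <- x * pmax(env, 0)
    x / max(sqrt(mean(x^2)), 1e-12) * 0.1
  })
}

#' Specify a synthetic session
#'
#' A session plays every vocabulary token `reps_per_token` times in seeded
#' pseudorandom order at `iti`-second intervals (the passive-listening
#' protocol: each sound presented 40-60 times, pseudorandomly interleaved,
#' at roughly 1 s intervals).
#'
#' @param vocabulary List of [token_spec()]s.
#' @param reps_per_token Repetitions of each token (default 40).
#' @param iti Inter-token silence, seconds (> 0, default 1).
#' @param fs Sample rate (default 30000).
#' @param seed Integer seed for the presentation order.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(vocabulary = default_vocabulary(),
                         reps_per_token = 40L, iti = 1.0,
                         fs = 30000, seed = 1L) {
  stopifnot(length(vocabulary) >= 1L,
            all(vapply(vocabulary, inherits, TRUE, "token_spec")))
  if (iti <= 0) stop("iti must be > 0")
  if (reps_per_token < 1L) stop("reps_per_token must be >= 1")
  structure(list(vocabulary = vocabulary,
                 reps_per_token = as.integer(reps_per_token),
                 iti = iti, fs = fs, seed = as.integer(seed)),
            class = "session_spec")
}

#' Build the session audio and trial table
#'
#' Token waveforms (synthesized once per token, reused across repetitions)
#' are concatenated in seeded pseudorandom order separated by `iti` seconds
#' of silence; the trial table spans exactly cover each token and all trials
#' are marked keep = TRUE.
#'
#' @param spec A [session_spec()].
#' @return List with `audio` (numeric vector) and `trials`
#'   ([trial_table()]).
#' @export
build_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  waves <- lapply(seq_along(spec$vocabulary), function(i) {
    synth_token_audio(spec$vocabulary[[i]], spec$fs, seed = spec$seed + i)
  })
  labels <- vapply(spec$vocabulary, `[[`, "", "name")
  order_idx <- with_seed(spec$seed,
    sample(rep(seq_along(spec$vocabulary), spec$reps_per_token)))
  gap <- numeric(round(spec$iti * spec$fs))
  pieces <- vector("list", 2L * length(order_idx) + 1L)
  pieces[[1L]] <- gap
  begin <- numeric(length(order_idx))
  end <- numeric(length(order_idx))
  cursor <- length(gap)
  for (i in seq_along(order_idx)) {
    w <- waves[[order_idx[i]]]
    begin[i] <- cursor
    end[i] <- cursor + length(w)
    pieces[[2L * i]] <- w
    pieces[[2L * i + 1L]] <- gap
    cursor <- cursor + length(w) + length(gap)
  }
  list(audio = unlist(pieces),
       trials = trial_table(begin, end, labels[order_idx]))
}

#' Sample a synthetic spectrotemporal encoding model
#'
#' Each informative channel gets a smooth spectrotemporal receptive field
#' (STRF): an excitatory Gaussian bump plus a weaker inhibitory bump at a
#' different band/lag, localized in both mel band and lag. Non-informative
#' channels have a zero STRF and fire only at baseline. Firing is
#' half-wave-rectified, so a low (or zero) baseline makes the audio-to-rate
#' mapping strongly nonlinear, while a high baseline keeps it close to
#' linear.
#'
#' @param n_channels Number of channels.
#' @param n_mels Mel bands of the encoding feature space (default 32).
#' @param n_lags STRF lag count on the encoding hop grid (default 5).
#' @param informative_fraction Fraction of channels with nonzero STRF.
#' @param seed Integer seed.
#' @param gain Scalar rate gain, spikes/s per unit normalized mel power.
#' @param baseline Baseline firing rate, spikes/s (per-channel scalar).
#' @param noise_sd Additive noise SD, microvolts.
#' @param pink_fraction Fraction of noise variance from pink (1/f) noise.
#' @param spike_amp Spike-trough amplitude, microvolts (waveform peak is
#'   negative, extracellular convention).
#' @return An object of class `encoding_model` with fields `strf`
#'   (channel x band x lag), `baseline`, `gain`, `waveform`, `noise_sd`,
#'   `pink_fraction`, `seed`.
#' @export
sample_encoding_model <- function(n_channels, n_mels = 32L, n_lags = 5L,
                                  informative_fraction = 0.75, seed = 1L,
                                  gain = 60, baseline = 10, noise_sd = 10,
                                  pink_fraction = 0.5, spike_amp = 80) {
  stopifnot(n_channels >= 1L, n_mels >= 1L, n_lags >= 1L)
  if (any(baseline < 0)) stop("baseline must be >= 0")
  strf <- array(0, c(n_channels, n_mels, n_lags))
  n_inf <- round(informative_fraction * n_channels)
  with_seed(seed, {
    if (n_inf > 0L) {
      for (c_i in seq_len(n_inf)) {
        # excitatory bump: spread channel tuning across the mel axis
        b0 <- 1 + (n_mels - 1) * ((c_i - 0.5) / n_inf) +
          stats::rnorm(1, 0, n_mels / 20)
        l0 <- stats::runif(1, 1, min(n_lags, 2.5))
        sb <- stats::runif(1, n_mels / 12, n_mels / 6)
        sl <- stats::runif(1, 0.6, 1.2)
        bump <- outer(seq_len(n_mels), seq_len(n_lags), function(b, l) {
          exp(-(b - b0)^2 / (2 * sb^2) - (l - l0)^2 / (2 * sl^2))
        })
        bump <- bump / sqrt(sum(bump^2))
        # weaker inhibitory sidelobe at a shifted band
        b1 <- ((b0 + n_mels / 2 - 1) %% n_mels) + 1
        side <- outer(seq_len(n_mels), seq_len(n_lags), function(b, l) {
          exp(-(b - b1)^2 / (2 * sb^2) - (l - l0)^2 / (2 * sl^2))
        })
        side <- side / sqrt(sum(side^2))
        strf[c_i, , ] <- bump - 0.6 * side
      }
    }
    waveform <- local({
      tt <- seq(0, 1.2e-3, by = 1 / 30000)
      w <- -exp(-(tt - 3e-4)^2 / (2 * (1.2e-4)^2)) +
        0.35 * exp(-(tt - 7e-4)^2 / (2 * (2.2e-4)^2))
      w / max(abs(w)) * spike_amp * -sign(min(w)) * 1  # trough = -spike_amp
    })
  })
  structure(list(strf = strf,
                 baseline = rep_len(baseline, n_channels),
                 gain = gain, waveform = waveform,
                 noise_sd = noise_sd, pink_fraction = pink_fraction,
                 seed = as.integer(seed)),
            class = "encoding_model")
}

# Pink (1/f) noise of unit SD via the standard pole-zero shaping filter.
pink_noise <- function(n) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  x <- as.numeric(signal::filter(b, a, stats::rnorm(n + 2000L)))
  x <- x[-seq_len(2000L)]  # drop filter warm-up
  x / max(stats::sd(x), 1e-12)
}

#' Generate a broadband neural trace driven by audio
#'
#' Per channel, the firing rate on the encoding hop grid is
#' `rectify(baseline + gain * sum(strf * melpower(t - lag)))`, held
#' piecewise-constant within each hop; spike times are drawn from an
#' inhomogeneous Poisson process at full `fs` resolution, each spike adds
#' the biphasic waveform template, and Gaussian-plus-pink noise at
#' `noise_sd` microvolts is added. Mel power is normalized by its session
#' RMS so `gain` is in interpretable units. Deterministic given
#' `model$seed`.
#'
#' @param audio Numeric waveform.
#' @param fs Sample rate.
#' @param model An [sample_encoding_model()] object.
#' @param hop Encoding hop, seconds (integer number of samples; default
#'   0.01).
#' @param n_fft FFT length for the encoding mel analysis (default 1024).
#' @return A [recording_bundle()] with the audio stored unmodified.
#' @export
encode_neural <- function(audio, fs, model, hop = 0.01, n_fft = 1024L) {
  stopifnot(inherits(model, "encoding_model"), length(audio) > 0L)
  hs <- hop_samples(hop, fs)
  n <- length(audio)
  n_mels <- dim(model$strf)[2]
  n_lags <- dim(model$strf)[3]
  n_ch <- dim(model$strf)[1]

  M <- mel_compress(stft_magnitude(audio, fs, n_fft, hop), n_mels)$values
  M <- M / max(sqrt(mean(M^2)), 1e-12)
  n_rate <- max(1L, n %/% hs)
  # drive[c, t] = sum over bands/lags of strf * lagged mel power
  drive <- matrix(0, n_ch, n_rate)
  for (l in seq_len(n_lags)) {
    Wl <- matrix(model$strf[, , l], n_ch, n_mels)
    src <- seq_len(n_rate) - (l - 1L)
    ok <- src >= 1L
    drive[, ok] <- drive[, ok] + Wl %*% M[, src[ok], drop = FALSE]
  }
  rate <- pmax(model$baseline + model$gain * drive, 0)

  wf <- model$waveform
  nw <- length(wf)
  with_seed(model$seed, {
    neural <- matrix(0, n_ch, n)
    for (c_i in seq_len(n_ch)) {
      lam <- rate[c_i, ] * hs / fs
      counts <- stats::rpois(n_rate, lam)
      tot <- sum(counts)
      if (tot > 0L) {
        bins <- rep.int(seq_len(n_rate) - 1L, counts)
        pos <- bins * hs + floor(stats::runif(tot) * hs) + 1L
        tr <- numeric(n + nw)
        for (s in pos) tr[s:(s + nw - 1L)] <- tr[s:(s + nw - 1L)] + wf
        neural[c_i, ] <- tr[seq_len(n)]
      }
      if (model$noise_sd > 0) {
        pf <- model$pink_fraction
        nz <- sqrt(1 - pf) * stats::rnorm(n)
        if (pf > 0) nz <- nz + sqrt(pf) * pink_noise(n)
        neural[c_i, ] <- neural[c_i, ] + model$noise_sd * nz
      }
    }
    recording_bundle(neural, audio, fs)
  })
}

#' Generate a complete synthetic session
#'
#' Convenience wrapper: builds the session audio and trial table, then the
#' encoded neural traces. The default configuration is a desk-scale session
#' of 16 channels and 3 tokens x 40 repetitions at 1 s intervals
#' (~2.5 minutes of 30 kS/s data).
#'
#' @param session A [session_spec()].
#' @param model An [sample_encoding_model()]; defaults to a 16-channel model
#'   seeded from the session seed.
#' @param hop Encoding hop for [encode_neural()].
#' @return List with `bundle`, `trials`, `model`, `session`.
#' @export
synth_session <- function(session = session_spec(),
                          model = NULL, hop = 0.01) {
  stopifnot(inherits(session, "session_spec"))
  if (is.null(model)) {
    model <- sample_encoding_model(16L, seed = session$seed + 1000L)
  }
  built <- build_session(session)
  bundle <- encode_neural(built$audio, session$fs, model, hop = hop)
  list(bundle = bundle, trials = built$trials, model = model,
       session = session)
}
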