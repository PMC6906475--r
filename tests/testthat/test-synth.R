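fs <- 30000

test_that("token synthesis is deterministic with the expected length", {
  spec <- token_spec("t", 0.5, 150, list(c(800, 1200)))
  a1 <- synth_token_audio(spec, fs, seed = 3)
  a2 <- synth_token_audio(spec, fs, seed = 3)
  expect_identical(a1, a2)
  expect_length(a1, 15000L)
  expect_false(identical(a1, synth_token_audio(spec, fs, seed = 4)))
  bad <- token_spec("x", 0.2, 150, list(c(16000, 16000)))
  expect_error(synth_token_audio(bad, fs), "Nyquist")
})

test_that("tokens with disjoint formant bands are spectrally distinct", {
  v <- default_vocabulary()
  mel_of <- function(tok) {
    mel_compress(stft_magnitude(synth_token_audio(tok, fs, 1), fs,
                                2048L, 0.01), 64L)$values
  }
  m1 <- mel_of(v[[1L]]); m3 <- mel_of(v[[3L]])
  n <- min(ncol(m1), ncol(m3))
  r <- stats::cor(as.vector(m1[, seq_len(n)]), as.vector(m3[, seq_len(n)]))
  expect_lt(abs(r), 0.5)
})

test_that("session assembly covers tokens exactly in seeded random order", {
  ses <- session_spec(reps_per_token = 40L, iti = 0.2, seed = 7L)
  built <- build_session(ses)
  tt <- built$trials
  expect_equal(nrow(tt), 120L)
  expect_true(all(table(tt$label) == 40L))
  expect_true(all(tt$keep))
  expect_true(all(diff(tt$begin_sample) > 0))
  expect_true(all(tt$end_sample[-120L] <= tt$begin_sample[-1L]))
  # spans exactly cover each token's samples
  durs <- vapply(ses$vocabulary, function(s) round(s$duration * fs), 0)
  names(durs) <- vapply(ses$vocabulary, `[[`, "", "name")
  expect_equal(tt$end_sample - tt$begin_sample, unname(durs[tt$label]))

  built2 <- build_session(session_spec(reps_per_token = 40L, iti = 0.2,
                                       seed = 8L))
  expect_false(identical(built2$trials$label, tt$label))
  expect_equal(sort(built2$trials$label), sort(tt$label))
})

test_that("encoding models respect the informative fraction and seed", {
  m0 <- sample_encoding_model(8L, informative_fraction = 0, seed = 1L)
  expect_true(all(m0$strf == 0))
  m1 <- sample_encoding_model(16L, informative_fraction = 1, seed = 1L)
  norms <- apply(m1$strf, 1L, function(s) sqrt(sum(s^2)))
  expect_true(all(norms > 0))
  m2 <- sample_encoding_model(16L, informative_fraction = 1, seed = 2L)
  expect_false(identical(m1$strf, m2$strf))
  expect_lt(min(m1$waveform), 0)  # trough-negative extracellular template
  expect_equal(min(m1$waveform), -80)
})

test_that("encoded traces are deterministic and silent models carry no signal", {
  tok <- synth_token_audio(default_vocabulary()[[1L]], fs, 1L)
  aud <- rep(c(tok, numeric(3000L)), 5L)
  model <- sample_encoding_model(2L, seed = 5L, gain = 60, baseline = 10,
                                 noise_sd = 10)
  b1 <- encode_neural(aud, fs, model)
  b2 <- encode_neural(aud, fs, model)
  expect_identical(b1$neural, b2$neural)
  expect_identical(b1$audio, aud)

  # zero gain, nonzero baseline: crossing counts uncorrelated with audio
  m0 <- sample_encoding_model(1L, seed = 6L, gain = 0, baseline = 25,
                              noise_sd = 8)
  long <- rep(c(tok, numeric(3000L)), 40L)
  b0 <- encode_neural(long, fs, m0)
  sig <- estimate_noise(b0$neural[1L, ])
  cr <- detect_crossings(b0$neural[1L, ], sig, 4, fs)
  nb <- length(long) %/% 600L
  counts <- bin_counts(cr, fs, 0.02, nb)[, 1L]
  rms <- sqrt(colMeans(matrix(long[seq_len(nb * 600L)]^2, 600L)))
  expect_gt(nb, 500L)
  expect_lt(abs(stats::cor(counts, rms)), 0.1)
})

test_that("constant-rate spiking matches Poisson expectations", {
  # 10 spikes/s baseline, zero STRF, no noise, 100 s of silence
  model <- sample_encoding_model(1L, seed = 9L, informative_fraction = 0,
                                 gain = 0, baseline = 10, noise_sd = 0)
  b <- encode_neural(numeric(100L * fs), fs, model)
  sig <- 2  # arbitrary; trough is -80 uV, threshold -8 uV catches all
  n_spikes <- length(detect_crossings(b$neural[1L, ], sig, 4, fs))
  expect_lt(abs(n_spikes - 1000), 3 * sqrt(1000))
})

test_that("noise channels rank below informative channels at equal baselines", {
  ses <- session_spec(reps_per_token = 4L, iti = 0.3, seed = 21L)
  model <- sample_encoding_model(8L, seed = 121L, informative_fraction = 0.5,
                                 gain = 60, baseline = 10, noise_sd = 10)
  ss <- synth_session(ses, model)
  filt <- design_bandpass(500, 3000, ss$bundle$fs)
  nf <- apply_bandpass(ss$bundle$neural, filt)
  sig <- estimate_noise(nf)
  cr <- lapply(1:8, function(ch) {
    detect_crossings(nf[ch, ], sig[ch], 4, ss$bundle$fs)
  })
  counts <- bin_counts(cr, ss$bundle$fs, 0.04, ncol(nf) %/% 1200L)
  rk <- rank_channels(counts)
  expect_setequal(rk[1:4], 1:4)   # informative channels are 1..4
})

test_that("hop must divide the sample grid", {
  model <- sample_encoding_model(1L, seed = 1L)
  expect_error(encode_neural(numeric(3000L), fs, model, hop = 1 / 7000),
               "hop")
})
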