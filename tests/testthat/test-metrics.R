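fs <- 30000

test_that("fisher-mean correlation matches its closed forms", {
  set.seed(1)
  Y <- matrix(stats::rnorm(5 * 100), 5)
  expect_equal(as.numeric(fisher_mean_correlation(Y, Y)), 1,
               tolerance = 1e-5)
  # two bands with r = 0 and r = 0.8 -> tanh(atanh(0.8)/2) = 0.5
  n <- 2000
  b1 <- stats::rnorm(n)
  e <- stats::rnorm(n)
  b2 <- 0.8 * scale(b1)[, 1] + sqrt(1 - 0.64) * scale(e)[, 1]
  Y2 <- rbind(b1, b1)
  Yh <- rbind(stats::rnorm(n), b2)
  r <- as.numeric(fisher_mean_correlation(Y2, Yh))
  r1 <- stats::cor(Y2[1, ], Yh[1, ]); r2 <- stats::cor(Y2[2, ], Yh[2, ])
  expect_equal(r, tanh((atanh(r1) + atanh(r2)) / 2), tolerance = 1e-10)
  expect_equal(tanh(atanh(0.8) / 2), 0.5, tolerance = 1e-12)
  # permutation over bands and symmetry in arguments
  perm <- c(3, 1, 4, 2, 5)
  Yp <- Y + matrix(stats::rnorm(500, sd = .5), 5)
  expect_equal(as.numeric(fisher_mean_correlation(Y, Yp)),
               as.numeric(fisher_mean_correlation(Y[perm, ], Yp[perm, ])))
  expect_equal(as.numeric(fisher_mean_correlation(Y, Yp)),
               as.numeric(fisher_mean_correlation(Yp, Y)))
  # zero-variance bands are excluded, all-zero errors
  Yz <- Y; Yz[1, ] <- 7
  expect_equal(attr(fisher_mean_correlation(Yz, Yp), "n_excluded"), 1L)
  expect_error(fisher_mean_correlation(matrix(1, 2, 10), matrix(1, 2, 10)),
               "zero variance")
})

test_that("envelope extraction tracks amplitude modulation", {
  t <- (0:(fs * 2 - 1)) / fs
  mod <- 1 + 0.8 * sin(2 * pi * 4 * t)
  am <- mod * sin(2 * pi * 1000 * t)
  expect_gte(stats::cor(audio_envelope(am, fs), mod), 0.99)
  expect_equal(envelope_correlation(am, am, fs), 1)
  expect_equal(envelope_correlation(am, 0.5 * am, fs), 1, tolerance = 1e-9)
  expect_error(envelope_correlation(am, am[-1], fs), "length")
})

test_that("NCF pitch finds tones, rejects noise, stays silent on silence", {
  t <- (0:(fs * 2 - 1)) / fs
  pt <- ncf_pitch(sin(2 * pi * 200 * t), fs)
  expect_true(all(abs(pt$f0[pt$voiced] - 200) <= 2))
  expect_true(mean(pt$voiced) > 0.9)
  set.seed(2)
  pn <- ncf_pitch(stats::rnorm(length(t)) * 0.1, fs)
  expect_lt(mean(pn$voiced), 0.2)
  ps <- ncf_pitch(numeric(fs), fs)
  expect_false(any(ps$voiced))
  expect_error(ncf_pitch(sin(2 * pi * 200 * t), fs, f0_range = c(50, 10000)),
               "f0 range")
})

test_that("gross pitch error implements the strict 20% rule", {
  v <- rep(TRUE, 4)
  expect_equal(gross_pitch_error(rep(100, 4), rep(100, 4), voiced = v), 0)
  expect_equal(gross_pitch_error(c(100, 100, 100, 100),
                                 c(100, 130, 100, 100), voiced = v), 25)
  expect_equal(gross_pitch_error(100, 120, voiced = TRUE), 0)   # exactly 20%
  expect_equal(gross_pitch_error(100, 120.01, voiced = TRUE), 100)
  expect_error(gross_pitch_error(100, 100, voiced = FALSE), "voiced")
})

test_that("momentary loudness matches the BS.1770 reference tone", {
  x <- sin(2 * pi * 997 * (0:(fs * 2 - 1)) / fs)
  l <- momentary_loudness(x, fs)
  expect_lt(abs(mean(l) - (-3.01)), 0.1)
  l_half <- momentary_loudness(0.5 * x, fs)
  expect_equal(l_half - l, rep(-6.0206, length(l)), tolerance = 1e-3,
               ignore_attr = TRUE)
  ls <- momentary_loudness(numeric(fs), fs)
  expect_true(all(ls == -120))
  expect_error(momentary_loudness(numeric(100), fs), "400 ms")
})

test_that("loudness factor doubles per 10 dB and averages correctly", {
  expect_equal(loudness_factor(10), 2)
  expect_equal(loudness_factor(-10), 2)
  expect_equal(loudness_factor(0), 1)
  expect_equal(mean_loudness_factor(rep(-20, 6), rep(-20, 6)), 1)
  expect_equal(mean_loudness_factor(rep(-10, 6), rep(-20, 6)), 2)
  expect_equal(mean_loudness_factor(rep(0, 6), rep(-20, 6)), 4)
  expect_error(mean_loudness_factor(1:3, 1:4), "length")
})

test_that("estoi scores identity, degrades with noise, ignores unrelated noise", {
  aud <- token_audio()
  expect_equal(estoi(aud, aud, fs), 1, tolerance = 1e-6)
  set.seed(3)
  scores <- vapply(c(20, 10, 0, -10), function(snr) {
    nz <- stats::rnorm(length(aud)) * sqrt(mean(aud^2)) / 10^(snr / 20)
    estoi(aud, aud + nz, fs)
  }, 0)
  expect_true(all(diff(scores) < 0))
  expect_lt(abs(estoi(aud, stats::rnorm(length(aud)) * 0.05, fs)), 0.1)
  expect_error(estoi(aud, aud[-1], fs), "length")
})

test_that("stmi follows its closed-form degradation identities", {
  aud <- token_audio()
  expect_equal(stmi(aud, aud, fs), 1)
  expect_equal(stmi(aud, numeric(length(aud)), fs), 0, tolerance = 1e-9)
  expect_equal(stmi(aud, 2 * aud, fs), 0, tolerance = 1e-9)
  expect_error(stmi(numeric(length(aud)), aud, fs), "silent target")
})

test_that("all six metrics degrade monotonically under growing corruption", {
  aud <- token_audio()
  set.seed(4)
  noise <- stats::rnorm(length(aud))
  levels <- c(0, 0.2, 1, 4) * sqrt(mean(aud^2))
  reports <- lapply(levels, function(s) {
    metric_report(aud, aud + s * noise, fs)
  })
  get <- function(col) vapply(reports, `[[`, 0, col)
  tol <- 1e-6
  expect_true(all(diff(get("fisher_mean_r")) <= tol))
  expect_true(all(diff(get("envelope_r")) <= tol))
  expect_true(all(diff(get("gpe_percent")) >= -tol))
  expect_true(all(diff(get("estoi")) <= tol))
  expect_true(all(diff(get("stmi")) <= tol))
  expect_true(all(diff(get("mean_loudness_factor")) >= -0.02))
})
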