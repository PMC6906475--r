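fs <- 30000

test_that("bandpass design validates cutoffs and attenuates out-of-band tones", {
  f <- design_bandpass(500, 3000, fs)
  expect_s3_class(f, "bandpass_filter")
  expect_error(design_bandpass(1000, 1000, fs), "low_hz < high_hz")
  expect_error(design_bandpass(500, 20000, fs), "Nyquist")

  t <- (0:(fs / 2)) / fs
  amp <- function(hz) {
    y <- apply_bandpass(sin(2 * pi * hz * t), f)
    sqrt(mean(y[5000:10000]^2))
  }
  mid <- amp(sqrt(500 * 3000))     # ~1225 Hz, in band
  expect_gt(20 * log10(mid / amp(125)), 10)
  expect_gt(20 * log10(mid / amp(6000)), 10)
})

test_that("filter grid enumeration matches a brute-force double loop", {
  g <- enumerate_filter_grid()
  expect_equal(nrow(g), 99L)
  expect_equal(nrow(enumerate_filter_grid(100, 1000)), 1L)
  lows <- c(200, 400, 800); highs <- c(300, 800, 1600)
  g2 <- enumerate_filter_grid(lows, highs)
  oracle <- NULL
  for (lo in sort(lows)) for (hi in sort(highs)) {
    if (lo < hi) oracle <- rbind(oracle, data.frame(low_hz = lo, high_hz = hi))
  }
  expect_equal(g2, oracle)
})

test_that("MAD noise estimate is consistent and spike-robust", {
  expect_equal(estimate_noise(rep(2, 500)), 0)
  set.seed(10)
  x <- stats::rnorm(300000)
  expect_lt(abs(estimate_noise(x) - 1), 0.01)
  spiky <- x
  spiky[sample(length(x), 3000)] <- -50   # 1% outliers
  expect_lt(abs(estimate_noise(spiky) - 1) / 1, 0.05)
  expect_gt(stats::sd(spiky), 3)
  expect_error(estimate_noise(numeric(0)), "empty")
})

brute_crossings <- function(trace, thr, dead) {
  out <- integer(0)
  last <- -Inf
  for (i in seq_along(trace)) {
    below <- trace[i] <= thr
    prev_above <- if (i == 1L) TRUE else trace[i - 1L] > thr
    if (below && prev_above && (i - last) >= dead) {
      out <- c(out, i - 1L)
      last <- i
    }
  }
  out
}

test_that("crossing detection matches the hand-evaluated examples", {
  tr <- c(0, 0, -60, -60, 0, 0)
  expect_equal(detect_crossings(tr, 10, 5, fs), 2L)
  expect_equal(detect_crossings(numeric(100), 1, 4, fs), integer(0))
  # two dips 0.5 ms apart with 1 ms dead time -> one crossing
  tr2 <- numeric(100)
  tr2[10] <- -100; tr2[25] <- -100   # 15 samples = 0.5 ms
  expect_length(detect_crossings(tr2, 10, 4, fs, dead_time = 0.001), 1L)
  expect_length(detect_crossings(tr2, 10, 4, fs, dead_time = 0.0004), 2L)
  expect_error(detect_crossings(tr2, 10, 0, fs), "threshold_factor")
  expect_error(detect_crossings(tr2, 10, 4, fs, dead_time = 0), "dead_time")
})

test_that("crossing detection agrees with the brute-force scan", {
  set.seed(20)
  for (i in 1:25) {
    tr <- stats::rnorm(400)
    tr[sample(400, 12)] <- -stats::runif(12, 3, 8)
    sig <- 1
    fast <- detect_crossings(tr, sig, 3, fs, dead_time = 0.0005)
    slow <- brute_crossings(tr, -3, 15L)
    expect_identical(fast, as.integer(slow))
  }
})

test_that("binning uses half-open hop-aligned windows and conserves counts", {
  b <- bin_counts(c(10L, 50L, 1300L), fs, 0.04, 3L)
  expect_equal(b[, 1L], c(2L, 1L, 0L))
  expect_equal(bin_counts(1200L, fs, 0.04, 2L)[, 1L], c(0L, 1L))
  expect_true(all(bin_counts(integer(0), fs, 0.04, 5L) == 0L))
  set.seed(3)
  cr <- sort(sample(0:47999, 200))
  expect_equal(sum(bin_counts(cr, fs, 0.04, 40L)), 200L)
})

test_that("channel ranking is by descending activity with index tie-breaks", {
  counts <- rbind(c(5, 100, 7), c(0, 0, 0))
  expect_equal(rank_channels(counts), c(2L, 3L, 1L))
  expect_equal(rank_channels(matrix(1, 4, 3)), 1:3)
  # top-k is a prefix of the full order
  set.seed(4)
  m <- matrix(stats::rpois(50 * 96, 2), 50, 96)
  full <- rank_channels(m)
  for (k in c(2, 4, 8, 16, 32, 64, 96)) {
    expect_equal(full[seq_len(k)], rank_channels(m)[seq_len(k)])
  }
})

test_that("feature windows are centered, zero-padded, and nested across spans", {
  counts <- matrix(1:20, 10, 2)
  f0 <- window_features(counts, 0L)
  expect_equal(unclass(f0), unclass(counts), ignore_attr = TRUE)
  f4 <- window_features(counts, 4L)
  expect_equal(ncol(f4), 2L * 5L)
  expect_equal(unname(f4[1L, 1:2]), c(0, 0))     # leading zeros per channel
  expect_equal(unname(f4[1L, 3:5]), c(1, 2, 3))
  expect_error(window_features(counts, 3L), "even")
  # span-4 columns appear among span-8 columns at aligned offsets
  f8 <- window_features(counts, 8L)
  sel <- as.vector(vapply(0:1, function(ch) ch * 9L + 3:7, integer(5)))
  expect_equal(unclass(f8)[, sel], unclass(f4), ignore_attr = TRUE)
  # row subsets keep geometry
  sub <- f4[2:6, ]
  expect_equal(attr(sub, "span"), 4L)
  expect_equal(attr(sub, "n_channels"), 2L)
})
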