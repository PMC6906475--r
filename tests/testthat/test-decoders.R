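fisher_r <- function(y, p) as.numeric(fisher_mean_correlation(t(y), t(p)))

test_that("wiener filter solves exact linear problems and matches normal equations", {
  set.seed(7)
  X <- matrix(stats::rnorm(200 * 5), 200)
  W <- matrix(stats::rnorm(5 * 3), 5)
  Y <- X %*% W + 2
  w <- speech_decoder(X, Y, "wiener")
  expect_lt(max(abs(predict(w, X) - Y)), 1e-8)
  expect_equal(fisher_r(Y, predict(w, X)), 1, tolerance = 1e-6)

  X10 <- matrix(stats::rnorm(10 * 3), 10)
  Y10 <- matrix(stats::rnorm(10 * 2), 10)
  w10 <- speech_decoder(X10, Y10, "wiener")
  D <- cbind(1, X10)
  B_oracle <- solve(t(D) %*% D, t(D) %*% Y10)
  expect_equal(unname(coef(w10)), unname(B_oracle), tolerance = 1e-10)

  # degenerate constant column is handled, not fatal
  Xc <- cbind(X10, 1)
  expect_silent(speech_decoder(Xc, Y10, "wiener"))
})

test_that("wiener filter finds nothing in independent noise", {
  set.seed(8)
  X <- matrix(stats::rnorm(600 * 4), 600)
  Y <- matrix(stats::rnorm(600 * 3), 600)
  w <- speech_decoder(X[1:500, ], Y[1:500, ], "wiener")
  r <- fisher_r(Y[501:600, ], predict(w, X[501:600, ]))
  expect_lt(abs(r), 0.15)
})

test_that("wiener cascade captures static nonlinearities the filter cannot", {
  set.seed(9)
  X <- matrix(stats::rnorm(300 * 5), 300)
  wv <- stats::rnorm(5)
  Y <- cbind((X %*% wv + 2)^2)
  tr <- 1:200; ho <- 201:300
  cs <- speech_decoder(X[tr, ], Y[tr, , drop = FALSE], "wiener_cascade",
                       degree = 2)
  wl <- speech_decoder(X[tr, ], Y[tr, , drop = FALSE], "wiener")
  r_cs <- stats::cor(predict(cs, X[ho, ])[, 1L], Y[ho, ])
  r_wl <- stats::cor(predict(wl, X[ho, ])[, 1L], Y[ho, ])
  expect_gte(r_cs, 0.95)
  expect_lt(r_wl, r_cs - 0.05)
  # degree-1 cascade is the plain filter
  d1 <- speech_decoder(X, Y, "wiener_cascade", degree = 1)
  expect_lt(max(abs(predict(d1, X) - predict(speech_decoder(X, Y, "wiener"),
                                             X))), 1e-8)
  for (dg in c(2, 3, 4, 5)) {
    expect_s3_class(speech_decoder(X[tr, ], Y[tr, , drop = FALSE],
                                   "wiener_cascade", degree = dg),
                    "speech_decoder")
  }
  expect_error(speech_decoder(X, Y, "wiener_cascade", degree = 0), "degree")
})

test_that("kalman filter beats persistence on a known state-space model", {
  set.seed(10)
  A <- matrix(c(.95, .05, -.05, .95), 2)
  H <- matrix(stats::rnorm(8), 4, 2)
  z <- matrix(0, 500, 2)
  for (t in 2:500) z[t, ] <- A %*% z[t - 1, ] + stats::rnorm(2, 0, .3)
  # observation noise well below process noise: the filtered state must
  # then beat even the oracle persistence baseline (true previous state)
  obs <- z %*% t(H) + matrix(stats::rnorm(2000, 0, .1), 500)
  for (C in c(0.1, 1, 10)) {
    kf <- speech_decoder(window_features(obs[1:400, ], 0L), z[1:400, ],
                         "kalman", C = C)
    pr <- predict(kf, obs[401:500, ])
    mse_k <- mean((pr[-1, ] - z[402:500, ])^2)
    mse_p <- mean((z[401:499, ] - z[402:500, ])^2)
    expect_lt(mse_k, mse_p)
  }
  # constant targets with noiseless observations converge to the constant
  Yc <- matrix(3, 100, 2)
  Xc <- Yc %*% t(matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE))
  kf <- speech_decoder(window_features(Xc, 0L), Yc, "kalman")
  expect_equal(unname(predict(kf, Xc)[100, ]), c(3, 3), tolerance = 1e-3)
  # single-bin features are required
  expect_error(speech_decoder(window_features(obs, 4L), z, "kalman"),
               "single input")
})

test_that("network gradients match numerical differentiation", {
  ns <- asNamespace("spikespeech")
  set.seed(42)
  for (arch in c("dense", "rnn", "gru", "lstm")) {
    N <- 4L; n_in <- 5L; units <- 6L; n_out <- 2L
    params <- ns$nn_init(arch, n_in, units, n_out)
    X <- if (arch == "dense") matrix(stats::rnorm(N * n_in), N) else
      lapply(1:3, function(t) matrix(stats::rnorm(N * n_in), N))
    Y <- matrix(stats::rnorm(N * n_out), N)
    fw <- ns$nn_forward(params, X, arch, cache = TRUE)
    dY <- 2 * (fw$Yhat - Y) / length(Y)
    g <- ns$nn_backward(params, X, arch, fw, dY)
    loss <- function(p) mean((ns$nn_forward(p, X, arch) - Y)^2)
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(4L, length(params[[nm]])))) {
        eps <- 1e-6
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (loss(p1) - loss(p2)) / (2 * eps)
        expect_lt(abs(num - g[[nm]][i]) /
                    max(1e-6, abs(num) + abs(g[[nm]][i])), 1e-4)
      }
    }
  }
})

test_that("network training is seeded-deterministic and obeys patience", {
  set.seed(11)
  X <- matrix(stats::rnorm(200 * 6), 200)
  Y <- pmax(X %*% matrix(stats::rnorm(6 * 2), 6), 0)
  colX <- window_features(X, 0L)
  fit1 <- speech_decoder(colX[1:160, ], Y[1:160, ], "dense_nn", units = 16L,
                         validation = list(x = colX[161:200, ],
                                           y = Y[161:200, ]),
                         max_epochs = 60L, seed = 3L)
  fit2 <- speech_decoder(colX[1:160, ], Y[1:160, ], "dense_nn", units = 16L,
                         validation = list(x = colX[161:200, ],
                                           y = Y[161:200, ]),
                         max_epochs = 60L, seed = 3L)
  expect_identical(predict(fit1, colX), predict(fit2, colX))
  # early stopping: training ends exactly patience epochs after the best one
  log <- fit1$fit$log
  if (fit1$fit$n_epochs < 60L) {
    expect_equal(fit1$fit$n_epochs, fit1$fit$best_epoch + 5L)
  }
  expect_lte(fit1$fit$n_epochs, 2048L)
  expect_error(speech_decoder(colX, Y, "dense_nn", units = 0L), "units")
})

test_that("recurrent decoders consume windowed sequences and predict finitely", {
  set.seed(12)
  counts <- matrix(stats::rpois(300 * 4, 2), 300)
  Xw <- window_features(counts, 4L)
  Y <- matrix(stats::rnorm(300 * 3), 300)
  for (alg in c("simple_rnn", "gru_rnn", "lstm_rnn")) {
    fit <- speech_decoder(Xw[1:240, ], Y[1:240, ], alg, units = 8L,
                          validation = list(x = Xw[241:300, ],
                                            y = Y[241:300, ]),
                          max_epochs = 8L, seed = 1L)
    p <- predict(fit, Xw)
    expect_equal(dim(p), c(300L, 3L))
    expect_true(all(is.finite(p)))
    expect_identical(p, predict(fit, Xw))  # deterministic across calls
  }
  # plain matrices without window geometry are rejected for recurrent nets
  expect_error(speech_decoder(counts, Y, "lstm_rnn"), "feature_matrix")
})

test_that("decoders are invariant to target offsets after standardization", {
  set.seed(13)
  X <- matrix(stats::rnorm(150 * 4), 150)
  Y <- X %*% matrix(stats::rnorm(4 * 2), 4)
  shift <- Y + 100
  s1 <- fit_standardizer(t(Y[1:100, ]))
  s2 <- fit_standardizer(t(shift[1:100, ]))
  y1 <- t(apply_standardizer(t(Y), s1))
  y2 <- t(apply_standardizer(t(shift), s2))
  w1 <- speech_decoder(X[1:100, ], y1[1:100, ], "wiener")
  w2 <- speech_decoder(X[1:100, ], y2[1:100, ], "wiener")
  expect_equal(predict(w1, X), predict(w2, X), tolerance = 1e-8)
})

test_that("decoder objects expose the standard modelling interface", {
  set.seed(14)
  X <- matrix(stats::rnorm(60 * 3), 60)
  Y <- X %*% matrix(1:6, 3) + 1
  w <- speech_decoder(X, Y, "wiener")
  expect_output(print(w), "speech_decoder: wiener")
  expect_output(print(summary(w)), "train MSE")
  expect_equal(dim(fitted(w)), dim(Y))
  expect_lt(max(abs(residuals(w, Y))), 1e-8)
  expect_error(predict(w, X[, 1:2]), "features")
})
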