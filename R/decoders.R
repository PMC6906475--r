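#' Fit a neural decoder mapping spike-count features to mel-band targets
#'
#' One fitting front-end for the seven decoder families: `kalman`, `wiener`,
#' `wiener_cascade`, `dense_nn`, `simple_rnn`, `gru_rnn` and `lstm_rnn`.
#' Features are windowed multiunit spike counts (rows = frames); targets are
#' standardized mel-spectrogram frames (rows = frames, columns = bands).
#' Recurrent networks consume each feature row as a `span+1`-step sequence
#' of per-channel counts; the dense network and the linear decoders consume
#' the row flattened; the Kalman filter requires single-bin features
#' (`span = 0`).
#'
#' Networks have a single hidden layer (`units`), linear output, no dropout;
#' ReLU hidden activations for `dense_nn`/`simple_rnn` and tanh gates for
#' `gru_rnn`/`lstm_rnn`; trained by Adam (`dense_nn`) or RMSprop (recurrent)
#' at learning rate 1e-3 with minibatches of 128, early stopping on
#' validation MSE with a maximum of 2048 epochs and a patience of 5 epochs,
#' restoring the best-epoch parameters.
#'
#' @param x Feature matrix (frames x features), ideally a
#'   [window_features()] `feature_matrix` carrying `span`/`n_channels`
#'   attributes (required for recurrent networks).
#' @param y Target matrix (frames x mel bands), standardized to zero mean.
#' @param algorithm Decoder family.
#' @param validation Optional list `list(x = , y = )` of validation frames
#'   used for early stopping; if omitted, the trailing 10% of the training
#'   frames is held out for monitoring (network decoders only).
#' @param units Hidden units for network decoders (grid values 256, 512,
#'   1024, 2048; smaller values are allowed).
#' @param degree Polynomial degree for the Wiener cascade (grid 2, 3, 4, 5).
#' @param C Kalman transition-noise scale (grid 0.1, 1, 10); multiplies the
#'   fitted transition-noise covariance.
#' @param max_epochs,patience,batch,lr Network training controls.
#' @param seed Integer seed for network initialization and batching; a given
#'   data + seed pair reproduces identical fits.
#' @return An object of class `speech_decoder` with `predict`, `print`,
#'   `summary`, `coef`, `fitted` and `residuals` methods.
#' @export
speech_decoder <- function(x, y,
                           algorithm = c("wiener", "wiener_cascade",
                                         "kalman", "dense_nn", "simple_rnn",
                                         "gru_rnn", "lstm_rnn"),
                           validation = NULL,
                           units = 256L, degree = 2L, C = 1,
                           max_epochs = 2048L, patience = 5L,
                           batch = 128L, lr = 1e-3, seed = 1L) {
  algorithm <- match.arg(algorithm)
  X <- unclass(as.matrix(x)); storage.mode(X) <- "double"
  Y <- as.matrix(y); storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) stop("x and y must have the same number of rows")
  span <- attr(x, "span")
  n_channels <- attr(x, "n_channels")
  fit <- switch(algorithm,
    wiener = fit_wiener_ols(X, Y),
    wiener_cascade = fit_wiener_cascade_ols(X, Y, degree),
    kalman = {
      if (!is.null(span) && span != 0L) {
        stop("the Kalman filter processes a single input at a time; ",
             "use span = 0 features")
      }
      fit_kalman_ss(X, Y, C)
    },
    {
      arch <- switch(algorithm, dense_nn = "dense", simple_rnn = "rnn",
                     gru_rnn = "gru", lstm_rnn = "lstm")
      if (arch != "dense") {
        if (is.null(span) || is.null(n_channels)) {
          stop("recurrent decoders need a feature_matrix with span/",
               "n_channels attributes (see window_features)")
        }
      }
      if (units < 1L) stop("units must be >= 1")
      prep <- function(M) {
        if (arch == "dense") M
        else features_to_sequence(M, span, n_channels)
      }
      if (is.null(validation)) {
        n <- nrow(X)
        n_val <- max(2L, floor(0.1 * n))
        vi <- (n - n_val + 1L):n
        Xv <- X[vi, , drop = FALSE]; Yv <- Y[vi, , drop = FALSE]
        Xt <- X[-vi, , drop = FALSE]; Yt <- Y[-vi, , drop = FALSE]
      } else {
        Xt <- X; Yt <- Y
        Xv <- unclass(as.matrix(validation$x))
        Yv <- as.matrix(validation$y)
        if (nrow(Xv) < 1L) stop("empty validation set")
      }
      # internal feature/target scaling (undone at predict time): networks
      # train poorly on raw count scales and wide mel-power ranges
      xm <- colMeans(Xt)
      xs <- pmax(apply(Xt, 2L, stats::sd), 1e-8)
      ym <- colMeans(Yt)
      ys <- pmax(apply(Yt, 2L, stats::sd), 1e-8)  # per-band scale: equalizes
      # band weighting in the MSE loss (high-power bands otherwise dominate)
      scale_x <- function(M) sweep(sweep(M, 2L, xm), 2L, xs, `/`)
      scale_y <- function(M) sweep(sweep(M, 2L, ym), 2L, ys, `/`)
      res <- nn_train(arch, prep(scale_x(Xt)), scale_y(Yt),
                      prep(scale_x(Xv)), scale_y(Yv), units = units,
                      max_epochs = max_epochs, patience = patience,
                      batch = batch, lr = lr,
                      optimizer = if (arch == "dense") "adam" else "rmsprop",
                      seed = seed)
      c(res, list(arch = arch,
                  xm = xm, xs = xs, ym = ym, ys = ys))
    })
  obj <- structure(
    list(algorithm = algorithm, fit = fit,
         n_features = ncol(X), n_bands = ncol(Y),
         span = span, n_channels = n_channels,
         units = if (grepl("nn$", algorithm)) units else NULL,
         degree = if (algorithm == "wiener_cascade") degree else NULL,
         C = if (algorithm == "kalman") C else NULL,
         seed = seed, call = match.call()),
    class = "speech_decoder")
  obj$fitted <- predict(obj, X)
  obj$train_mse <- mse(obj$fitted, Y)
  obj
}

# ---- Wiener filter: per-band ordinary least squares with intercept ----

ols_coef <- function(X1, Y) {
  qr_x <- qr(X1)
  B <- qr.coef(qr_x, Y)
  B[is.na(B)] <- 0  # rank-deficient columns contribute nothing
  B
}

fit_wiener_ols <- function(X, Y) {
  B <- ols_coef(cbind(1, X), Y)
  list(B = B)
}

# ---- Wiener cascade: linear stage + per-band static polynomial ----

fit_wiener_cascade_ols <- function(X, Y, degree) {
  if (degree < 1L) stop("degree must be >= 1")
  B <- ols_coef(cbind(1, X), Y)
  U <- cbind(1, X) %*% B  # linear-stage outputs, one column per band
  P <- matrix(0, degree + 1L, ncol(Y))
  for (j in seq_len(ncol(Y))) {
    u <- U[, j]
    D <- outer(u, 0:degree, `^`)
    cj <- tryCatch(ols_coef(D, Y[, j, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(cj)) cj <- c(mean(Y[, j]), rep(0, degree))
    P[, j] <- cj
  }
  list(B = B, P = P, degree = degree)
}

# ---- Kalman filter: linear-Gaussian state space over target frames ----
# State = target vector; A, W from consecutive target pairs; H, Q from
# regressing features on targets; C scales W. No intercepts, matching the
# reference decoding-library convention (targets are zero-mean).

fit_kalman_ss <- function(X, Y, C) {
  n <- nrow(Y)
  if (n < 3L) stop("need at least 3 frames to fit the state-space model")
  Y1 <- Y[-n, , drop = FALSE]
  Y2 <- Y[-1L, , drop = FALSE]
  A <- t(ols_coef(Y1, Y2))           # y_t ~ A y_{t-1}
  Wres <- Y2 - Y1 %*% t(A)
  W <- crossprod(Wres) / (n - 1L)
  H <- t(ols_coef(Y, X))             # x_t ~ H y_t
  Qres <- X - Y %*% t(H)
  Q <- crossprod(Qres) / n
  # scale-aware regularization: keep the filter responsive when the fitted
  # noise covariances degenerate (constant targets / noiseless features),
  # with process noise dominating so observations stay trusted
  w_ridge <- 1e-6 * mean(Y^2) + 1e-12
  q_ridge <- 1e-10 * mean(X^2) + 1e-15
  list(A = A, W = C * W + diag(w_ridge, ncol(Y)),
       H = H, Q = Q + diag(q_ridge, ncol(X)))
}

kalman_predict <- function(fit, X) {
  A <- fit$A; W <- fit$W; H <- fit$H; Q <- fit$Q
  m <- nrow(A); n <- nrow(X)
  ridge <- diag(1e-15 * (1 + mean(diag(Q))), nrow(Q))
  x <- numeric(m)
  P <- W
  out <- matrix(0, n, m)
  for (t in seq_len(n)) {
    xp <- A %*% x
    Pp <- A %*% P %*% t(A) + W
    S <- H %*% Pp %*% t(H) + Q + ridge
    K <- t(solve(S, H %*% Pp))
    x <- xp + K %*% (X[t, ] - H %*% xp)
    P <- Pp - K %*% H %*% Pp
    out[t, ] <- x
  }
  out
}

#' Predict mel-band frames from features
#'
#' @param object A fitted [speech_decoder()].
#' @param newdata Feature matrix with the training width.
#' @param ... Unused.
#' @return frames x bands matrix of predicted standardized mel values.
#' @export
predict.speech_decoder <- function(object, newdata, ...) {
  X <- unclass(as.matrix(newdata)); storage.mode(X) <- "double"
  if (ncol(X) != object$n_features) {
    stop("newdata has ", ncol(X), " features; the decoder was trained on ",
         object$n_features)
  }
  out <- switch(object$algorithm,
    wiener = cbind(1, X) %*% object$fit$B,
    wiener_cascade = {
      U <- cbind(1, X) %*% object$fit$B
      dg <- object$fit$degree
      O <- matrix(0, nrow(U), ncol(U))
      for (j in seq_len(ncol(U))) {
        O[, j] <- outer(U[, j], 0:dg, `^`) %*% object$fit$P[, j]
      }
      O
    },
    kalman = kalman_predict(object$fit, X),
    {
      Xs <- sweep(sweep(X, 2L, object$fit$xm), 2L, object$fit$xs, `/`)
      Xin <- if (object$fit$arch == "dense") Xs
             else features_to_sequence(Xs, object$span, object$n_channels)
      out <- nn_forward(object$fit$params, Xin, object$fit$arch)
      sweep(sweep(out, 2L, object$fit$ys, `*`), 2L, object$fit$ym, `+`)
    })
  if (!all(is.finite(out))) stop("non-finite predictions")
  out
}

#' @export
print.speech_decoder <- function(x, ...) {
  cat(sprintf("<speech_decoder: %s> %d features -> %d mel bands\n",
              x$algorithm, x$n_features, x$n_bands))
  if (!is.null(x$fit$log)) {
    cat(sprintf("  trained %d epochs (best %d), val MSE %.4g\n",
                x$fit$n_epochs, x$fit$best_epoch,
                min(x$fit$log$val_loss)))
  }
  cat(sprintf("  training MSE %.4g\n", x$train_mse))
  invisible(x)
}

#' @export
summary.speech_decoder <- function(object, ...) {
  out <- list(algorithm = object$algorithm,
              n_features = object$n_features, n_bands = object$n_bands,
              train_mse = object$train_mse,
              hyper = Filter(Negate(is.null),
                             object[c("units", "degree", "C", "span")]),
              training_log = object$fit$log)
  class(out) <- "summary.speech_decoder"
  out
}

#' @export
print.summary.speech_decoder <- function(x, ...) {
  cat(sprintf("speech_decoder (%s): %d features -> %d bands, train MSE %.4g\n",
              x$algorithm, x$n_features, x$n_bands, x$train_mse))
  if (length(x$hyper)) {
    cat("  hyperparameters:",
        paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", "),
        "\n")
  }
  if (!is.null(x$training_log)) {
    cat("  training log (last epochs):\n")
    print(utils::tail(x$training_log, 3L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.speech_decoder <- function(object, ...) {
  switch(object$algorithm,
    wiener = object$fit$B,
    wiener_cascade = list(linear = object$fit$B,
                          polynomial = object$fit$P),
    kalman = object$fit[c("A", "W", "H", "Q")],
    object$fit$params)
}

#' @export
fitted.speech_decoder <- function(object, ...) object$fitted

#' @export
residuals.speech_decoder <- function(object, y = NULL, ...) {
  if (is.null(y)) stop("supply the training targets y to compute residuals")
  as.matrix(y) - object$fitted
}
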