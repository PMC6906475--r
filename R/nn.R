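# Minimal neural-network engine: single-hidden-layer dense, simple-RNN, GRU
# and LSTM regressors with Adam/RMSprop optimizers and validation-loss early
# stopping. Written against base matrix ops; gradients are verified by
# numerical differentiation in the test suite.

sigm <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

nn_init <- function(arch, n_in, units, n_out) {
  switch(arch,
    dense = list(W1 = glorot(n_in, units), b1 = numeric(units),
                 V = glorot(units, n_out), c = numeric(n_out)),
    rnn = list(W = glorot(n_in, units), U = glorot(units, units),
               b = numeric(units),
               V = glorot(units, n_out), c = numeric(n_out)),
    gru = list(Wz = glorot(n_in, units), Uz = glorot(units, units),
               bz = numeric(units),
               Wr = glorot(n_in, units), Ur = glorot(units, units),
               br = numeric(units),
               Wn = glorot(n_in, units), Un = glorot(units, units),
               bn = numeric(units),
               V = glorot(units, n_out), c = numeric(n_out)),
    lstm = list(W = glorot(n_in, 4L * units), U = glorot(units, 4L * units),
                b = c(numeric(units), rep(1, units), numeric(2L * units)),
                V = glorot(units, n_out), c = numeric(n_out)),
    stop("unknown architecture: ", arch))
}

addb <- function(M, b) sweep(M, 2L, b, `+`)

# Forward pass. For recurrent archs, X is a list of T matrices (N x n_in,
# time-major); for dense, a single N x n_in matrix. Returns prediction and,
# if cache = TRUE, the intermediates needed for backprop.
nn_forward <- function(params, X, arch, cache = FALSE) {
  if (arch == "dense") {
    Z1 <- addb(X %*% params$W1, params$b1)
    H <- pmax(Z1, 0)
    Yhat <- addb(H %*% params$V, params$c)
    if (!cache) return(Yhat)
    return(list(Yhat = Yhat, H = H, Z1 = Z1))
  }
  Tn <- length(X)
  N <- nrow(X[[1L]])
  units <- nrow(params$V)
  h <- matrix(0, N, units)
  st <- if (cache) vector("list", Tn) else NULL
  if (arch == "rnn") {
    for (t in seq_len(Tn)) {
      hprev <- h
      Z <- addb(X[[t]] %*% params$W + hprev %*% params$U, params$b)
      h <- pmax(Z, 0)
      if (cache) st[[t]] <- list(Z = Z, hprev = hprev, h = h)
    }
  } else if (arch == "gru") {
    for (t in seq_len(Tn)) {
      hprev <- h
      z <- sigm(addb(X[[t]] %*% params$Wz + hprev %*% params$Uz, params$bz))
      r <- sigm(addb(X[[t]] %*% params$Wr + hprev %*% params$Ur, params$br))
      nn <- tanh(addb(X[[t]] %*% params$Wn + (r * hprev) %*% params$Un,
                      params$bn))
      h <- (1 - z) * nn + z * hprev
      if (cache) st[[t]] <- list(z = z, r = r, nn = nn, hprev = hprev, h = h)
    }
  } else if (arch == "lstm") {
    cc <- matrix(0, N, units)
    for (t in seq_len(Tn)) {
      hprev <- h; cprev <- cc
      A <- addb(X[[t]] %*% params$W + hprev %*% params$U, params$b)
      i <- sigm(A[, seq_len(units), drop = FALSE])
      f <- sigm(A[, units + seq_len(units), drop = FALSE])
      g <- tanh(A[, 2L * units + seq_len(units), drop = FALSE])
      o <- sigm(A[, 3L * units + seq_len(units), drop = FALSE])
      cc <- f * cprev + i * g
      tc <- tanh(cc)
      h <- o * tc
      if (cache) st[[t]] <- list(i = i, f = f, g = g, o = o, cc = cc,
                                 tc = tc, hprev = hprev, cprev = cprev,
                                 h = h)
    }
  }
  Yhat <- addb(h %*% params$V, params$c)
  if (!cache) return(Yhat)
  list(Yhat = Yhat, states = st, hT = h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backward pass for MSE loss; dY is dL/dYhat. Returns grads with the same
# names as params.
nn_backward <- function(params, X, arch, fw, dY) {
  g <- lapply(params, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))
  if (arch == "dense") {
    g$V <- t(fw$H) %*% dY
    g$c <- colSums(dY)
    dH <- dY %*% t(params$V)
    dZ1 <- dH * (fw$Z1 > 0)
    g$W1 <- t(X) %*% dZ1
    g$b1 <- colSums(dZ1)
    return(g)
  }
  Tn <- length(X)
  units <- nrow(params$V)
  st <- fw$states
  g$V <- t(fw$hT) %*% dY
  g$c <- colSums(dY)
  dh <- dY %*% t(params$V)
  if (arch == "rnn") {
    for (t in rev(seq_len(Tn))) {
      dZ <- dh * (st[[t]]$Z > 0)
      g$W <- g$W + t(X[[t]]) %*% dZ
      g$U <- g$U + t(st[[t]]$hprev) %*% dZ
      g$b <- g$b + colSums(dZ)
      dh <- dZ %*% t(params$U)
    }
  } else if (arch == "gru") {
    for (t in rev(seq_len(Tn))) {
      s <- st[[t]]
      dn <- dh * (1 - s$z)
      dz <- dh * (s$hprev - s$nn)
      dhprev <- dh * s$z
      dan <- dn * (1 - s$nn^2)
      g$Wn <- g$Wn + t(X[[t]]) %*% dan
      g$Un <- g$Un + t(s$r * s$hprev) %*% dan
      g$bn <- g$bn + colSums(dan)
      drh <- dan %*% t(params$Un)
      dr <- drh * s$hprev
      dhprev <- dhprev + drh * s$r
      daz <- dz * s$z * (1 - s$z)
      g$Wz <- g$Wz + t(X[[t]]) %*% daz
      g$Uz <- g$Uz + t(s$hprev) %*% daz
      g$bz <- g$bz + colSums(daz)
      dhprev <- dhprev + daz %*% t(params$Uz)
      dar <- dr * s$r * (1 - s$r)
      g$Wr <- g$Wr + t(X[[t]]) %*% dar
      g$Ur <- g$Ur + t(s$hprev) %*% dar
      g$br <- g$br + colSums(dar)
      dhprev <- dhprev + dar %*% t(params$Ur)
      dh <- dhprev
    }
  } else if (arch == "lstm") {
    dc <- matrix(0, nrow(dh), units)
    for (t in rev(seq_len(Tn))) {
      s <- st[[t]]
      do <- dh * s$tc
      dc <- dc + dh * s$o * (1 - s$tc^2)
      di <- dc * s$g
      dg <- dc * s$i
      df <- dc * s$cprev
      dA <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do * s$o * (1 - s$o))
      g$W <- g$W + t(X[[t]]) %*% dA
      g$U <- g$U + t(s$hprev) %*% dA
      g$b <- g$b + colSums(dA)
      dh <- dA %*% t(params$U)
      dc <- dc * s$f
    }
  }
  g
}

make_optimizer <- function(type = c("adam", "rmsprop"), params, lr) {
  type <- match.arg(type)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  t_step <- 0L
  step <- function(params, grads) {
    t_step <<- t_step + 1L
    for (nm in names(params)) {
      if (type == "adam") {
        m[[nm]] <<- 0.9 * m[[nm]] + 0.1 * grads[[nm]]
        v[[nm]] <<- 0.999 * v[[nm]] + 0.001 * grads[[nm]]^2
        mhat <- m[[nm]] / (1 - 0.9^t_step)
        vhat <- v[[nm]] / (1 - 0.999^t_step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      } else {
        v[[nm]] <<- 0.9 * v[[nm]] + 0.1 * grads[[nm]]^2
        params[[nm]] <- params[[nm]] - lr * grads[[nm]] /
          (sqrt(v[[nm]]) + 1e-8)
      }
    }
    params
  }
  step
}

# Reshape a windowed feature matrix (channel-major lag blocks) into the
# time-major sequence consumed by recurrent nets: T = span+1 matrices of
# N x n_channels.
features_to_sequence <- function(X, span, n_channels) {
  Tn <- span + 1L
  stopifnot(ncol(X) == n_channels * Tn)
  lapply(seq_len(Tn), function(t) {
    X[, (seq_len(n_channels) - 1L) * Tn + t, drop = FALSE]
  })
}

mse <- function(a, b) mean((a - b)^2)

# Core training loop with early stopping (restores best-validation-epoch
# parameters). Xtr/Xval are matrices (dense) or time-major sequence lists.
nn_train <- function(arch, Xtr, Ytr, Xval, Yval, units,
                     max_epochs = 2048L, patience = 5L, batch = 128L,
                     lr = 1e-3, optimizer = c("adam", "rmsprop"),
                     seed = 1L) {
  optimizer <- match.arg(optimizer)
  dense <- arch == "dense"
  n_in <- if (dense) ncol(Xtr) else ncol(Xtr[[1L]])
  n_out <- ncol(Ytr)
  N <- nrow(Ytr)
  take <- function(X, idx) {
    if (dense) X[idx, , drop = FALSE]
    else lapply(X, function(m) m[idx, , drop = FALSE])
  }
  with_seed(seed, {
    params <- nn_init(arch, n_in, units, n_out)
    opt <- make_optimizer(optimizer, params, lr)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    log <- matrix(NA_real_, max_epochs, 2L,
                  dimnames = list(NULL, c("train_loss", "val_loss")))
    n_epochs <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(N)
      for (start in seq(1L, N, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, N)]
        Xb <- take(Xtr, idx)
        Yb <- Ytr[idx, , drop = FALSE]
        fw <- nn_forward(params, Xb, arch, cache = TRUE)
        dY <- 2 * (fw$Yhat - Yb) / length(Yb)
        grads <- nn_backward(params, Xb, arch, fw, dY)
        params <- opt(params, grads)
      }
      tr_loss <- mse(nn_forward(params, Xtr, arch), Ytr)
      val_loss <- mse(nn_forward(params, Xval, arch), Yval)
      log[epoch, ] <- c(tr_loss, val_loss)
      n_epochs <- epoch
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    list(params = best$params, best_epoch = best$epoch,
         n_epochs = n_epochs,
         log = as.data.frame(cbind(epoch = seq_len(n_epochs),
                                   log[seq_len(n_epochs), , drop = FALSE])),
         optimizer = optimizer, lr = lr, batch = batch, units = units)
  })
}
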