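# Statistical comparison of decoding models: multisample correlation
# chi-square with a Tukey-type post-hoc, and block-based Friedman + Conover
# tests for the other metrics.

#' Multisample correlation test
#'
#' Tests whether k correlation coefficients (one per model, each with its
#' validation sample size) share a common value. Each correlation is Fisher
#' z-transformed; the common correlation `r_w` is the sample-size-weighted
#' mean in z-space, back-transformed; the statistic is
#' `chi2 = sum n_i (r_i - r_w)^2 / (1 - r_i r_w)^2` with `k - 1` degrees of
#' freedom.
#'
#' @param r Numeric vector of correlations, all strictly inside (-1, 1).
#' @param n Integer vector of sample sizes (validation frame counts),
#'   each >= 4.
#' @return List with `chi2`, `df`, `p_value`, `r_common`.
#' @export
paul_chi_square <- function(r, n) {
  if (length(r) < 2L || length(r) != length(n)) {
    stop("need k >= 2 correlations with matching sample sizes")
  }
  if (any(abs(r) >= 1)) stop("correlations must be strictly inside (-1, 1)")
  if (any(n < 4)) stop("each sample size must be at least 4")
  z <- atanh(r)
  r_w <- tanh(sum(n * z) / sum(n))
  chi2 <- sum(n * (r - r_w)^2 / (1 - r * r_w)^2)
  df <- length(r) - 1L
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       r_common = r_w)
}

#' Tukey-type post-hoc comparisons of correlations
#'
#' Pairwise studentized-range statistics on the Fisher z-transformed
#' correlations with standard errors `1/sqrt(n_i - 3)`; p-values from the
#' studentized range distribution with `k` groups.
#'
#' @inheritParams paul_chi_square
#' @param labels Optional model names.
#' @return List with `table` (one row per pair: statistic and adjusted p)
#'   and the symmetric `p_matrix`.
#' @export
tukey_correlation_posthoc <- function(r, n, labels = NULL) {
  k <- length(r)
  if (k < 2L) stop("need at least 2 samples")
  if (k == 2L) warning("only two samples: reduces to a two-sample z test")
  if (any(n <= 3)) stop("sample sizes must exceed 3")
  if (is.null(labels)) labels <- paste0("model", seq_len(k))
  z <- atanh(r)
  se2 <- 1 / (n - 3)
  pairs <- utils::combn(k, 2L)
  q <- numeric(ncol(pairs)); p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    se <- sqrt((se2[i1] + se2[i2]) / 2)
    q[j] <- abs(z[i1] - z[i2]) / se
    p[j] <- stats::ptukey(q[j], nmeans = k, df = Inf, lower.tail = FALSE)
  }
  pm <- matrix(1, k, k, dimnames = list(labels, labels))
  for (j in seq_len(ncol(pairs))) {
    pm[pairs[1L, j], pairs[2L, j]] <- p[j]
    pm[pairs[2L, j], pairs[1L, j]] <- p[j]
  }
  list(table = data.frame(a = labels[pairs[1L, ]], b = labels[pairs[2L, ]],
                          statistic = q, p_value = p),
       p_matrix = pm)
}

#' Evaluate a metric on non-overlapping blocks
#'
#' Splits the audio timeline into non-overlapping blocks (default 2 s,
#' trailing partial block dropped) and evaluates `metric` for each block and
#' each reconstruction, yielding the block x model matrix consumed by
#' [friedman_test()] / [conover_posthoc()].
#'
#' @param target Target waveform.
#' @param recons Named list of reconstruction waveforms (one per model),
#'   each the same length as `target`.
#' @param fs Sample rate.
#' @param metric Function `(target_block, recon_block, fs) -> scalar`.
#' @param block Block length, seconds.
#' @return blocks x models numeric matrix.
#' @export
blockify <- function(target, recons, fs, metric, block = 2) {
  stopifnot(is.list(recons), length(recons) >= 1L)
  bs <- round(block * fs)
  n_blocks <- length(target) %/% bs
  if (n_blocks < 3L) stop("need at least 3 full blocks of audio")
  if (is.null(names(recons))) names(recons) <- paste0("model", seq_along(recons))
  out <- matrix(NA_real_, n_blocks, length(recons),
                dimnames = list(NULL, names(recons)))
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * bs + 1L):(b * bs)
    tb <- target[idx]
    for (j in seq_along(recons)) {
      if (length(recons[[j]]) != length(target)) stop("length mismatch")
      out[b, j] <- metric(tb, recons[[j]][idx], fs)
    }
  }
  out
}

#' Friedman test on a block x model matrix
#'
#' Within-block ranks (midranks for ties), standard Friedman chi-square
#' with `models - 1` degrees of freedom.
#'
#' @param m blocks x models numeric matrix (>= 3 blocks, >= 2 models, no
#'   missing cells).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 models")
  if (nrow(m) < 3L) stop("need at least 3 blocks")
  if (anyNA(m)) stop("missing cells are not allowed")
  ht <- stats::friedman.test(m)
  stat <- unname(ht$statistic)
  p <- ht$p.value
  if (!is.finite(stat)) {  # complete within-block ties: no evidence at all
    stat <- 0
    p <- 1
  }
  list(statistic = stat, df = unname(ht$parameter), p_value = p)
}

#' Conover post-hoc comparisons after a Friedman test
#'
#' Pairwise t-type statistics on within-block rank sums following Conover's
#' procedure, with df `(n-1)(k-1)` and step-down Holm adjustment of the
#' pairwise p-values.
#'
#' @param m blocks x models matrix, as for [friedman_test()].
#' @param p_adjust Multiplicity adjustment passed to [stats::p.adjust()].
#' @return List with `table` (pairwise statistics, raw and adjusted p) and
#'   the symmetric `p_matrix` of adjusted p-values.
#' @export
conover_posthoc <- function(m, p_adjust = "holm") {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (k < 3L) stop("need at least 3 models (two models reduce to a sign/",
                   "Wilcoxon comparison)")
  if (anyNA(m)) stop("missing cells are not allowed")
  labels <- colnames(m)
  if (is.null(labels)) labels <- paste0("model", seq_len(k))
  R <- t(apply(m, 1L, rank))
  Rj <- colSums(R)
  T1 <- friedman_test(m)$statistic
  A1 <- sum(R^2)
  C1 <- n * k * (k + 1)^2 / 4
  scale2 <- 2 * n * (A1 - C1) / ((n - 1) * (k - 1)) *
    max(1 - T1 / (n * (k - 1)), 1e-12)
  df <- (n - 1) * (k - 1)
  pairs <- utils::combn(k, 2L)
  tstat <- numeric(ncol(pairs)); p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    d_rank <- abs(Rj[pairs[1L, j]] - Rj[pairs[2L, j]])
    tstat[j] <- if (scale2 > 0) d_rank / sqrt(scale2) else 0
    p[j] <- 2 * stats::pt(tstat[j], df, lower.tail = FALSE)
  }
  p_adj <- stats::p.adjust(pmin(p, 1), method = p_adjust)
  pm <- matrix(1, k, k, dimnames = list(labels, labels))
  for (j in seq_len(ncol(pairs))) {
    pm[pairs[1L, j], pairs[2L, j]] <- p_adj[j]
    pm[pairs[2L, j], pairs[1L, j]] <- p_adj[j]
  }
  list(table = data.frame(a = labels[pairs[1L, ]], b = labels[pairs[2L, ]],
                          statistic = tstat, p_value = pmin(p, 1),
                          p_adjusted = p_adj),
       p_matrix = pm)
}
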