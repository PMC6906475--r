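# End-to-end orchestration: sequential splitting, dataset assembly with
# training-only fitting of all preprocessing statistics, single experiment
# runs, and hyperparameter grid search.

#' Sequential train/validation/test split
#'
#' Contiguous, ordered, disjoint frame ranges covering all frames:
#' the first `floor(0.8 n)` frames train, the next `floor(0.1 n)` validate,
#' the remainder tests. Splitting is sequential (never shuffled) to limit
#' leakage between temporally adjacent frames.
#'
#' @param n_frames Total frame count (>= 10).
#' @param fractions Length-3 positive fractions summing to 1.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
sequential_split <- function(n_frames, fractions = c(0.8, 0.1, 0.1)) {
  if (n_frames < 10L) stop("need at least 10 frames")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be 3 positive numbers summing to 1")
  }
  n_train <- as.integer(floor(fractions[1] * n_frames))
  n_val <- as.integer(floor(fractions[2] * n_frames))
  list(train = seq_len(n_train),
       val = n_train + seq_len(n_val),
       test = (n_train + n_val + 1L):as.integer(n_frames))
}

default_config <- function() {
  list(
    sounds = NULL,            # NULL = all labels
    n_fft = 2048L, hop_ms = 40, n_mels = 128L,
    filter_low_hz = 500, filter_high_hz = 3000,
    threshold_factor = 4, dead_time_ms = 1,
    span = 4L, n_channels = NULL,  # NULL = all, ranked order
    fractions = c(0.8, 0.1, 0.1),
    algorithm = "wiener", units = 256L, degree = 2L, C = 1,
    max_epochs = 2048L, patience = 5L, batch = 128L, lr = 1e-3,
    gl_iters = 64L, seed = 1L)
}

merge_config <- function(config) {
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  cfg
}

#' Assemble a decoding dataset from a recording and its trial table
#'
#' Kept trials (keep = TRUE, label in the sound subset) are concatenated in
#' session order, each trimmed to a whole number of hops. On the shared hop
#' grid it computes mel targets and binned threshold-crossing counts, then
#' fits every data-dependent statistic on training frames only: channel
#' noise levels (MAD), channel activity ranking, and the target
#' standardizer.
#'
#' @param bundle A [recording_bundle()].
#' @param trials A [trial_table()].
#' @param config Named list overriding [pipeline defaults][run_experiment]:
#'   `sounds`, `n_fft`, `hop_ms`, `n_mels`, `filter_low_hz`,
#'   `filter_high_hz`, `threshold_factor`, `dead_time_ms`, `span`,
#'   `n_channels`, `fractions`.
#' @return List with `features` (frame x channel*(span+1)
#'   [window_features()] matrix), `targets` (frame x band standardized mel),
#'   `split`, `mel` (raw mel values, band x frame), `standardizer`,
#'   `sigma`, `ranking`, `channels_used`, `target_audio`, `fs`, `config`.
#' @export
assemble_dataset <- function(bundle, trials, config = list()) {
  stopifnot(inherits(bundle, "recording_bundle"),
            inherits(trials, "trial_table"))
  cfg <- merge_config(config)
  fs <- bundle$fs
  hop <- cfg$hop_ms / 1000
  hs <- hop_samples(hop, fs)

  kept <- trials[trials$keep, , drop = FALSE]
  if (!is.null(cfg$sounds)) {
    bad <- setdiff(cfg$sounds, unique(trials$label))
    if (length(bad)) stop("unknown sounds: ", paste(bad, collapse = ", "))
    kept <- kept[kept$label %in% cfg$sounds, , drop = FALSE]
  }
  if (nrow(kept) == 0L) stop("no trials selected")

  filt <- design_bandpass(cfg$filter_low_hz, cfg$filter_high_hz, fs)
  neural_f <- apply_bandpass(bundle$neural, filt)

  seg_frames <- pmax((kept$end_sample - kept$begin_sample) %/% hs, 0L)
  if (any(seg_frames == 0L)) stop("trial shorter than one hop")
  audio_segs <- vector("list", nrow(kept))
  neural_segs <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    idx <- (kept$begin_sample[i] + 1L):(kept$begin_sample[i] +
                                          seg_frames[i] * hs)
    audio_segs[[i]] <- bundle$audio[idx]
    neural_segs[[i]] <- neural_f[, idx, drop = FALSE]
  }
  target_audio <- unlist(audio_segs)
  neural_cat <- do.call(cbind, neural_segs)
  n_frames <- sum(seg_frames)
  split <- sequential_split(n_frames, cfg$fractions)

  train_samples <- seq_len(length(split$train) * hs)
  sigma <- estimate_noise(neural_cat[, train_samples, drop = FALSE])

  crossings <- lapply(seq_len(nrow(neural_cat)), function(ch) {
    detect_crossings(neural_cat[ch, ], sigma[ch], cfg$threshold_factor, fs,
                     dead_time = cfg$dead_time_ms / 1000)
  })
  counts <- bin_counts(crossings, fs, hop, n_frames)
  ranking <- rank_channels(counts[split$train, , drop = FALSE])
  n_ch <- if (is.null(cfg$n_channels)) nrow(neural_cat) else cfg$n_channels
  channels_used <- ranking[seq_len(min(n_ch, length(ranking)))]

  mel <- mel_compress(stft_magnitude(target_audio, fs, cfg$n_fft, hop),
                      cfg$n_mels)
  mel_vals <- mel$values[, seq_len(n_frames), drop = FALSE]
  standardizer <- fit_standardizer(
    mel_vals[, split$train, drop = FALSE])
  targets <- t(apply_standardizer(mel_vals, standardizer))

  features <- window_features(counts[, channels_used, drop = FALSE],
                              cfg$span)
  list(features = features, targets = targets, split = split,
       mel = mel_vals, standardizer = standardizer, sigma = sigma,
       ranking = ranking, channels_used = channels_used,
       target_audio = target_audio, fs = fs, hop = hop, config = cfg)
}

#' Run one decoding experiment end to end
#'
#' Assembles the dataset, trains one decoder on the training frames (with
#' the validation frames driving early stopping for network decoders),
#' predicts every split bin-by-bin (no averaging across bins or trials),
#' un-standardizes the predictions, reconstructs audio by mel inversion and
#' Griffin-Lim, and computes the six reconstruction metrics per
#' reconstructed split.
#'
#' @param bundle,trials As for [assemble_dataset()].
#' @param config Named list; in addition to the [assemble_dataset()] keys:
#'   `algorithm` (`"perfect"` bypasses decoding and scores the targets
#'   against themselves — the upper-bound path), `units`, `degree`, `C`,
#'   `max_epochs`, `patience`, `batch`, `lr`, `gl_iters`, `seed`.
#' @param reconstruct Splits for which audio is reconstructed and the full
#'   metric suite computed (default validation and test).
#' @param shuffle_targets If TRUE, the target frames are permuted (seeded)
#'   before fitting — the permutation null control; feature-target
#'   alignment is destroyed while both marginals are preserved.
#' @param data Optional pre-assembled dataset from [assemble_dataset()],
#'   reused as-is (the caller must keep preprocessing keys consistent);
#'   avoids re-filtering when only the decoder configuration changes.
#' @return List with `row` (one-row data.frame: configuration, per-split
#'   Fisher-mean correlations, per-split metric suite, training wall time),
#'   `recon` (named list of reconstructed waveforms), `target` (matching
#'   target waveforms), `decoder`, `data`.
#' @export
run_experiment <- function(bundle, trials, config = list(),
                           reconstruct = c("val", "test"),
                           shuffle_targets = FALSE, data = NULL) {
  cfg <- merge_config(config)
  if (cfg$algorithm == "kalman") cfg$span <- 0L
  if (is.null(data)) {
    data <- assemble_dataset(bundle, trials, cfg[c(
      "sounds", "n_fft", "hop_ms", "n_mels", "filter_low_hz",
      "filter_high_hz", "threshold_factor", "dead_time_ms", "span",
      "n_channels", "fractions")])
  }
  Y <- data$targets
  if (shuffle_targets) {
    perm <- with_seed(cfg$seed + 77L, sample.int(nrow(Y)))
    Y <- Y[perm, , drop = FALSE]
  }
  sp <- data$split
  X <- data$features
  hs <- hop_samples(data$hop, data$fs)

  sub <- function(M, idx) M[idx, , drop = FALSE]
  t0 <- proc.time()[["elapsed"]]
  if (cfg$algorithm == "perfect") {
    decoder <- NULL
    pred <- Y
  } else {
    decoder <- speech_decoder(
      sub(X, sp$train), sub(Y, sp$train), algorithm = cfg$algorithm,
      validation = list(x = sub(X, sp$val), y = sub(Y, sp$val)),
      units = cfg$units, degree = cfg$degree, C = cfg$C,
      max_epochs = cfg$max_epochs, patience = cfg$patience,
      batch = cfg$batch, lr = cfg$lr, seed = cfg$seed)
    pred <- predict(decoder, X)
  }
  train_time <- proc.time()[["elapsed"]] - t0

  row <- data.frame(algorithm = cfg$algorithm, n_mels = cfg$n_mels,
                    hop_ms = cfg$hop_ms, span = cfg$span,
                    n_channels = length(data$channels_used),
                    filter_low_hz = cfg$filter_low_hz,
                    filter_high_hz = cfg$filter_high_hz,
                    threshold_factor = cfg$threshold_factor,
                    units = cfg$units, degree = cfg$degree, C = cfg$C,
                    seed = cfg$seed, train_time_s = train_time)
  for (s in c("train", "val", "test")) {
    row[[paste0(s, "_r")]] <- as.numeric(
      fisher_mean_correlation(t(sub(Y, sp[[s]])), t(sub(pred, sp[[s]]))))
  }

  recon <- list(); target <- list()
  for (s in intersect(reconstruct, c("train", "val", "test"))) {
    idx <- sp[[s]]
    mel_pred <- structure(
      list(values = invert_standardizer(t(sub(pred, idx)),
                                        data$standardizer),
           n_mels = cfg$n_mels, hop = data$hop, n_fft = cfg$n_fft,
           fs = data$fs, db = FALSE),
      class = "mel_spec")
    n_samp <- length(idx) * hs
    wav <- mel_to_audio(mel_pred, n_iter = cfg$gl_iters,
                        seed = cfg$seed + 13L, length_out = n_samp)
    tgt <- data$target_audio[((idx[1L] - 1L) * hs + 1L):
                               ((idx[1L] - 1L) * hs + n_samp)]
    recon[[s]] <- wav
    target[[s]] <- tgt
    mr <- metric_report(tgt, wav, data$fs,
                        y = data$mel[, idx, drop = FALSE],
                        yhat = mel_pred$values, hop = data$hop)
    names(mr) <- paste0(s, "_", names(mr))
    mr[[paste0(s, "_fisher_mean_r")]] <- NULL  # keep the bin-level r column
    row <- cbind(row, mr)
  }
  list(row = row, recon = recon, target = target, decoder = decoder,
       data = data)
}

#' Grid search over pipeline hyperparameters
#'
#' Evaluates every combination of the supplied hyperparameter lists (the
#' Cartesian product), running [run_experiment()] for each, and returns the
#' results ranked by validation-set Fisher-mean mel correlation
#' (descending). A failing combination is flagged, not fatal.
#'
#' @param bundle,trials As for [assemble_dataset()].
#' @param grid Named list of vectors of config values to cross (e.g.
#'   `list(algorithm = c("wiener", "lstm_rnn"), span = c(4, 8))`).
#' @param base_config Config values shared by all runs.
#' @param reconstruct Splits reconstructed per run (default none, for
#'   speed; ranking needs only the correlations).
#' @return data.frame of class `ranked_results`, one row per evaluated
#'   model, sorted by `val_r` descending, with an `ok` flag.
#' @export
grid_search <- function(bundle, trials, grid, base_config = list(),
                        reconstruct = character(0)) {
  stopifnot(is.list(grid), length(grid) >= 1L, !is.null(names(grid)))
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- base_config
    cfg[names(combos)] <- as.list(combos[i, , drop = FALSE])
    res <- tryCatch(
      run_experiment(bundle, trials, cfg, reconstruct = reconstruct),
      error = function(e) e)
    if (inherits(res, "error")) {
      r <- cbind(as.data.frame(combos[i, , drop = FALSE]),
                 ok = FALSE, error = conditionMessage(res),
                 val_r = NA_real_)
    } else {
      r <- cbind(res$row, ok = TRUE, error = NA_character_)
    }
    rows[[i]] <- r
  }
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA
    r[all_names]
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$val_r), -Inf, out$val_r)), ]
  rownames(out) <- NULL
  class(out) <- c("ranked_results", "data.frame")
  out
}

#' @export
print.ranked_results <- function(x, n = 10L, ...) {
  cat(sprintf("<ranked_results> %d models (%d failed); top by val_r:\n",
              nrow(x), sum(!x$ok)))
  cols <- intersect(c("algorithm", "units", "degree", "C", "span",
                      "n_channels", "n_mels", "train_r", "val_r", "test_r"),
                    names(x))
  print(utils::head(as.data.frame(x)[, cols], n), row.names = FALSE)
  invisible(x)
}
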