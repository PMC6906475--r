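# Shared small synthetic fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Desk-scale session for pipeline-level tests: 3 tokens x 6 reps, 6 channels.
small_session <- function() {
  if (is.null(.fixture_env$small)) {
    ses <- session_spec(reps_per_token = 6L, iti = 0.4, seed = 11L)
    model <- sample_encoding_model(6L, seed = 111L,
                                   informative_fraction = 1.0,
                                   gain = 60, baseline = 10, noise_sd = 10)
    .fixture_env$small <- synth_session(ses, model)
  }
  .fixture_env$small
}

small_dataset <- function(config = list(n_mels = 16L, span = 4L)) {
  key <- paste(deparse(config), collapse = "")
  if (is.null(.fixture_env[[key]])) {
    ss <- small_session()
    .fixture_env[[key]] <- assemble_dataset(ss$bundle, ss$trials, config)
  }
  .fixture_env[[key]]
}

hop_samples_t <- function(hop, fs) as.integer(round(hop * fs))

# A few seconds of structured test audio (tokens with gaps), used by the
# metric tests.
token_audio <- function(fs = 30000, seed = 2L) {
  tok <- synth_token_audio(default_vocabulary()[[1L]], fs, seed = seed)
  rep(c(tok, numeric(round(0.1 * fs))), 6L)
}
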