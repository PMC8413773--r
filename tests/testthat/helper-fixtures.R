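# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A moderately sized study: default 60-symbol paradigm, 4 participants,
# realistic learner, default gain.
signal_dataset <- function() {
  fixture("signal_dataset", simulate_dataset(
    n_participants = 4, fwd = forward_model(gain = 8), seed = 101
  ))
}

# Small paradigm (3 blocks, 12 symbols) for fast structural checks.
tiny_dataset <- function(gain = 4, seed = 7, ...) {
  simulate_dataset(
    config = paradigm_config(n_blocks = 3), n_participants = 2,
    fwd = forward_model(gain = gain, ...), seed = seed
  )
}

# Hand-built epoch collection from an explicit array.
manual_epochs <- function(data, fs = 250, t0_ms = 0, words = NULL,
                          exposure_index = NULL, n_exposures = 10L) {
  n <- dim(data)[1]
  words <- words %||% sprintf("w%02d", seq_len(n))
  info <- tibble::tibble(
    participant = 1L, symbol = match(words, unique(words)), word = words,
    exposure_index = exposure_index %||% seq_len(n),
    n_exposures = n_exposures
  )
  epoch_collection(data, info, sprintf("E%02d", seq_len(dim(data)[2])),
                   fs, t0_ms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
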