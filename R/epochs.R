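#' Construct an epoch collection
#'
#' The in-memory container for epoched multichannel EEG: a numeric array of
#' dimension (epochs x electrodes x samples) in microvolts, plus a metadata
#' tibble with one row per epoch. All epochs share the electrode set, the
#' sampling rate and the time axis, which starts at `t0_ms` relative to
#' symbol onset (0 ms).
#'
#' @param data Numeric array, dim = c(n_epochs, n_electrodes, n_samples).
#' @param info Tibble with one row per epoch. Must contain at least
#'   `participant`, `symbol`, `word`, `exposure_index` and `n_exposures`
#'   (total pre-rejection presentations of that symbol to that participant).
#' @param electrodes Character vector of electrode names.
#' @param fs Sampling rate in Hz.
#' @param t0_ms Time of the first sample relative to symbol onset, in ms.
#' @return An `epoch_collection`.
#' @export
epoch_collection <- function(data, info, electrodes, fs, t0_ms = 0) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  stopifnot(nrow(info) == dim(data)[1])
  stopifnot(length(electrodes) == dim(data)[2])
  needed <- c("participant", "symbol", "word", "exposure_index", "n_exposures")
  missing <- setdiff(needed, names(info))
  if (length(missing) > 0L) {
    stop("epoch metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(data = data, info = tibble::as_tibble(info),
         electrodes = as.character(electrodes),
         fs = fs, t0_ms = t0_ms),
    class = "epoch_collection"
  )
}

#' @export
print.epoch_collection <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_collection> %d epochs x %d electrodes x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs))
  cat(sprintf("  time span: [%g, %g) ms; %d participants, %d symbols\n",
              x$t0_ms, x$t0_ms + d[3] * 1000 / x$fs,
              dplyr::n_distinct(x$info$participant),
              dplyr::n_distinct(x$info$symbol)))
  invisible(x)
}

#' Sample times of an epoch collection
#'
#' @param x An `epoch_collection`.
#' @return Numeric vector of sample times in ms relative to symbol onset.
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "epoch_collection"))
  x$t0_ms + (seq_len(dim(x$data)[3]) - 1L) * 1000 / x$fs
}

#' Number of epochs
#' @param x An `epoch_collection`.
#' @return Integer count.
#' @export
n_epochs <- function(x) {
  stopifnot(inherits(x, "epoch_collection"))
  dim(x$data)[1]
}

# Subset an epoch collection by epoch index, keeping data and metadata
# aligned.
subset_epochs <- function(x, idx) {
  epoch_collection(x$data[idx, , , drop = FALSE], x$info[idx, , drop = FALSE],
                   x$electrodes, x$fs, x$t0_ms)
}

#' Forward model for synthetic EEG
#'
#' Parameters of the generative model used by [generate_eeg_epochs()]:
#' an epoch is per-electrode AR(1) noise plus, on trials where the simulated
#' learner has already acquired the symbol's mapping, a planted linear
#' semantic signal `gain * g(t) * (M y_s)` where `M` is an
#' electrodes-by-dimensions mixing matrix, `y_s` the symbol's word vector and
#' `g(t)` a raised-cosine temporal envelope with maximum 1 supported on
#' `envelope_ms`.
#'
#' @param gain Signal amplitude in microvolts per unit of mixed embedding
#'   (0 disables the signal; default 2, which places trial-averaged decoding
#'   in the moderately-above-chance regime typical of EEG).
#' @param envelope_ms Length-2 support of the temporal envelope, in ms
#'   (half-open; default 150--650 ms after symbol onset).
#' @param ar_coef AR(1) coefficient of the per-electrode noise (default
#'   0.95).
#' @param noise_sd Stationary noise standard deviation, microvolts (default
#'   10).
#' @param artifact_rate Probability that an epoch receives an injected
#'   high-amplitude artifact guaranteed to violate the peak-to-peak or
#'   gradient rejection rule (default 0).
#' @param participant_jitter Standard deviation of the multiplicative
#'   elementwise jitter applied to `M` per participant, emulating
#'   inter-participant variability (default 0.1).
#' @param mixing Optional fixed mixing matrix (electrodes x dims); drawn
#'   as N(0, 1/v) entries when `NULL`.
#' @param active_electrodes Optional electrode names/indices outside of which
#'   the mixing rows are zeroed, confining the signal spatially.
#' @return A `forward_model` list.
#' @export
forward_model <- function(gain = 2, envelope_ms = c(150, 650),
                          ar_coef = 0.95, noise_sd = 10, artifact_rate = 0,
                          participant_jitter = 0.1, mixing = NULL,
                          active_electrodes = NULL) {
  stop_if_not_scalar_number(gain, "gain", 0)
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0)
  stopifnot(length(envelope_ms) == 2L, envelope_ms[1] < envelope_ms[2])
  stopifnot(ar_coef >= 0, ar_coef < 1)
  stopifnot(artifact_rate >= 0, artifact_rate <= 1)
  structure(
    list(gain = gain, envelope_ms = envelope_ms, ar_coef = ar_coef,
         noise_sd = noise_sd, artifact_rate = artifact_rate,
         participant_jitter = participant_jitter, mixing = mixing,
         active_electrodes = active_electrodes),
    class = "forward_model"
  )
}

#' Generate synthetic EEG epochs for simulated trials
#'
#' Produces one epoch per trial record. Noise is per-electrode AR(1) with
#' stationary standard deviation `noise_sd`. On trials flagged
#' `acquired_before_trial` a linear semantic signal is planted (see
#' [forward_model()]). With probability `artifact_rate` an epoch additionally
#' receives a single-sample 150 microvolt spike on a random electrode, which
#' violates both the 100 microvolt peak-to-peak and the 10 microvolts/ms
#' gradient rejection rules by a wide margin. Ground-truth flags
#' `signal_present` and `artifact_injected` are stored in the metadata.
#'
#' @param trials Trial records from [simulate_behavior()] (possibly several
#'   participants row-bound together).
#' @param vectors Word vectors with a labelled row for every trial word.
#' @param fwd A [forward_model()].
#' @param n_electrodes Number of electrodes (default 32).
#' @param n_samples Samples per epoch (default 250).
#' @param fs Sampling rate, Hz (default 250).
#' @param t0_ms Time of the first sample relative to symbol onset (default 0;
#'   use -200 with `n_samples = 300` to include a baseline span).
#' @param seed Integer seed.
#' @param electrodes Electrode names; defaults to the 32-channel layout names
#'   when `n_electrodes == 32`, otherwise `E01`, `E02`, ...
#' @return An [epoch_collection()].
#' @export
generate_eeg_epochs <- function(trials, vectors, fwd = forward_model(),
                                n_electrodes = 32, n_samples = 250, fs = 250,
                                t0_ms = 0, seed = 1L, electrodes = NULL) {
  stopifnot(inherits(fwd, "forward_model"))
  missing <- setdiff(unique(trials$word), rownames(vectors))
  if (length(missing) > 0L) {
    stop("no word vector for symbol word(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ne <- as.integer(n_electrodes)
  l <- as.integer(n_samples)
  n <- nrow(trials)
  v <- ncol(vectors)
  electrodes <- electrodes %||%
    (if (ne == 32L) montage_1020_32()$electrodes else sprintf("E%02d",
                                                              seq_len(ne)))
  stopifnot(length(electrodes) == ne)

  times <- t0_ms + (seq_len(l) - 1L) * 1000 / fs
  g <- envelope_weights(times, fwd$envelope_ms)

  with_seed(seed, {
    # mixing matrix, optionally spatially confined
    M <- fwd$mixing %||% matrix(stats::rnorm(ne * v, sd = 1 / sqrt(v)), ne, v)
    stopifnot(nrow(M) == ne, ncol(M) == v)
    if (!is.null(fwd$active_electrodes)) {
      act <- fwd$active_electrodes
      if (is.character(act)) act <- match(act, electrodes)
      if (anyNA(act)) stop("unknown electrode in `active_electrodes`.",
                           call. = FALSE)
      M[-act, ] <- 0
    }

    # AR(1) noise, vectorized across epochs and electrodes
    innov_sd <- fwd$noise_sd * sqrt(1 - fwd$ar_coef^2)
    data <- array(stats::rnorm(n * ne * l, sd = innov_sd), c(n, ne, l))
    data[, , 1] <- stats::rnorm(n * ne, sd = fwd$noise_sd)
    for (k in 2:l) {
      data[, , k] <- fwd$ar_coef * data[, , k - 1] + data[, , k]
    }

    # per-participant jittered mixing, planted signal on acquired trials
    participants <- unique(trials$participant)
    signal_present <- trials$acquired_before_trial & fwd$gain > 0
    for (p in participants) {
      Mp <- M * (1 + fwd$participant_jitter *
                   matrix(stats::rnorm(ne * v), ne, v))
      rows <- which(trials$participant == p & signal_present)
      if (length(rows) == 0L) next
      src <- Mp %*% t(vectors[trials$word[rows], , drop = FALSE])  # ne x nrow
      for (ii in seq_along(rows)) {
        data[rows[ii], , ] <- data[rows[ii], , ] +
          fwd$gain * outer(src[, ii], g)
      }
    }

    # margin-guaranteed artifacts: one-sample 150 uV spike
    artifact <- stats::runif(n) < fwd$artifact_rate
    for (i in which(artifact)) {
      e <- sample.int(ne, 1L)
      k <- sample(2:(l - 1L), 1L)
      data[i, e, k] <- data[i, e, k] + sample(c(-150, 150), 1L)
    }

    info <- trials |>
      dplyr::group_by(.data$participant, .data$symbol) |>
      dplyr::mutate(n_exposures = max(.data$exposure_index)) |>
      dplyr::ungroup() |>
      dplyr::mutate(signal_present = signal_present,
                    artifact_injected = artifact)
    epoch_collection(data, info, electrodes, fs, t0_ms)
  })
}

# Raised-cosine (Hann) temporal envelope on [on, off) ms, rescaled so its
# maximum over the sampled points is exactly 1.
envelope_weights <- function(times, envelope_ms) {
  on <- envelope_ms[1]; off <- envelope_ms[2]
  g <- numeric(length(times))
  inside <- times >= on & times < off
  g[inside] <- sin(pi * (times[inside] - on) / (off - on))^2
  if (any(g > 0)) g <- g / max(g)
  g
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper tying the paradigm, behavior, word-vector and EEG
#' generators together: builds one schedule per participant, simulates each
#' participant's trial-by-trial behavior, draws (or accepts) word vectors and
#' generates epochs with a shared mixing matrix (jittered per participant).
#'
#' @param config A [paradigm_config()].
#' @param n_participants Number of simulated participants (default 25).
#' @param learner A [learner_model()] shared by all participants.
#' @param fwd A [forward_model()].
#' @param vectors Optional word vectors; generated when `NULL`.
#' @param v Embedding dimensionality when generating vectors (default 50).
#' @param n_electrodes,n_samples,fs,t0_ms Epoch geometry, see
#'   [generate_eeg_epochs()].
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A list with elements `epochs` ([epoch_collection()]), `vectors`,
#'   `trials`, `schedules` (per-participant list) and the generator settings.
#' @export
simulate_dataset <- function(config = paradigm_config(), n_participants = 25,
                             learner = learner_model("exposure_rate", 0.3),
                             fwd = forward_model(), vectors = NULL, v = 50,
                             n_electrodes = 32, n_samples = 250, fs = 250,
                             t0_ms = 0, seed = 1L) {
  seeds <- derive_seeds(seed, 2L * n_participants + 2L)
  ns <- n_symbols(config)
  vectors <- vectors %||% generate_word_vectors(ns, v, seed = seeds[1])
  schedules <- lapply(seq_len(n_participants), function(p) {
    build_schedule(config, seed = seeds[1L + p])
  })
  trials <- dplyr::bind_rows(lapply(seq_len(n_participants), function(p) {
    simulate_behavior(schedules[[p]], config, learner,
                      seed = seeds[1L + n_participants + p], participant = p)
  }))
  epochs <- generate_eeg_epochs(trials, vectors, fwd, n_electrodes, n_samples,
                                fs, t0_ms, seed = seeds[2L * n_participants + 2L])
  list(epochs = epochs, vectors = vectors, trials = trials,
       schedules = schedules, config = config, learner = learner, fwd = fwd,
       seed = seed)
}
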