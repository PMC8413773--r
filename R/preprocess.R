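#' Trim epochs to the 1000 ms window after symbol onset
#'
#' Keeps the samples whose times lie in [0, 1000) ms. After trimming each
#' epoch holds exactly `fs` samples (one second of signal).
#'
#' @param epochs An [epoch_collection()].
#' @return The trimmed `epoch_collection`; metadata are preserved. Already
#'   trimmed input is returned unchanged.
#' @export
trim_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_collection"))
  t <- epoch_times(epochs)
  keep <- which(t >= 0 & t < 1000)
  if (length(keep) != round(epochs$fs)) {
    stop("epochs do not cover the full [0, 1000) ms window.", call. = FALSE)
  }
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$t0_ms <- t[keep[1]]
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and electrode, the mean voltage over the baseline
#' window (default the 200 ms before symbol onset).
#'
#' @param epochs An [epoch_collection()] whose time axis still contains the
#'   baseline span (apply before [trim_epochs()]).
#' @param baseline Length-2 half-open window in ms (default `c(-200, 0)`).
#' @return The corrected `epoch_collection`.
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_collection"), length(baseline) == 2L)
  t <- epoch_times(epochs)
  idx <- which(t >= baseline[1] & t < baseline[2])
  expected <- round(diff(baseline) * epochs$fs / 1000)
  if (length(idx) < expected || length(idx) == 0L) {
    stop(sprintf("baseline span [%g, %g) ms is not covered by the epochs.",
                 baseline[1], baseline[2]), call. = FALSE)
  }
  m <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  # (epoch, electrode) means recycle over the sample dimension
  epochs$data <- epochs$data - as.vector(m)
  epochs
}

#' Reject artifact epochs by peak-to-peak and gradient thresholds
#'
#' An epoch is dropped if on any electrode the voltage range (max minus min)
#' exceeds `p2p_limit`, or any adjacent-sample absolute difference exceeds
#' `grad_limit * (1000 / fs)` microvolts (the gradient rule discretized at
#' the sampling interval).
#'
#' @param epochs A trimmed, baseline-corrected [epoch_collection()].
#' @param p2p_limit Peak-to-peak threshold, microvolts (default 100).
#' @param grad_limit Gradient threshold, microvolts per ms (default 10).
#' @return A list with `epochs` (the retained collection) and `report`, a
#'   one-row tibble: `n_total`, `n_rejected`, `n_p2p`, `n_gradient`,
#'   `fraction_rejected`. Epochs violating both rules count in both per-rule
#'   columns.
#' @export
reject_artifacts <- function(epochs, p2p_limit = 100, grad_limit = 10) {
  stopifnot(inherits(epochs, "epoch_collection"))
  d <- dim(epochs$data)
  n <- d[1]; ne <- d[2]; l <- d[3]
  m <- matrix(epochs$data, nrow = n * ne)  # rows: (epoch, electrode) pairs
  step_limit <- grad_limit * 1000 / epochs$fs

  mx <- m[, 1]; mn <- m[, 1]; grad_bad <- rep(FALSE, n * ne)
  for (k in 2:l) {
    mx <- pmax(mx, m[, k])
    mn <- pmin(mn, m[, k])
    grad_bad <- grad_bad | abs(m[, k] - m[, k - 1]) > step_limit
  }
  p2p_bad <- (mx - mn) > p2p_limit

  by_epoch <- function(flags) {
    apply(matrix(flags, nrow = n, ncol = ne), 1, any)
  }
  p2p_epoch <- by_epoch(p2p_bad)
  grad_epoch <- by_epoch(grad_bad)
  reject <- p2p_epoch | grad_epoch

  report <- tibble::tibble(
    n_total = n,
    n_rejected = sum(reject),
    n_p2p = sum(p2p_epoch),
    n_gradient = sum(grad_epoch),
    fraction_rejected = sum(reject) / n
  )
  list(epochs = subset_epochs(epochs, !reject), report = report)
}

#' Select trials and symbols for analysis
#'
#' Per participant, symbols presented fewer than `min_exposures` times are
#' excluded entirely, and either the first `drop_first` exposures are dropped
#' or, when `trial_window = c(a, b)` is given, only exposures `a..b` are
#' kept. Exposure indices count presentations in the original order, so
#' earlier artifact rejection cannot shift which exposures are "first".
#' Symbols excluded for every participant disappear from the symbol axis.
#'
#' @param epochs An [epoch_collection()].
#' @param min_exposures Minimum presentations per participant-symbol
#'   (default 6).
#' @param drop_first Leading exposures to drop (default 2). Ignored when
#'   `trial_window` is given.
#' @param trial_window Optional length-2 inclusive exposure range to keep.
#' @return The filtered `epoch_collection`, with an attribute
#'   `excluded_symbols` naming symbols removed for all participants.
#' @export
select_trials <- function(epochs, min_exposures = 6, drop_first = 2,
                          trial_window = NULL) {
  stopifnot(inherits(epochs, "epoch_collection"))
  info <- epochs$info
  keep <- info$n_exposures >= min_exposures
  if (is.null(trial_window)) {
    keep <- keep & info$exposure_index > drop_first
  } else {
    stopifnot(length(trial_window) == 2L, trial_window[1] <= trial_window[2])
    keep <- keep & info$exposure_index >= trial_window[1] &
      info$exposure_index <= trial_window[2]
  }
  if (!any(keep)) {
    stop("trial selection excluded every symbol.", call. = FALSE)
  }
  excluded <- setdiff(unique(info$word), unique(info$word[keep]))
  out <- subset_epochs(epochs, keep)
  attr(out, "excluded_symbols") <- excluded
  out
}

#' Average selected trials into a per-symbol tensor
#'
#' Pools all retained trials of a symbol across participants with equal
#' weight per trial and returns the symbol-by-electrode-by-sample mean
#' tensor.
#'
#' @param epochs A selected [epoch_collection()].
#' @return A `selected_tensor`: list with `data` (array ns x ne x l),
#'   `words`, `symbols`, `electrodes`, `times` (ms), `fs` and `provenance`
#'   (trial counts per symbol).
#' @export
average_selected <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_collection"))
  info <- epochs$info
  ord <- order(info$symbol)
  syms <- unique(info$symbol[ord])
  words <- info$word[ord][!duplicated(info$symbol[ord])]
  d <- dim(epochs$data)
  out <- array(0, c(length(syms), d[2], d[3]))
  counts <- integer(length(syms))
  for (s in seq_along(syms)) {
    idx <- which(info$symbol == syms[s])
    counts[s] <- length(idx)
    sl <- epochs$data[idx, , , drop = FALSE]
    out[s, , ] <- colMeans(sl, dims = 1)
  }
  structure(
    list(data = out, words = words, symbols = syms,
         electrodes = epochs$electrodes, times = epoch_times(epochs),
         fs = epochs$fs,
         provenance = tibble::tibble(symbol = syms, word = words,
                                     n_trials = counts)),
    class = "selected_tensor"
  )
}

#' @export
print.selected_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<selected_tensor> %d symbols x %d electrodes x %d samples\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Restrict a selected tensor to a time window
#'
#' Sample `k` (at time `t_k` ms) is kept iff `start <= t_k < end`.
#'
#' @param x A `selected_tensor`.
#' @param window Length-2 half-open window in ms.
#' @return The restricted `selected_tensor`.
#' @export
select_window <- function(x, window) {
  stopifnot(inherits(x, "selected_tensor"), length(window) == 2L)
  keep <- which(x$times >= window[1] & x$times < window[2])
  if (length(keep) == 0L) {
    stop(sprintf("window [%g, %g) ms contains no samples.",
                 window[1], window[2]), call. = FALSE)
  }
  x$data <- x$data[, , keep, drop = FALSE]
  x$times <- x$times[keep]
  x
}

#' Restrict a selected tensor to an electrode group
#'
#' @param x A `selected_tensor`.
#' @param electrodes Electrode names (or indices) to keep.
#' @return The restricted `selected_tensor`.
#' @export
select_electrodes <- function(x, electrodes) {
  stopifnot(inherits(x, "selected_tensor"))
  if (is.character(electrodes)) {
    idx <- match(electrodes, x$electrodes)
    if (anyNA(idx)) {
      stop("unknown electrode(s): ",
           paste(electrodes[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- electrodes
  }
  if (length(idx) == 0L) stop("empty electrode selection.", call. = FALSE)
  x$data <- x$data[, idx, , drop = FALSE]
  x$electrodes <- x$electrodes[idx]
  x
}

#' Flatten a selected tensor into a design matrix
#'
#' Reshapes the symbol-by-electrode-by-sample tensor into a matrix with one
#' row per symbol and `ne * l` columns in electrode-major, time-minor order:
#' all samples of electrode 1, then all samples of electrode 2, and so on.
#'
#' @param x A `selected_tensor`.
#' @return A numeric matrix (rows labelled by word) with attributes
#'   `electrodes` and `times` recording the feature layout.
#' @export
flatten <- function(x) {
  stopifnot(inherits(x, "selected_tensor"))
  d <- dim(x$data)
  X <- matrix(aperm(x$data, c(1, 3, 2)), nrow = d[1])
  rownames(X) <- x$words
  colnames(X) <- paste0(rep(x$electrodes, each = d[3]), "@",
                        rep(x$times, times = d[2]))
  attr(X, "electrodes") <- x$electrodes
  attr(X, "times") <- x$times
  X
}
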