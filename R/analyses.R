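# The four orchestrated analyses: whole-window semantic decoding, the
# sliding-window time course, onset-of-acquisition over exposure triples,
# and the electrode-group searchlight.

# Draw the permutation index matrix used by an analysis run (one row per
# permutation). All units of a run share these draws, which keeps their
# null distributions comparable and the run reproducible from one seed.
draw_perms <- function(n, n_perm, seed) {
  with_seed(seed, {
    matrix(replicate(n_perm, sample.int(n)), nrow = n_perm, byrow = TRUE)
  })
}

prepare_selected <- function(epochs, vectors, config, trial_window = NULL) {
  sel <- select_trials(epochs, config$min_exposures, config$drop_first,
                       trial_window = trial_window)
  avg <- average_selected(sel)
  y <- align_vectors(vectors, avg$words)
  list(avg = avg, y = y)
}

#' Whole-window semantic decoding analysis
#'
#' Tests whether EEG recorded while the symbol is on screen predicts the
#' word vector of its mapped word: selects trials (symbols with at least
#' `min_exposures` presentations, first `drop_first` exposures dropped),
#' averages them per symbol, restricts to `window_ms` (default 0--500 ms,
#' before the word choices appear), flattens to a design matrix and runs the
#' leave-two-out 2 vs. 2 evaluation with a permutation test.
#'
#' @param epochs A preprocessed [epoch_collection()] (trimmed,
#'   baseline-corrected, artifact-rejected).
#' @param vectors Word vectors covering the epoch words.
#' @param config A [run_config()].
#' @return A one-row `semantic_report` tibble: `window_start`, `window_end`,
#'   `n_symbols`, `n_features`, `accuracy`, `p`, `significant`. The
#'   permutation result travels in the report attributes
#'   (see [report_meta()]).
#' @export
run_semantic_analysis <- function(epochs, vectors, config = run_config()) {
  prep <- prepare_selected(epochs, vectors, config)
  win <- select_window(prep$avg, config$window_ms)
  X <- flatten(win)
  op <- loto_operator(X, config$alpha)
  observed <- loto_apply(op, prep$y)$accuracy
  perms <- draw_perms(nrow(X), config$n_perm, config$seed)
  null <- perm_null(op, prep$y, perms)
  p <- (1 + sum(null >= observed)) / (1 + config$n_perm)
  new_report(
    tibble::tibble(
      window_start = config$window_ms[1], window_end = config$window_ms[2],
      n_symbols = nrow(X), n_features = ncol(X),
      accuracy = observed, p = p, significant = p <= config$fdr_alpha
    ),
    "semantic", config,
    extra = list(null = null)
  )
}

#' Sliding-window time course of decoding accuracy
#'
#' Evaluates the decoding pipeline on consecutive short windows (default
#' 50 ms long, advancing by 25 ms) across the epoch, giving one 2 vs. 2
#' accuracy and permutation p-value per window, with
#' Benjamini-Hochberg-Yekutieli correction across windows. Permutation
#' draws are shared across windows.
#'
#' @param epochs A preprocessed [epoch_collection()].
#' @param vectors Word vectors covering the epoch words.
#' @param window_len Window length in ms (default 50).
#' @param step Step between window starts in ms (default 25).
#' @param config A [run_config()].
#' @return A `timecourse_report` tibble ordered by window start:
#'   `window_start`, `window_end`, `accuracy`, `p`, `significant`.
#' @export
run_timecourse <- function(epochs, vectors, window_len = 50, step = 25,
                           config = run_config()) {
  prep <- prepare_selected(epochs, vectors, config)
  t0 <- min(prep$avg$times)
  span_end <- max(prep$avg$times) + 1000 / prep$avg$fs
  if (window_len > span_end - t0) {
    stop("`window_len` exceeds the epoch time span.", call. = FALSE)
  }
  starts <- seq(t0, span_end - window_len, by = step)
  perms <- draw_perms(length(prep$avg$words), config$n_perm, config$seed)
  rows <- purrr::map(starts, function(st) {
    X <- flatten(select_window(prep$avg, c(st, st + window_len)))
    op <- loto_operator(X, config$alpha)
    observed <- loto_apply(op, prep$y)$accuracy
    null <- perm_null(op, prep$y, perms)
    tibble::tibble(
      window_start = st, window_end = st + window_len,
      accuracy = observed,
      p = (1 + sum(null >= observed)) / (1 + config$n_perm)
    )
  }) |> dplyr::bind_rows()
  rows$significant <- fdr_bhy(rows$p, config$fdr_alpha)
  new_report(rows, "timecourse", config,
             extra = list(window_len = window_len, step = step,
                          n_symbols = length(prep$avg$words)))
}

#' Onset-of-acquisition analysis over exposure triples
#'
#' Asks from which exposure onward the semantic mapping is decodable:
#' averages overlapping triples of exposures (1--3, 2--4, 3--5, 4--6 by
#' default) drawn from the first six presentations of each symbol, decodes
#' each average in each time window (0--500 and 0--700 ms by default), and
#' bootstrap-compares the first and last triple per time window.
#'
#' @param epochs A preprocessed [epoch_collection()].
#' @param vectors Word vectors covering the epoch words.
#' @param config A [run_config()].
#' @param trial_windows List of inclusive exposure ranges (default the four
#'   overlapping triples of the first six exposures).
#' @param time_windows List of half-open ms windows (default
#'   `list(c(0, 500), c(0, 700))`).
#' @return An `onset_report` tibble with one row per (trial window, time
#'   window) cell: `trial_start`, `trial_end`, `window_start`, `window_end`,
#'   `n_symbols`, `accuracy`, `p`, `significant` (BY-FDR across cells).
#'   The bootstrap comparisons between the first and last trial window (one
#'   per time window) are in the report attributes as `bootstrap`.
#' @export
run_onset <- function(epochs, vectors, config = run_config(),
                      trial_windows = list(c(1, 3), c(2, 4), c(3, 5),
                                           c(4, 6)),
                      time_windows = list(c(0, 500), c(0, 700))) {
  preps <- lapply(trial_windows, function(tw) {
    prepare_selected(epochs, vectors, config, trial_window = tw)
  })
  # artifact rejection can empty a symbol's trials in one window but not
  # another; restrict all windows to the common surviving symbol set
  words <- Reduce(intersect, lapply(preps, function(pr) pr$avg$words))
  if (length(words) < 3L) {
    stop("fewer than 3 symbols survive all trial windows.", call. = FALSE)
  }
  preps <- lapply(preps, function(pr) {
    idx <- match(words, pr$avg$words)
    pr$avg$data <- pr$avg$data[idx, , , drop = FALSE]
    pr$avg$words <- pr$avg$words[idx]
    pr$avg$symbols <- pr$avg$symbols[idx]
    pr$y <- pr$y[idx, , drop = FALSE]
    pr
  })
  y <- preps[[1]]$y
  perms <- draw_perms(length(words), config$n_perm, config$seed)

  designs <- list()
  rows <- list()
  k <- 0L
  for (ti in seq_along(trial_windows)) {
    for (wi in seq_along(time_windows)) {
      tw <- trial_windows[[ti]]; w <- time_windows[[wi]]
      X <- flatten(select_window(preps[[ti]]$avg, w))
      designs[[paste(ti, wi)]] <- X
      op <- loto_operator(X, config$alpha)
      observed <- loto_apply(op, y)$accuracy
      null <- perm_null(op, y, perms)
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        trial_start = tw[1], trial_end = tw[2],
        window_start = w[1], window_end = w[2],
        n_symbols = length(words), accuracy = observed,
        p = (1 + sum(null >= observed)) / (1 + config$n_perm)
      )
    }
  }
  rows <- dplyr::bind_rows(rows)
  rows$significant <- fdr_bhy(rows$p, config$fdr_alpha)

  first <- 1L; last <- length(trial_windows)
  boots <- lapply(seq_along(time_windows), function(wi) {
    bootstrap_accuracy_diff(
      designs[[paste(first, wi)]], designs[[paste(last, wi)]], y,
      alpha = config$alpha, B_boot = config$B_boot, seed = config$seed
    )
  })
  boot_tbl <- dplyr::bind_rows(lapply(seq_along(time_windows), function(wi) {
    b <- boots[[wi]]
    tibble::tibble(
      window_start = time_windows[[wi]][1],
      window_end = time_windows[[wi]][2],
      accuracy_first = b$accuracy_a, accuracy_last = b$accuracy_b,
      diff = b$diff, ci_low = b$ci[1], ci_high = b$ci[2], p = b$p
    )
  }))
  new_report(rows, "onset", config,
             extra = list(bootstrap = boot_tbl, comparisons = boots))
}

#' Electrode-group searchlight analysis
#'
#' Localizes decodable semantic information: for every electrode, decoding
#' is restricted to the group formed by that electrode and its immediate
#' montage neighbors, per time window (0--500, 500--1000 and 0--1000 ms by
#' default). Permutation draws are shared across groups and windows;
#' BY-FDR is applied across groups within each window. The group accuracy is
#' annotated to the central electrode together with its layout coordinates,
#' so the report doubles as a topography table.
#'
#' @param epochs A preprocessed [epoch_collection()].
#' @param vectors Word vectors covering the epoch words.
#' @param montage A [montage()] covering the epoch electrodes.
#' @param config A [run_config()].
#' @param time_windows List of half-open ms windows (default the three
#'   windows 0--500, 500--1000, 0--1000).
#' @return A `searchlight_report` tibble with one row per (electrode, time
#'   window): `electrode`, `x`, `y`, `window_start`, `window_end`,
#'   `n_channels`, `accuracy`, `p`, `significant`.
#' @export
run_searchlight <- function(epochs, vectors, montage = montage_1020_32(),
                            config = run_config(),
                            time_windows = list(c(0, 500), c(500, 1000),
                                                c(0, 1000))) {
  stopifnot(inherits(montage, "montage"))
  missing <- setdiff(epochs$electrodes, montage$electrodes)
  if (length(missing) > 0L) {
    stop("montage does not cover electrode(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prep <- prepare_selected(epochs, vectors, config)
  perms <- draw_perms(length(prep$avg$words), config$n_perm, config$seed)

  out <- list()
  k <- 0L
  for (w in time_windows) {
    wavg <- select_window(prep$avg, w)
    res <- purrr::map(seq_along(epochs$electrodes), function(ei) {
      e <- epochs$electrodes[ei]
      group <- intersect(c(e, montage$neighbors[[e]]), epochs$electrodes)
      X <- flatten(select_electrodes(wavg, group))
      op <- loto_operator(X, config$alpha)
      observed <- loto_apply(op, prep$y)$accuracy
      null <- perm_null(op, prep$y, perms)
      mi <- match(e, montage$electrodes)
      tibble::tibble(
        electrode = e, x = montage$x[mi], y = montage$y[mi],
        window_start = w[1], window_end = w[2],
        n_channels = length(group), accuracy = observed,
        p = (1 + sum(null >= observed)) / (1 + config$n_perm)
      )
    }) |> dplyr::bind_rows()
    res$significant <- fdr_bhy(res$p, config$fdr_alpha)
    k <- k + 1L
    out[[k]] <- res
  }
  new_report(dplyr::bind_rows(out), "searchlight", config,
             extra = list(n_symbols = length(prep$avg$words)))
}
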