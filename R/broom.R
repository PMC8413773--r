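# Broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a 2 vs. 2 result
#'
#' @param x A `two_vs_two_result` from [evaluate_loto()].
#' @param ... Unused.
#' @return `tidy()`: the per-pair outcome tibble. `glance()`: a one-row
#'   summary with the accuracy.
#' @export
tidy.two_vs_two_result <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.two_vs_two_result
#' @export
glance.two_vs_two_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_pairs = nrow(x$pairs),
                 n_symbols = x$n_symbols, alpha = x$alpha)
}

#' Tidy a ridge model
#'
#' @param x A `ridge_model` from [fit_ridge()].
#' @param ... Unused.
#' @return `tidy()`: a long tibble of weights (`feature`, `dimension`,
#'   `weight`). `glance()`: one-row summary.
#' @export
tidy.ridge_model <- function(x, ...) {
  W <- x$W
  tibble::tibble(
    feature = rep(rownames(W) %||% as.character(seq_len(nrow(W))),
                  times = ncol(W)),
    dimension = rep(seq_len(ncol(W)), each = nrow(W)),
    weight = as.vector(W)
  )
}

#' @rdname tidy.ridge_model
#' @export
glance.ridge_model <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$W), v = ncol(x$W), alpha = x$alpha,
                 centered = x$center, standardized = x$standardize)
}

#' Tidy a permutation result
#'
#' @param x A `permutation_result` from [permutation_test()].
#' @param ... Unused.
#' @return `tidy()`: one row per permutation (`perm`, `accuracy`).
#'   `glance()`: observed accuracy, p-value and null summary.
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(perm = seq_along(x$null), accuracy = x$null)
}

#' @rdname tidy.permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(observed = x$observed, p = x$p, n_perm = x$n_perm,
                 null_mean = mean(x$null), null_sd = stats::sd(x$null))
}

#' Tidy a bootstrap accuracy comparison
#'
#' @param x A `bootstrap_comparison` from [bootstrap_accuracy_diff()].
#' @param ... Unused.
#' @return `tidy()`: one row per replicate (`replicate`, `diff`).
#'   `glance()`: the observed accuracies, difference, CI and p-value.
#' @export
tidy.bootstrap_comparison <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicates), diff = x$replicates)
}

#' @rdname tidy.bootstrap_comparison
#' @export
glance.bootstrap_comparison <- function(x, ...) {
  tibble::tibble(accuracy_a = x$accuracy_a, accuracy_b = x$accuracy_b,
                 diff = x$diff, ci_low = x$ci[1], ci_high = x$ci[2],
                 sd_boot = x$sd_boot, p = x$p, B_boot = x$B_boot)
}
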