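#' Permutation test of 2 vs. 2 accuracy
#'
#' Builds the null distribution by shuffling the symbol-to-word-vector row
#' assignment and re-running the full leave-two-out 2 vs. 2 evaluation for
#' each shuffle (the design matrix, and hence the precomputed leave-two-out
#' operator, is unchanged by the shuffle). The p-value uses the add-one
#' estimator `p = (1 + #{null >= observed}) / (1 + n_perm)`, so it is never
#' exactly zero.
#'
#' @param x Design matrix (symbols x features).
#' @param y Word vectors, row-aligned with `x`.
#' @param alpha Ridge regularization (default 0.1).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `permutation_result`: `observed`, `null` (length `n_perm`),
#'   `p`, `n_perm`, `seed`.
#' @export
permutation_test <- function(x, y, alpha = 0.1, n_perm = 1000, seed = 1L) {
  stop_if_not_scalar_number(n_perm, "n_perm", 1)
  op <- loto_operator(as.matrix(x), alpha)
  y <- as.matrix(y)
  observed <- loto_apply(op, y)$accuracy
  perms <- with_seed(seed, {
    matrix(replicate(n_perm, sample.int(op$n)), nrow = n_perm, byrow = TRUE)
  })
  null <- perm_null(op, y, perms)
  structure(
    list(observed = observed, null = null,
         p = (1 + sum(null >= observed)) / (1 + n_perm),
         n_perm = as.integer(n_perm), seed = seed),
    class = "permutation_result"
  )
}

# Null accuracies for a fixed operator under given row permutations of y
# (one permutation per row of `perms`).
perm_null <- function(op, y, perms) {
  vapply(seq_len(nrow(perms)), function(b) {
    loto_apply(op, y[perms[b, ], , drop = FALSE])$accuracy
  }, 0)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed = %.4f, null mean = %.4f, p = %.4g (%d permutations)\n",
    x$observed, mean(x$null), x$p, x$n_perm))
  invisible(x)
}

#' Benjamini-Hochberg-Yekutieli false-discovery-rate control
#'
#' Step-up procedure valid under arbitrary dependence: with `m` p-values
#' sorted ascending, reject the `k` smallest where `k` is the largest `i`
#' such that `p_(i) <= i * alpha / (m * c(m))`, with the harmonic correction
#' `c(m) = sum_{i=1..m} 1/i`.
#'
#' @param p Vector of p-values in (0, 1].
#' @param alpha Target false discovery rate (default 0.05).
#' @return Logical rejection mask aligned with `p` (empty input gives an
#'   empty mask).
#' @export
#' @examples
#' fdr_bhy(c(0.005, 0.02, 0.5), alpha = 0.05)
fdr_bhy <- function(p, alpha = 0.05) {
  m <- length(p)
  if (m == 0L) return(logical(0))
  stopifnot(all(p > 0 & p <= 1))
  o <- order(p)
  cm <- sum(1 / seq_len(m))
  thresh <- seq_len(m) * alpha / (m * cm)
  below <- which(p[o] <= thresh)
  mask <- logical(m)
  if (length(below) > 0L) {
    mask[o[seq_len(max(below))]] <- TRUE
  }
  mask
}

#' Bootstrap comparison of 2 vs. 2 accuracies between two conditions
#'
#' Compares the leave-two-out 2 vs. 2 accuracy of two design matrices over
#' the same symbols (e.g., EEG averaged over early versus late exposures).
#' Symbols are the resampling unit: each bootstrap replicate draws symbols
#' with replacement, recomputes both accuracies restricted to the resampled
#' symbols' pairs (pairs of identical symbols are skipped; replicates with
#' fewer than 3 distinct symbols are redrawn) and takes the difference.
#' A normal-theory confidence interval and two-sided p-value are derived
#' from the bootstrap standard deviation.
#'
#' @param x_a,x_b Design matrices for conditions A and B, row-aligned with
#'   `y` and with each other.
#' @param y Word vectors shared by both conditions.
#' @param alpha Ridge regularization (default 0.1).
#' @param B_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf_level Confidence level of the normal-theory interval
#'   (default 0.95).
#' @return A `bootstrap_comparison`: observed accuracies, `diff`
#'   (B minus A), `replicates`, `ci` (length 2), `p`.
#' @export
bootstrap_accuracy_diff <- function(x_a, x_b, y, alpha = 0.1, B_boot = 1000,
                                    seed = 1L, conf_level = 0.95) {
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b); y <- as.matrix(y)
  n <- nrow(y)
  stopifnot(nrow(x_a) == n, nrow(x_b) == n)
  res_a <- evaluate_loto(x_a, y, alpha)
  res_b <- evaluate_loto(x_b, y, alpha)
  Oa <- outcome_matrix(res_a)
  Ob <- outcome_matrix(res_b)
  pairs <- utils::combn(n, 2L)
  pi_ <- pairs[1L, ]; pj_ <- pairs[2L, ]
  reps <- with_seed(seed, {
    t(vapply(seq_len(B_boot), function(b) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        if (length(unique(idx)) >= 3L) break
      }
      ii <- idx[pi_]; jj <- idx[pj_]
      keep <- ii != jj
      cells <- cbind(ii[keep], jj[keep])
      c(mean(Oa[cells]), mean(Ob[cells]))
    }, c(0, 0)))
  })
  diffs <- reps[, 2] - reps[, 1]
  observed <- res_b$accuracy - res_a$accuracy
  sd_boot <- stats::sd(diffs)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (sd_boot == 0) {
    if (observed == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(observed) / sd_boot)
  }
  structure(
    list(accuracy_a = res_a$accuracy, accuracy_b = res_b$accuracy,
         diff = observed, replicates = diffs,
         ci = c(observed - z * sd_boot, observed + z * sd_boot),
         sd_boot = sd_boot, p = p, B_boot = as.integer(B_boot), seed = seed,
         conf_level = conf_level),
    class = "bootstrap_comparison"
  )
}

# Symmetric per-pair outcome matrix from a two_vs_two_result.
outcome_matrix <- function(res) {
  n <- res$n_symbols
  O <- matrix(NA_real_, n, n)
  O[cbind(res$pairs$i, res$pairs$j)] <- res$pairs$outcome
  O[cbind(res$pairs$j, res$pairs$i)] <- res$pairs$outcome
  O
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_comparison> acc A = %.4f, acc B = %.4f, diff = %+.4f\n",
    x$accuracy_a, x$accuracy_b, x$diff))
  cat(sprintf("  %d%% normal-theory CI [%.4f, %.4f], p = %.4g (%d replicates)\n",
              round(100 * x$conf_level), x$ci[1], x$ci[2], x$p, x$B_boot))
  invisible(x)
}
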