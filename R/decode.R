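#' Fit per-dimension ridge regression from EEG features to word vectors
#'
#' Solves, independently for each embedding dimension `i`,
#' `min_w ||X w - Y[, i]||^2 + alpha ||w||^2` in closed form. Columns of `X`
#' and `Y` are centered on the training data in lieu of an intercept (the
#' centers are stored for prediction). When the feature count exceeds the
#' sample count the solution is computed through the n-by-n dual (Gram)
#' formulation `W = X' (X X' + alpha I)^{-1} Y`, which is algebraically equal
#' to the primal normal-equations solution.
#'
#' @param x Design matrix (symbols x features).
#' @param y Word-vector matrix (symbols x dimensions), row-aligned with `x`.
#' @param alpha Regularization strength, strictly positive (default 0.1).
#' @param center Center the columns of `x` and `y` on the training data
#'   (default `TRUE`).
#' @param standardize Additionally scale `x` columns to unit standard
#'   deviation (default `FALSE`; constant columns are left unscaled).
#' @return A `ridge_model` with weights `W`, the centers/scales and `alpha`.
#' @export
fit_ridge <- function(x, y, alpha = 0.1, center = TRUE, standardize = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a single number > 0.", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in `x` or `y`.", call. = FALSE)
  }
  if (nrow(x) != nrow(y)) {
    stop("`x` and `y` must have the same number of rows.", call. = FALSE)
  }
  n <- nrow(x); p <- ncol(x)
  x_center <- if (center) colMeans(x) else rep(0, p)
  y_center <- if (center) colMeans(y) else rep(0, ncol(y))
  Xc <- sweep(x, 2, x_center)
  Yc <- sweep(y, 2, y_center)
  x_scale <- rep(1, p)
  if (standardize) {
    s <- apply(Xc, 2, stats::sd)
    x_scale <- ifelse(s > 0, s, 1)
    Xc <- sweep(Xc, 2, x_scale, "/")
  }
  W <- if (p <= n) {
    solve(crossprod(Xc) + diag(alpha, p), crossprod(Xc, Yc))
  } else {
    crossprod(Xc, solve(tcrossprod(Xc) + diag(alpha, n), Yc))
  }
  structure(
    list(W = W, alpha = alpha, x_center = x_center, y_center = y_center,
         x_scale = x_scale, center = center, standardize = standardize),
    class = "ridge_model"
  )
}

#' Predict word vectors from new EEG features
#'
#' @param object A `ridge_model` from [fit_ridge()].
#' @param newdata Feature matrix with the training column count.
#' @param ... Unused.
#' @return Matrix of predicted word vectors, one row per input row.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_center)) {
    stop(sprintf("`newdata` has %d columns; the model was trained on %d.",
                 ncol(newdata), length(object$x_center)), call. = FALSE)
  }
  Xc <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  sweep(Xc %*% object$W, 2, object$y_center, "+")
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> %d features -> %d dimensions, alpha = %g\n",
              nrow(x$W), ncol(x$W), x$alpha))
  invisible(x)
}

# Row-wise cosine distance between two matrices (or vectors).
# Zero-norm rows get distance 1, with a warning.
cosine_distance <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  zero <- na == 0 | nb == 0
  if (any(zero)) {
    warning("zero-norm vector in cosine distance; distance set to 1.",
            call. = FALSE)
  }
  d <- 1 - rowSums(a * b) / (na * nb)
  d[zero] <- 1
  d
}

#' Score one 2 vs. 2 comparison
#'
#' The test passes (outcome 1) when the summed cosine distances of the
#' correctly matched true/predicted pairs are smaller than those of the
#' mismatched assignment, fails (0) when larger, and scores 0.5 on an exact
#' tie.
#'
#' @param y_i,y_j True word vectors.
#' @param yhat_i,yhat_j Predicted word vectors.
#' @return 0, 0.5 or 1.
#' @export
two_vs_two_pair <- function(y_i, y_j, yhat_i, yhat_j) {
  lens <- lengths(list(y_i, y_j, yhat_i, yhat_j))
  if (length(unique(lens)) != 1L) {
    stop("all four vectors must have the same dimension.", call. = FALSE)
  }
  matched <- cosine_distance(y_i, yhat_i) + cosine_distance(y_j, yhat_j)
  mismatched <- cosine_distance(y_i, yhat_j) + cosine_distance(y_j, yhat_i)
  if (matched < mismatched) 1 else if (matched > mismatched) 0 else 0.5
}

#' Precompute the leave-two-out prediction operator
#'
#' For every unordered pair of rows, fitting centered ridge regression on the
#' remaining rows and predicting the two held-out rows is a linear map of the
#' target matrix `Y`. This function precomputes that map from the Gram matrix
#' of `X` alone, so the full 2 vs. 2 evaluation for any `Y` (in particular
#' for the shuffled targets of a permutation test) costs one matrix product.
#'
#' @param x Design matrix (symbols x features), at least 3 rows.
#' @param alpha Ridge regularization (default 0.1).
#' @return A `loto_operator` list used by [evaluate_loto()] and the
#'   permutation machinery.
#' @export
loto_operator <- function(x, alpha = 0.1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 symbols for leave-two-out.", call. = FALSE)
  stopifnot(is.numeric(alpha), alpha > 0)
  K <- tcrossprod(x)
  pairs <- utils::combn(n, 2L)
  P <- ncol(pairs)
  H <- matrix(0, 2L * P, n)
  s <- numeric(2L * P)
  all_idx <- seq_len(n)
  ones <- rep(1, n - 2L)
  for (p in seq_len(P)) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    tr <- all_idx[-c(i, j)]
    Kt <- K[tr, tr]
    rM <- rowMeans(Kt)
    mAll <- mean(rM)
    # Gram matrix of the fold-centered training features
    Kc <- Kt - outer(rM, ones) - outer(ones, rM) + mAll
    kn <- K[c(i, j), tr, drop = FALSE]
    knc <- kn - rowMeans(kn) -
      matrix(rM, 2L, n - 2L, byrow = TRUE) + mAll
    h <- t(solve(Kc + diag(alpha, n - 2L), t(knc)))
    H[c(2L * p - 1L, 2L * p), tr] <- h
    s[c(2L * p - 1L, 2L * p)] <- rowSums(h)
  }
  structure(
    list(H = H, s = s, i = pairs[1L, ], j = pairs[2L, ], n = n,
         alpha = alpha, words = rownames(x)),
    class = "loto_operator"
  )
}

# Fast 2 vs. 2 evaluation of a precomputed operator against targets Y.
# Returns accuracy, per-pair outcomes and distances; optionally predictions.
loto_apply <- function(op, y, keep_predictions = FALSE) {
  y <- as.matrix(y)
  stopifnot(nrow(y) == op$n)
  n <- op$n
  P <- length(op$i)
  odd <- seq(1L, 2L * P, by = 2L)
  even <- odd + 1L
  P0 <- op$H %*% y
  tot <- colSums(y)
  ybar <- (matrix(tot, P, ncol(y), byrow = TRUE) -
             y[op$i, , drop = FALSE] - y[op$j, , drop = FALSE]) / (n - 2)
  pred_i <- P0[odd, , drop = FALSE] + (1 - op$s[odd]) * ybar
  pred_j <- P0[even, , drop = FALSE] + (1 - op$s[even]) * ybar
  yi <- y[op$i, , drop = FALSE]
  yj <- y[op$j, , drop = FALSE]
  matched <- cosine_distance(yi, pred_i) + cosine_distance(yj, pred_j)
  mismatched <- cosine_distance(yi, pred_j) + cosine_distance(yj, pred_i)
  outcome <- 0.5 * ((matched < mismatched) - (matched > mismatched) + 1)
  res <- list(accuracy = mean(outcome), outcome = outcome,
              d_matched = matched, d_mismatched = mismatched)
  if (keep_predictions) {
    res$pred_i <- pred_i
    res$pred_j <- pred_j
  }
  res
}

#' Leave-two-out 2 vs. 2 evaluation
#'
#' For every unordered pair of symbols, fits ridge regression on the
#' remaining `ns - 2` rows, predicts the two held-out word vectors and
#' scores the pair with [two_vs_two_pair()]. The accuracy is the mean
#' outcome over all `choose(ns, 2)` pairs; chance is 0.5.
#'
#' The default `"gram"` engine precomputes the leave-two-out operator
#' ([loto_operator()]); the `"naive"` engine refits every fold with
#' [fit_ridge()]. Both produce the same result to numerical precision.
#'
#' @param x Design matrix (symbols x features).
#' @param y Word vectors (symbols x dims), row-aligned with `x`.
#' @param alpha Ridge regularization (default 0.1).
#' @param engine `"gram"` (default) or `"naive"`.
#' @param keep_predictions Keep the held-out predictions per pair.
#' @return A `two_vs_two_result`: list with `accuracy`, `pairs` (tibble of
#'   per-pair outcomes and distances), `n_symbols`, `alpha`, and optionally
#'   `predictions`.
#' @export
#' @examples
#' X <- matrix(rnorm(200), 10)
#' B <- matrix(rnorm(100), 20)
#' res <- evaluate_loto(X, X %*% B[1:20, 1:5], alpha = 1e-8)
#' res$accuracy
evaluate_loto <- function(x, y, alpha = 0.1,
                          engine = c("gram", "naive"),
                          keep_predictions = FALSE) {
  engine <- match.arg(engine)
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 symbols for leave-two-out.", call. = FALSE)
  if (nrow(y) != n) stop("`x` and `y` must be row-aligned.", call. = FALSE)
  words <- rownames(x) %||% as.character(seq_len(n))

  if (engine == "gram") {
    op <- loto_operator(x, alpha)
    r <- loto_apply(op, y, keep_predictions)
    ii <- op$i; jj <- op$j
  } else {
    pairs <- utils::combn(n, 2L)
    ii <- pairs[1L, ]; jj <- pairs[2L, ]
    P <- ncol(pairs)
    outcome <- d_matched <- d_mismatched <- numeric(P)
    pred_i <- pred_j <- matrix(NA_real_, P, ncol(y))
    for (p in seq_len(P)) {
      i <- ii[p]; j <- jj[p]
      fit <- fit_ridge(x[-c(i, j), , drop = FALSE],
                       y[-c(i, j), , drop = FALSE], alpha)
      pr <- predict(fit, x[c(i, j), , drop = FALSE])
      d_matched[p] <- cosine_distance(y[i, ], pr[1, ]) +
        cosine_distance(y[j, ], pr[2, ])
      d_mismatched[p] <- cosine_distance(y[i, ], pr[2, ]) +
        cosine_distance(y[j, ], pr[1, ])
      outcome[p] <- 0.5 * ((d_matched[p] < d_mismatched[p]) -
                             (d_matched[p] > d_mismatched[p]) + 1)
      pred_i[p, ] <- pr[1, ]; pred_j[p, ] <- pr[2, ]
    }
    r <- list(accuracy = mean(outcome), outcome = outcome,
              d_matched = d_matched, d_mismatched = d_mismatched)
    if (keep_predictions) {
      r$pred_i <- pred_i; r$pred_j <- pred_j
    }
  }

  out <- structure(
    list(
      accuracy = r$accuracy,
      pairs = tibble::tibble(
        i = ii, j = jj, word_i = words[ii], word_j = words[jj],
        outcome = r$outcome, d_matched = r$d_matched,
        d_mismatched = r$d_mismatched
      ),
      n_symbols = n, alpha = alpha, engine = engine
    ),
    class = "two_vs_two_result"
  )
  if (keep_predictions) {
    out$predictions <- list(pred_i = r$pred_i, pred_j = r$pred_j)
  }
  out
}

#' @export
print.two_vs_two_result <- function(x, ...) {
  cat(sprintf(
    "<two_vs_two_result> %d symbols, %d pairs, accuracy = %.4f (alpha = %g)\n",
    x$n_symbols, nrow(x$pairs), x$accuracy, x$alpha))
  invisible(x)
}
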