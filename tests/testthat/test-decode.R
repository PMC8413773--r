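test_that("ridge regression solves the penalized normal equations", {
  set.seed(1)
  # identity design, centering off: W = Y / (1 + alpha)
  Y <- matrix(rnorm(25), 5)
  fit <- fit_ridge(diag(5), Y, alpha = 0.3, center = FALSE)
  expect_equal(fit$W, Y / 1.3, tolerance = 1e-12)

  # extreme regularization shrinks the weights away
  X <- matrix(rnorm(200), 10)
  fit_big <- fit_ridge(X, Y[1:10 %% 5 + 1, ], alpha = 1e9)
  expect_lt(sqrt(sum(fit_big$W^2)), 1e-6 * sqrt(sum(Y^2)))

  # random instance vs the direct normal-equations oracle
  X <- matrix(rnorm(20 * 40), 20)
  Y2 <- matrix(rnorm(20 * 5), 20)
  fit2 <- fit_ridge(X, Y2, alpha = 0.1, center = FALSE)
  oracle <- solve(crossprod(X) + diag(0.1, 40), crossprod(X, Y2))
  expect_lt(max(abs(fit2$W - oracle)), 1e-8)

  # dual (features > samples) equals the primal solution, with centering
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y2, 2, colMeans(Y2))
  primal <- solve(crossprod(Xc) + diag(0.1, 40), crossprod(Xc, Yc))
  expect_lt(max(abs(fit_ridge(X, Y2, 0.1)$W - primal)), 1e-8)

  expect_error(fit_ridge(X, Y2, alpha = 0), "> 0")
  expect_error(fit_ridge(X, Y2, alpha = -1), "> 0")
  X_bad <- X; X_bad[1, 1] <- NA
  expect_error(fit_ridge(X_bad, Y2, 0.1), "non-finite")
})

test_that("prediction is linear, centered and dimension-checked", {
  set.seed(2)
  X <- matrix(rnorm(12 * 12), 12)   # square, almost surely invertible
  Y <- matrix(rnorm(12 * 3), 12)
  fit <- fit_ridge(X, Y, alpha = 1e-10)
  # near-interpolation at vanishing alpha on a full-rank training set
  expect_equal(predict(fit, X), Y, tolerance = 1e-5)
  # batch prediction equals row-by-row prediction
  one_by_one <- do.call(rbind, lapply(seq_len(nrow(X)), function(i) {
    predict(fit, X[i, , drop = FALSE])
  }))
  expect_equal(predict(fit, X), one_by_one, tolerance = 1e-12)
  # a zero-variance feature contributes nothing after centering
  Xz <- cbind(X, 7)
  fitz <- fit_ridge(Xz, Y, alpha = 0.1)
  base <- fit_ridge(X, Y, alpha = 0.1)
  expect_equal(predict(fitz, Xz), predict(base, X), tolerance = 1e-10)
  expect_error(predict(fit, X[, 1:3]), "columns")
})

test_that("the 2 vs. 2 comparison scores matches, swaps and ties", {
  y1 <- c(1, 0, 0); y2 <- c(0, 1, 0)
  expect_identical(two_vs_two_pair(y1, y2, y1, y2), 1)
  expect_identical(two_vs_two_pair(y1, y2, y2, y1), 0)
  expect_identical(two_vs_two_pair(y1, y2, c(1, 1, 0), c(1, 1, 0)), 0.5)
  # cosine distance ignores positive rescaling of any one vector
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5); pa <- rnorm(5); pb <- rnorm(5)
    expect_identical(two_vs_two_pair(a, b, pa, pb),
                     two_vs_two_pair(3.7 * a, b, pa, 0.2 * pb))
  }
  expect_error(two_vs_two_pair(y1, y2, y1, c(1, 2)), "dimension")
  # the zero-norm vector warns in both the matched and mismatched distance
  expect_warning(
    expect_warning(two_vs_two_pair(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                   "zero-norm"),
    "zero-norm")
})

test_that("random independent predictions are calibrated at one half", {
  set.seed(4)
  outs <- replicate(4000, {
    two_vs_two_pair(rnorm(8), rnorm(8), rnorm(8), rnorm(8))
  })
  expect_lt(abs(mean(outs) - 0.5), 2.576 * 0.5 / sqrt(4000))
})

test_that("leave-two-out evaluation covers all pairs and recovers noiseless maps", {
  set.seed(5)
  X <- matrix(rnorm(60 * 3), 60)
  Y <- matrix(rnorm(60 * 4), 60)
  res <- evaluate_loto(X, Y, alpha = 0.1)
  expect_identical(nrow(res$pairs), 1770L)   # choose(60, 2)
  expect_true(all(res$pairs$outcome %in% c(0, 0.5, 1)))
  expect_gte(res$accuracy, 0)
  expect_lte(res$accuracy, 1)

  # noiseless linear map with more symbols than features: exact recovery
  X2 <- matrix(rnorm(60 * 40), 60)
  B <- matrix(rnorm(40 * 10), 40)
  res2 <- evaluate_loto(X2, X2 %*% B, alpha = 1e-8)
  expect_equal(res2$accuracy, 1.0)

  # shuffled targets sit at chance on average
  set.seed(6)
  null_accs <- replicate(25, {
    evaluate_loto(X2, (X2 %*% B)[sample(60), ], alpha = 0.1)$accuracy
  })
  expect_lt(abs(mean(null_accs) - 0.5), 0.06)

  expect_error(evaluate_loto(X2[1:2, ], X2[1:2, 1:3]), "at least 3")
})

test_that("the cached Gram engine reproduces naive refitting", {
  set.seed(7)
  X <- matrix(rnorm(20 * 40), 20)
  Y <- matrix(rnorm(20 * 5), 20)
  g <- evaluate_loto(X, Y, alpha = 0.1, engine = "gram")
  n <- evaluate_loto(X, Y, alpha = 0.1, engine = "naive")
  expect_lt(max(abs(g$pairs$d_matched - n$pairs$d_matched)), 1e-10)
  expect_lt(max(abs(g$pairs$d_mismatched - n$pairs$d_mismatched)), 1e-10)
  expect_identical(g$pairs$outcome, n$pairs$outcome)
  expect_equal(g$accuracy, n$accuracy)

  # also when features < samples (primal branch of the naive path)
  Xs <- X[, 1:6]
  gs <- evaluate_loto(Xs, Y, alpha = 0.5, engine = "gram")
  ns <- evaluate_loto(Xs, Y, alpha = 0.5, engine = "naive")
  expect_lt(max(abs(gs$pairs$d_matched - ns$pairs$d_matched)), 1e-10)
})

test_that("accuracy is invariant under simultaneous row permutation", {
  set.seed(8)
  X <- matrix(rnorm(15 * 10), 15)
  Y <- matrix(rnorm(15 * 4), 15)
  base <- evaluate_loto(X, Y, alpha = 0.1)
  p <- sample(15)
  perm <- evaluate_loto(X[p, ], Y[p, ], alpha = 0.1)
  expect_equal(perm$accuracy, base$accuracy, tolerance = 1e-12)
})

test_that("tidy and glance summarize decoding objects", {
  set.seed(9)
  X <- matrix(rnorm(10 * 6), 10, dimnames = list(sprintf("w%02d", 1:10), NULL))
  Y <- matrix(rnorm(10 * 3), 10)
  res <- evaluate_loto(X, Y)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 45L)
  expect_identical(td$word_i[1], "w01")
  gl <- glance(res)
  expect_identical(gl$n_pairs, 45L)
  expect_equal(gl$accuracy, res$accuracy)

  fit <- fit_ridge(X, Y)
  expect_identical(nrow(tidy(fit)), 6L * 3L)
  expect_identical(glance(fit)$n_features, 6L)
})
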