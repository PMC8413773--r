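test_that("trimming keeps exactly one second after symbol onset", {
  # epochs spanning -1000..2000 ms at 250 Hz
  d <- array(rnorm(2 * 3 * 750), c(2, 3, 750))
  ep <- manual_epochs(d, fs = 250, t0_ms = -1000, words = c("w01", "w02"))
  tr <- trim_epochs(ep)
  expect_identical(dim(tr$data)[3], 250L)
  expect_equal(range(epoch_times(tr)), c(0, 996))
  expect_identical(tr$data[, , 1], d[, , 251])  # t = 0 ms sample
  expect_identical(trim_epochs(tr)$data, tr$data)  # idempotent

  ep100 <- manual_epochs(array(0, c(1, 2, 120)), fs = 100, t0_ms = -100,
                         words = "w01")
  expect_identical(dim(trim_epochs(ep100)$data)[3], 100L)

  short <- manual_epochs(array(0, c(1, 2, 100)), fs = 250, t0_ms = 0,
                         words = "w01")
  expect_error(trim_epochs(short), "1000")
})

test_that("baseline correction subtracts the pre-onset mean per electrode", {
  d <- array(0, c(2, 2, 300))  # -200..1000 ms at 250 Hz
  d[1, 1, ] <- 7                        # constant epoch -> all zero
  d[2, 1, 1:50] <- 5                    # baseline mean 5
  d[2, 1, 51:300] <- 12                 # post-onset 12 -> 7
  ep <- manual_epochs(d, fs = 250, t0_ms = -200, words = c("w01", "w02"))
  bc <- baseline_correct(ep)
  expect_true(all(bc$data[1, 1, ] == 0))
  expect_true(all(bc$data[2, 1, 51:300] == 7))
  expect_true(all(bc$data[2, 2, ] == 0))
  # after trimming the baseline span is gone
  expect_error(baseline_correct(trim_epochs(bc)), "not covered")
})

test_that("peak-to-peak and gradient rules reject exactly the contracted epochs", {
  l <- 250
  mk <- function(f) { d <- array(0, c(1, 2, l)); f(d) }
  collect <- function(mods) {
    d <- array(0, c(length(mods), 2, l))
    for (i in seq_along(mods)) d[i, , ] <- mods[[i]]
    manual_epochs(d, fs = 250, words = sprintf("w%02d", seq_along(mods)))
  }
  ramp <- function(lo, hi) {  # slow ramp: every step below the grad limit
    e <- matrix(0, 2, l); e[1, ] <- seq(lo, hi, length.out = l); e
  }
  jump <- function(delta) {   # one adjacent-sample step of `delta` uV
    e <- matrix(0, 2, l); e[2, 126:l] <- delta; e
  }
  ep <- collect(list(
    ramp(-51, 50),    # 101 uV p2p        -> rejected (p2p)
    ramp(-50, 50),    # 100 uV p2p        -> retained (not > limit)
    jump(41),         # 10.25 uV/ms       -> rejected (gradient)
    jump(39),         # 9.75 uV/ms        -> retained
    jump(40),         # exactly 10 uV/ms  -> retained (strict >)
    matrix(0, 2, l)   # all-zero          -> retained
  ))
  out <- reject_artifacts(ep)
  expect_identical(out$report$n_total, 6L)
  expect_identical(out$report$n_rejected, 2L)
  expect_identical(out$report$n_p2p, 1L)
  expect_identical(out$report$n_gradient, 1L)
  expect_equal(out$report$fraction_rejected, 2 / 6)
  expect_identical(out$epochs$info$word, c("w02", "w04", "w05", "w06"))

  # invariant to electrode order and to an appended all-zero electrode
  perm <- ep
  perm$data <- perm$data[, 2:1, , drop = FALSE]
  perm$electrodes <- perm$electrodes[2:1]
  expect_identical(reject_artifacts(perm)$report, out$report)
  aug <- ep
  newd <- array(0, c(6, 3, l))
  newd[, 1:2, ] <- ep$data
  aug$data <- newd
  aug$electrodes <- c(ep$electrodes, "Z")
  expect_identical(reject_artifacts(aug)$report, out$report)
})

test_that("rejection report matches the generator's ground-truth flags", {
  ds <- simulate_dataset(config = paradigm_config(n_blocks = 4),
                         n_participants = 2,
                         fwd = forward_model(gain = 2, artifact_rate = 0.2),
                         seed = 31)
  out <- reject_artifacts(ds$epochs)
  expect_identical(out$report$n_rejected,
                   sum(ds$epochs$info$artifact_injected))
  expect_false(any(out$epochs$info$artifact_injected))
})

test_that("trial selection follows the exposure-count rules", {
  # one participant; w01 seen 5x, w02 seen 7x
  n <- 12
  d <- array(seq_len(n * 2 * 10), c(n, 2, 10))
  words <- c(rep("w01", 5), rep("w02", 7))
  info <- tibble::tibble(
    participant = 1L, symbol = c(rep(1L, 5), rep(2L, 7)), word = words,
    exposure_index = c(1:5, 1:7), n_exposures = c(rep(5L, 5), rep(7L, 7))
  )
  ep <- epoch_collection(d, info, c("E01", "E02"), fs = 10, t0_ms = 0)

  sel <- select_trials(ep, min_exposures = 6, drop_first = 2)
  expect_false("w01" %in% sel$info$word)      # fewer than six presentations
  expect_identical(attr(sel, "excluded_symbols"), "w01")
  expect_identical(sel$info$exposure_index, 3:7)

  win <- select_trials(ep, min_exposures = 6, trial_window = c(4, 6))
  expect_identical(win$info$exposure_index, 4:6)
  expect_identical(unique(win$info$word), "w02")

  expect_error(select_trials(ep, min_exposures = 100), "every symbol")
})

test_that("averaging pools trials with equal weight across participants", {
  # two trials x and -x cancel
  d <- array(0, c(2, 2, 5))
  d[1, , ] <- matrix(1:10, 2)
  d[2, , ] <- -matrix(1:10, 2)
  ep <- manual_epochs(d, fs = 5, words = c("w01", "w01"),
                      exposure_index = 1:2)
  avg <- average_selected(ep)
  expect_equal(dim(avg$data), c(1, 2, 5))
  expect_true(all(avg$data == 0))

  # pooled mean against a brute-force sum/count oracle on a random fixture
  set.seed(88)
  n <- 30
  words <- sample(c("w01", "w02", "w03"), n, replace = TRUE)
  parts <- sample(1:3, n, replace = TRUE)
  d <- array(rnorm(n * 4 * 6), c(n, 4, 6))
  info <- tibble::tibble(participant = parts,
                         symbol = match(words, sort(unique(words))),
                         word = words, exposure_index = 1L,
                         n_exposures = 10L)
  ep <- epoch_collection(d, info, sprintf("E%02d", 1:4), fs = 6, t0_ms = 0)
  avg <- average_selected(ep)
  for (w in avg$words) {
    idx <- which(words == w)
    oracle <- apply(d[idx, , , drop = FALSE], c(2, 3), sum) / length(idx)
    expect_equal(avg$data[match(w, avg$words), , ], oracle,
                 tolerance = 1e-12)
  }

  # relabeling participants does not change the pooled mean
  ep2 <- ep
  ep2$info$participant <- ((ep2$info$participant + 1) %% 3) + 1
  expect_equal(average_selected(ep2)$data, avg$data)

  # mean of a single trial is that trial
  one <- manual_epochs(array(rnorm(8), c(1, 2, 4)), fs = 4, words = "w01")
  expect_equal(average_selected(one)$data[1, , ], one$data[1, , ])
})

test_that("window and electrode selection map ms to samples half-open", {
  ds <- tiny_dataset(gain = 0, seed = 3)
  avg <- average_selected(select_trials(ds$epochs, 1, 0))
  w1 <- select_window(avg, c(0, 500))
  expect_identical(length(w1$times), 125L)
  expect_equal(range(w1$times), c(0, 496))
  w2 <- select_window(avg, c(25, 75))
  expect_identical(length(w2$times), 12L)          # samples 7..18
  expect_equal(w2$times, seq(28, 72, by = 4))
  expect_error(select_window(avg, c(997, 998)), "no samples")

  g <- select_electrodes(avg, c("Cz", "Pz"))
  expect_identical(g$electrodes, c("Cz", "Pz"))
  expect_error(select_electrodes(avg, "Nope"), "Nope")

  # flatten: electrode-major, time-minor; full window is a no-op
  X_full <- flatten(avg)
  expect_identical(dim(X_full), c(length(avg$words), 32L * 250L))
  expect_identical(flatten(select_window(avg, c(0, 1000))), X_full)
  ne <- length(avg$electrodes); l <- length(avg$times)
  for (probe in list(c(2, 3, 10), c(1, 32, 250), c(3, 1, 1))) {
    s <- probe[1]; e <- probe[2]; k <- probe[3]
    expect_identical(X_full[s, (e - 1) * l + k], avg$data[s, e, k])
  }
})
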