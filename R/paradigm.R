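#' Configuration of the symbol-learning paradigm
#'
#' Describes the growing-vocabulary reinforcement-learning task: participants
#' learn a mapping from unfamiliar symbols to familiar words through trial and
#' error. The first block presents `initial_symbols` new symbols; every later
#' block introduces `added_per_block` new symbols and pairs them with
#' previously seen ones so that each block cycles through `initial_symbols`
#' symbols. A block ends once rolling response accuracy over the last
#' `mastery_window` trials reaches `mastery_threshold`.
#'
#' @param n_blocks Number of blocks (default 19).
#' @param initial_symbols Symbols in the first block, which is also the number
#'   of active symbols in every block (default 6).
#' @param added_per_block New symbols introduced in each block after the first
#'   (default 3).
#' @param n_choices Number of word choices displayed per trial (default 4):
#'   the correct word plus `n_choices - 1` distractors drawn without
#'   replacement from the other active words of the block.
#' @param mastery_threshold Rolling accuracy required to finish a block
#'   (default 0.9).
#' @param mastery_window Number of most recent trials the rolling accuracy is
#'   computed over (default 10).
#' @param max_exposures Maximum number of presentations of any one symbol
#'   across the whole experiment (default 20).
#' @param choice_onset_ms Time after symbol onset at which the word choices
#'   appear, in ms (default 500). Used only for annotation; epochs are aligned
#'   to symbol onset.
#' @param max_block_trials Safety cap on trials per block so that
#'   non-learning (random) responders terminate; capped blocks are flagged in
#'   the simulated behavior (default 200).
#'
#' @return A `paradigm_config` list.
#' @seealso [build_schedule()], [simulate_behavior()],
#'   [perfect_learner_first_trial_accuracy()]
#' @export
#' @examples
#' cfg <- paradigm_config()
#' n_symbols(cfg)
paradigm_config <- function(n_blocks = 19, initial_symbols = 6,
                            added_per_block = 3, n_choices = 4,
                            mastery_threshold = 0.9, mastery_window = 10,
                            max_exposures = 20, choice_onset_ms = 500,
                            max_block_trials = 200) {
  stop_if_not_scalar_number(n_blocks, "n_blocks", 1)
  stop_if_not_scalar_number(initial_symbols, "initial_symbols", 2)
  stop_if_not_scalar_number(added_per_block, "added_per_block", 1)
  stop_if_not_scalar_number(n_choices, "n_choices", 2)
  stop_if_not_scalar_number(max_exposures, "max_exposures", 1)
  stop_if_not_scalar_number(max_block_trials, "max_block_trials", 1)
  if (added_per_block >= initial_symbols) {
    stop("`added_per_block` must be smaller than the block size ",
         "(`initial_symbols`).", call. = FALSE)
  }
  if (n_choices > initial_symbols) {
    stop("`n_choices` cannot exceed the number of active symbols per block.",
         call. = FALSE)
  }
  if (!is.numeric(mastery_threshold) || mastery_threshold <= 0 ||
      mastery_threshold > 1) {
    stop("`mastery_threshold` must lie in (0, 1].", call. = FALSE)
  }
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      initial_symbols = as.integer(initial_symbols),
      added_per_block = as.integer(added_per_block),
      n_choices = as.integer(n_choices),
      mastery_threshold = mastery_threshold,
      mastery_window = as.integer(mastery_window),
      max_exposures = as.integer(max_exposures),
      choice_onset_ms = choice_onset_ms,
      max_block_trials = as.integer(max_block_trials)
    ),
    class = "paradigm_config"
  )
}

#' Total number of symbols introduced by a paradigm
#'
#' Closed form: `initial_symbols + (n_blocks - 1) * added_per_block`.
#'
#' @param config A [paradigm_config()].
#' @return Integer symbol count.
#' @export
n_symbols <- function(config) {
  stopifnot(inherits(config, "paradigm_config"))
  config$initial_symbols + (config$n_blocks - 1L) * config$added_per_block
}

#' Word labels used for the symbol lexicon
#'
#' Symbols are identified by integers 1..ns; the mapped words are labelled
#' `w01`, `w02`, ... The mapping is fixed (symbol k always means word k), as
#' in the task where the symbol-to-word assignment is constant across
#' participants.
#'
#' @param ns Number of symbols.
#' @return Character vector of word labels.
#' @export
symbol_words <- function(ns) {
  sprintf("w%02d", seq_len(ns))
}

#' Build the block schedule of a simulated participant
#'
#' Block 1 holds the `initial_symbols` first symbols, all new. Every later
#' block introduces the next `added_per_block` symbols and pairs them with
#' randomly chosen previously seen symbols so that each block cycles through
#' `initial_symbols` active symbols.
#'
#' @param config A [paradigm_config()].
#' @param seed Integer seed; the carried-symbol pairing is random.
#' @return A tibble with one row per (block, symbol): columns `block`,
#'   `symbol`, `word`, `is_new`.
#' @export
#' @examples
#' sched <- build_schedule(paradigm_config(), seed = 1)
#' dplyr::n_distinct(sched$symbol) # 60
build_schedule <- function(config, seed = 1L) {
  stopifnot(inherits(config, "paradigm_config"))
  ns <- n_symbols(config)
  words <- symbol_words(ns)
  n_carry <- config$initial_symbols - config$added_per_block
  with_seed(seed, {
    rows <- vector("list", config$n_blocks)
    introduced <- integer(0)
    next_id <- 1L
    for (b in seq_len(config$n_blocks)) {
      if (b == 1L) {
        new_ids <- seq_len(config$initial_symbols)
        carried <- integer(0)
      } else {
        new_ids <- next_id + seq_len(config$added_per_block) - 1L
        carried <- sample(introduced, n_carry)
      }
      next_id <- max(new_ids) + 1L
      introduced <- c(introduced, new_ids)
      ids <- c(new_ids, carried)
      rows[[b]] <- tibble::tibble(
        block = b,
        symbol = as.integer(ids),
        word = words[ids],
        is_new = c(rep(TRUE, length(new_ids)), rep(FALSE, length(carried)))
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' Learner models for behavior simulation
#'
#' Idealized response strategies used when simulating the task:
#' * `"perfect"` -- the learner knows a symbol's word from the trial after its
#'   `acquire_after`-th exposure onward (default 1: one exposure suffices,
#'   whether or not the guess on that exposure was correct). On trials where
#'   the mapping is unknown the learner eliminates displayed words already
#'   mapped to other known symbols and guesses uniformly among the rest.
#' * `"exposure_rate"` -- after each exposure the mapping is acquired with
#'   probability `acquisition_rate`; response strategy as above.
#' * `"random"` -- never acquires; always guesses with elimination
#'   unavailable (nothing is ever known).
#'
#' @param kind One of `"perfect"`, `"exposure_rate"`, `"random"`.
#' @param acquisition_rate Per-exposure acquisition probability
#'   (`"exposure_rate"` only).
#' @param acquire_after For `"perfect"`: number of exposures after which the
#'   mapping is known (default 1). Values above 1 delay acquisition, which is
#'   useful for planting a semantic signal from a known exposure onward.
#' @return A `learner_model` list.
#' @export
learner_model <- function(kind = c("perfect", "exposure_rate", "random"),
                          acquisition_rate = 0.3, acquire_after = 1L) {
  kind <- match.arg(kind)
  if (kind == "exposure_rate") {
    stopifnot(is.numeric(acquisition_rate), acquisition_rate >= 0,
              acquisition_rate <= 1)
  }
  stop_if_not_scalar_number(acquire_after, "acquire_after", 1)
  structure(
    list(kind = kind, acquisition_rate = acquisition_rate,
         acquire_after = as.integer(acquire_after)),
    class = "learner_model"
  )
}

#' Simulate the trial-by-trial behavior of one participant
#'
#' Within each block, symbols are drawn uniformly from the active set
#' (excluding symbols that have reached `max_exposures`). The choice set is
#' the correct word plus `n_choices - 1` distractors drawn without replacement
#' from the other active words. A block ends when rolling accuracy over the
#' last `mastery_window` trials reaches `mastery_threshold`, or at
#' `max_block_trials` (flagged in `block_capped`).
#'
#' @param schedule A schedule from [build_schedule()].
#' @param config The [paradigm_config()] the schedule was built from.
#' @param learner A [learner_model()].
#' @param seed Integer seed.
#' @param participant Participant identifier stored in the records.
#' @return A tibble of trial records: `participant`, `block`, `trial`
#'   (within block), `symbol`, `word`, `exposure_index` (1-based count of
#'   presentations of that symbol so far), `choices` (list column of the
#'   displayed words), `response`, `correct`, `acquired_before_trial`,
#'   `block_capped`.
#' @export
simulate_behavior <- function(schedule, config, learner = learner_model(),
                              seed = 1L, participant = 1L) {
  stopifnot(inherits(config, "paradigm_config"),
            inherits(learner, "learner_model"))
  ns <- n_symbols(config)
  words <- symbol_words(ns)
  with_seed(seed, {
    exposures <- integer(ns)
    acquired <- logical(ns)
    recs <- list()
    k <- 0L
    for (b in unique(schedule$block)) {
      block_syms <- schedule$symbol[schedule$block == b]
      correct_run <- logical(0)
      capped <- FALSE
      repeat {
        active <- block_syms[exposures[block_syms] < config$max_exposures]
        if (length(active) == 0L) break
        s <- if (length(active) == 1L) active else sample(active, 1L)
        others <- setdiff(block_syms, s)
        distract <- sample(others, config$n_choices - 1L)
        choice_syms <- sample(c(s, distract))
        acq_before <- acquired[s]
        if (acq_before) {
          resp_sym <- s
        } else {
          # eliminate displayed words whose (other-symbol) mapping is known
          cand <- choice_syms[!acquired[choice_syms]]
          if (length(cand) == 0L) cand <- choice_syms
          resp_sym <- if (length(cand) == 1L) cand else sample(cand, 1L)
        }
        exposures[s] <- exposures[s] + 1L
        k <- k + 1L
        recs[[k]] <- list(
          participant = participant, block = b,
          trial = length(correct_run) + 1L,
          symbol = s, word = words[s],
          exposure_index = exposures[s],
          choices = words[choice_syms],
          response = words[resp_sym],
          correct = resp_sym == s,
          acquired_before_trial = acq_before
        )
        correct_run <- c(correct_run, resp_sym == s)
        # learner update after feedback
        acquired[s] <- switch(
          learner$kind,
          perfect = exposures[s] >= learner$acquire_after,
          exposure_rate = acquired[s] ||
            stats::runif(1) < learner$acquisition_rate,
          random = FALSE
        )
        nt <- length(correct_run)
        if (nt >= config$mastery_window &&
            mean(correct_run[(nt - config$mastery_window + 1L):nt]) >=
              config$mastery_threshold) {
          break
        }
        if (nt >= config$max_block_trials) {
          capped <- TRUE
          break
        }
      }
      if (k > 0L && length(recs) >= 1L) {
        idx <- which(vapply(recs, function(r) r$block, 0) == b)
        for (i in idx) recs[[i]]$block_capped <- capped
      }
    }
    tibble::tibble(
      participant = vapply(recs, `[[`, 0, "participant"),
      block = vapply(recs, `[[`, 0, "block"),
      trial = vapply(recs, `[[`, 0L, "trial"),
      symbol = vapply(recs, `[[`, 0L, "symbol"),
      word = vapply(recs, `[[`, "", "word"),
      exposure_index = vapply(recs, `[[`, 0L, "exposure_index"),
      choices = lapply(recs, `[[`, "choices"),
      response = vapply(recs, `[[`, "", "response"),
      correct = vapply(recs, `[[`, NA, "correct"),
      acquired_before_trial = vapply(recs, `[[`, NA, "acquired_before_trial"),
      block_capped = vapply(recs, `[[`, NA, "block_capped")
    )
  })
}

#' Expected first-exposure accuracy of a perfect learner
#'
#' Closed-form enumeration of the probability that an idealized learner --
#' who knows every symbol's word after a single exposure and answers unknown
#' symbols by eliminating displayed words already mapped to known symbols,
#' then guessing uniformly -- responds correctly on the very first exposure
#' of a symbol, averaged equally over all symbols of the paradigm.
#'
#' For a first encounter with `u` still-unknown words among the other
#' `initial_symbols - 1` active words, the number `k` of unknown distractors
#' among the `n_choices - 1` drawn is hypergeometric, and the success
#' probability is `E[1 / (1 + k)]`. In the first block the `j`-th newly
#' encountered symbol has `u = initial_symbols - j`; in later blocks the
#' `j`-th of the `added_per_block` new symbols has `u = added_per_block - j`
#' (all carried words being known).
#'
#' @param config A [paradigm_config()].
#' @return The expected accuracy as a fraction in (0, 1]. With the default
#'   paradigm this is about 0.712 (71% after rounding).
#' @export
#' @examples
#' round(100 * perfect_learner_first_trial_accuracy(paradigm_config()))
perfect_learner_first_trial_accuracy <- function(config = paradigm_config()) {
  stopifnot(inherits(config, "paradigm_config"))
  bs <- config$initial_symbols       # active symbols per block
  d <- config$n_choices - 1L         # distractors drawn
  pool <- bs - 1L                    # candidate distractor words

  exp_acc <- function(u) {
    # E[1/(1+k)], k ~ Hypergeometric(u unknown, pool - u known, d drawn)
    k <- 0:min(u, d)
    sum(stats::dhyper(k, u, pool - u, d) / (1 + k))
  }

  first_block <- vapply(seq_len(bs), function(j) exp_acc(bs - j), 0)
  a <- config$added_per_block
  later <- vapply(seq_len(a), function(j) exp_acc(a - j), 0)

  total <- bs + (config$n_blocks - 1L) * a
  (sum(first_block) + (config$n_blocks - 1L) * sum(later)) / total
}
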