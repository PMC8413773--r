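# Fast analysis-level checks on small syntheses; the heavier end-to-end
# reconstructions live in test-acceptance.R.

fast_config <- function(n_perm = 19, ...) {
  run_config(n_perm = n_perm, B_boot = 30, seed = 5, ...)
}

test_that("the sliding time course tiles the epoch as contracted", {
  ds <- tiny_dataset(gain = 4, seed = 21)
  cfg <- fast_config(min_exposures = 2, drop_first = 0)
  rep <- run_timecourse(ds$epochs, ds$vectors, window_len = 50, step = 25,
                        config = cfg)
  expect_identical(nrow(rep), 39L)                  # starts 0, 25, ..., 950
  expect_equal(rep$window_start, seq(0, 950, by = 25))
  expect_equal(rep$window_end, rep$window_start + 50)
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
  expect_true(all(rep$p > 0 & rep$p <= 1))
  # FDR-significant windows are a subset of raw p <= alpha
  expect_true(all(rep$p[rep$significant] <= cfg$fdr_alpha))
  expect_error(
    run_timecourse(ds$epochs, ds$vectors, window_len = 2000, config = cfg),
    "time span")
})

test_that("a single full-width time-course window equals the whole-window run", {
  ds <- tiny_dataset(gain = 4, seed = 22)
  cfg <- fast_config(min_exposures = 2, drop_first = 0, window_ms = c(0, 500))
  sem <- run_semantic_analysis(ds$epochs, ds$vectors, cfg)
  tc <- run_timecourse(ds$epochs, ds$vectors, window_len = 500, step = 1000,
                       config = cfg)
  expect_identical(nrow(tc), 1L)
  expect_equal(tc$accuracy, sem$accuracy)
  expect_equal(tc$p, sem$p)
})

test_that("whole-window analysis reports are reproducible and self-describing", {
  ds <- tiny_dataset(gain = 6, seed = 23)
  cfg <- fast_config(min_exposures = 2, drop_first = 0)
  r1 <- run_semantic_analysis(ds$epochs, ds$vectors, cfg)
  r2 <- run_semantic_analysis(ds$epochs, ds$vectors, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  meta <- report_meta(r1)
  expect_identical(meta$config, cfg)
  expect_identical(meta$seed, cfg$seed)
  expect_length(meta$null, cfg$n_perm)
  expect_identical(r1$n_features, 32L * 125L)
})

test_that("the onset analysis reports all trial-by-time cells plus a bootstrap", {
  ds <- tiny_dataset(gain = 4, seed = 24)
  cfg <- fast_config(min_exposures = 6)
  rep <- run_onset(ds$epochs, ds$vectors, cfg)
  expect_identical(nrow(rep), 8L)                       # 4 triples x 2 windows
  expect_identical(unique(rep$trial_start), c(1, 2, 3, 4))
  expect_identical(unique(rep$window_end), c(500, 700))
  boot <- report_meta(rep)$bootstrap
  expect_identical(nrow(boot), 2L)
  expect_true(all(boot$ci_low <= boot$diff & boot$diff <= boot$ci_high))
  expect_true(all(rep$p[rep$significant] <= cfg$fdr_alpha))
})

test_that("searchlight groups are centered electrodes plus montage neighbors", {
  ds <- tiny_dataset(gain = 4, seed = 25)
  mont <- montage_1020_32()
  cfg <- fast_config(min_exposures = 2, drop_first = 0, n_perm = 5)
  rep <- run_searchlight(ds$epochs, ds$vectors, mont, cfg)
  expect_identical(nrow(rep), 32L * 3L)
  expect_identical(unique(paste(rep$window_start, rep$window_end)),
                   c("0 500", "500 1000", "0 1000"))
  for (e in c("Cz", "Fp1", "T7")) {
    expect_identical(rep$n_channels[rep$electrode == e][1],
                     length(mont$neighbors[[e]]) + 1L)
  }
  # montage that does not cover the cap errors informatively
  sub <- montage(c("A", "B"), c(0, 1), c(0, 0), list(A = "B", B = "A"))
  expect_error(run_searchlight(ds$epochs, ds$vectors, sub, cfg), "Cz")
})

test_that("a fully connected montage reproduces the whole-cap accuracy", {
  ds <- tiny_dataset(gain = 5, seed = 26)
  cfg <- fast_config(min_exposures = 2, drop_first = 0, n_perm = 3)
  mont <- full_montage(ds$epochs$electrodes)
  rep <- run_searchlight(ds$epochs, ds$vectors, mont, cfg,
                         time_windows = list(c(0, 500)))
  sel <- select_trials(ds$epochs, 2, 0)
  avg <- average_selected(sel)
  X <- flatten(select_window(avg, c(0, 500)))
  Y <- align_vectors(ds$vectors, avg$words)
  whole <- evaluate_loto(X, Y, cfg$alpha)$accuracy
  expect_true(all(abs(rep$accuracy - whole) < 1e-12))
})

test_that("reports serialize to TSV and JSON with their configuration", {
  ds <- tiny_dataset(gain = 4, seed = 27)
  cfg <- fast_config(min_exposures = 2, drop_first = 0)
  rep <- run_semantic_analysis(ds$epochs, ds$vectors, cfg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report_tsv(rep, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$accuracy, rep$accuracy)
  write_report_json(rep, js)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(obj$type, "semantic_report")
  expect_equal(obj$config$n_perm, cfg$n_perm)
  expect_equal(obj$results$accuracy, rep$accuracy)
})

test_that("report plots build without error", {
  ds <- tiny_dataset(gain = 4, seed = 28)
  cfg <- fast_config(min_exposures = 2, drop_first = 0, n_perm = 5)
  tc <- run_timecourse(ds$epochs, ds$vectors, config = cfg)
  sl <- run_searchlight(ds$epochs, ds$vectors, montage_1020_32(), cfg,
                        time_windows = list(c(0, 500)))
  on <- run_onset(ds$epochs, ds$vectors, fast_config(n_perm = 5))
  sem <- run_semantic_analysis(ds$epochs, ds$vectors, cfg)
  for (p in list(autoplot(tc), autoplot(sl), autoplot(on), autoplot(sem))) {
    expect_s3_class(p, "ggplot")
    built <- ggplot2::ggplot_build(p)
    expect_true(length(built$data) >= 1)
  }
})
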