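#' Analysis run configuration
#'
#' Bundles the tunable analysis settings shared by the high-level runs
#' ([run_semantic_analysis()], [run_timecourse()], [run_onset()],
#' [run_searchlight()]). The configuration is echoed verbatim into every
#' report so a report plus the epochs suffice to re-run the analysis.
#'
#' @param alpha Ridge regularization (default 0.1).
#' @param n_perm Permutations per significance test (default 1000).
#' @param fdr_alpha Target false discovery rate for the
#'   Benjamini-Hochberg-Yekutieli correction (default 0.05).
#' @param min_exposures Minimum presentations per participant-symbol
#'   (default 6).
#' @param drop_first Leading exposures dropped in the whole-window analyses
#'   (default 2).
#' @param B_boot Bootstrap replicates for accuracy comparisons (default
#'   1000).
#' @param window_ms Analysis window of the whole-window semantic run, ms
#'   (default `c(0, 500)`, before the word choices appear).
#' @param seed Seed for all analysis-stage randomness (permutation draws,
#'   bootstrap resampling).
#' @return A `run_config` list.
#' @export
run_config <- function(alpha = 0.1, n_perm = 1000, fdr_alpha = 0.05,
                       min_exposures = 6, drop_first = 2, B_boot = 1000,
                       window_ms = c(0, 500), seed = 1L) {
  stop_if_not_scalar_number(alpha, "alpha", 0, strict_min = TRUE)
  stop_if_not_scalar_number(n_perm, "n_perm", 1)
  stop_if_not_scalar_number(fdr_alpha, "fdr_alpha", 0, strict_min = TRUE)
  stopifnot(length(window_ms) == 2L, window_ms[1] < window_ms[2])
  structure(
    list(alpha = alpha, n_perm = as.integer(n_perm), fdr_alpha = fdr_alpha,
         min_exposures = min_exposures, drop_first = drop_first,
         B_boot = as.integer(B_boot), window_ms = window_ms,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Serialize a run configuration to JSON
#'
#' @param config A [run_config()].
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
config_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "run_config"))
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# Attach the standard report metadata and class.
new_report <- function(tbl, type, config, extra = list()) {
  out <- tibble::as_tibble(tbl)
  attr(out, "config") <- config
  attr(out, "seed") <- config$seed
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c(paste0(type, "_report"), "semdec_report", class(out))
  out
}

#' Report metadata
#'
#' Analysis reports are tibbles; the run configuration, seed and any
#' analysis-specific companion objects travel along as attributes. This
#' accessor returns them.
#'
#' @param report A report produced by one of the `run_*()` analyses.
#' @return A list with at least `config` and `seed`.
#' @export
report_meta <- function(report) {
  stopifnot(inherits(report, "semdec_report"))
  at <- attributes(report)
  at[setdiff(names(at), c("names", "row.names", "class"))]
}
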