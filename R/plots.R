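# ggplot2 views of the analysis reports. Each autoplot() returns a plot the
# caller can restyle; plot_*() are mnemonic wrappers.

#' Plot a decoding time course
#'
#' Accuracy per sliding window with chance level at 0.5 and FDR-significant
#' windows highlighted.
#'
#' @param object A `timecourse_report` from [run_timecourse()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.timecourse_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_start,
                                   y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$significant),
      colour = "goldenrod", size = 2.5
    ) +
    ggplot2::labs(x = "window start (ms)", y = "2 vs. 2 accuracy",
                  title = "Decoding accuracy over time",
                  subtitle = "highlighted points: FDR-significant windows") +
    ggplot2::theme_minimal()
}

#' Plot a searchlight topography
#'
#' Electrode-group accuracies at their layout positions, faceted by time
#' window; significant groups are ringed.
#'
#' @param object A `searchlight_report` from [run_searchlight()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.searchlight_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(window = sprintf("%g-%g ms", .data$window_start,
                                   .data$window_end))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accuracy), size = 5) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$significant),
      shape = 21, size = 7, stroke = 1, colour = "black"
    ) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~window) +
    ggplot2::labs(title = "Searchlight 2 vs. 2 accuracy",
                  subtitle = "ringed electrodes: FDR-significant groups",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an onset-of-acquisition report
#'
#' Accuracy per exposure triple, one line per time window.
#'
#' @param object An `onset_report` from [run_onset()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.onset_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      trials = sprintf("%g-%g", .data$trial_start, .data$trial_end),
      window = sprintf("%g-%g ms", .data$window_start, .data$window_end)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trials, y = .data$accuracy,
                                   group = .data$window,
                                   colour = .data$window)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 3) +
    ggplot2::labs(x = "averaged exposures", y = "2 vs. 2 accuracy",
                  title = "Onset of the decodable semantic mapping") +
    ggplot2::theme_minimal()
}

#' Plot a whole-window permutation null
#'
#' Histogram of the permutation null with the observed accuracy marked.
#'
#' @param object A `semantic_report` from [run_semantic_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.semantic_report <- function(object, ...) {
  null <- report_meta(object)$null
  obs <- object$accuracy[1]
  ggplot2::ggplot(tibble::tibble(accuracy = null),
                  ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = obs, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(title = "Permutation null of 2 vs. 2 accuracy",
                  subtitle = sprintf("observed = %.3f, p = %.3g", obs,
                                     object$p[1]),
                  x = "null accuracy", y = "count") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.timecourse_report
#' @param report The report to plot.
#' @export
plot_timecourse <- function(report, ...) autoplot(report, ...)

#' @rdname autoplot.searchlight_report
#' @param report The report to plot.
#' @export
plot_topography <- function(report, ...) autoplot(report, ...)

#' @rdname autoplot.onset_report
#' @param report The report to plot.
#' @export
plot_onset <- function(report, ...) autoplot(report, ...)
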