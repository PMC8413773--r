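# On-disk containers. Epochs live in a directory holding the numeric tensor
# (Parquet when the arrow package is available, otherwise full-precision
# TSV), the per-epoch metadata table and a JSON attribute file, so a dataset
# round-trips exactly and remains readable outside R.

EPOCHS_SCHEMA_VERSION <- "1.0"

#' Write an epoch collection to disk
#'
#' Creates (or reuses) a directory containing `meta.json` (sampling rate,
#' time origin, electrode names, schema version, column classes),
#' `info.tsv` (per-epoch metadata) and the voltage tensor as
#' `data.parquet` (via arrow) or `data.tsv` (full-precision text fallback).
#' `read_epochs(write_epochs(x, d))` reproduces `x` exactly, values and
#' metadata.
#'
#' @param x An [epoch_collection()].
#' @param path Directory path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_collection"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$data)
  info <- x$info
  list_cols <- names(info)[vapply(info, is.list, NA)]
  for (nm in list_cols) {
    info[[nm]] <- vapply(info[[nm]], paste, "", collapse = "|")
  }
  jsonlite::write_json(
    list(schema_version = EPOCHS_SCHEMA_VERSION,
         fs = x$fs, t0_ms = x$t0_ms, electrodes = x$electrodes,
         n_epochs = d[1], n_electrodes = d[2], n_samples = d[3],
         info_classes = lapply(x$info, function(col) class(col)[1]),
         list_columns = list_cols),
    file.path(path, "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(info, file.path(path, "info.tsv"), progress = FALSE)
  # rows ordered epoch-major, electrode within epoch
  m <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[1] * d[2])
  colnames(m) <- sprintf("s%03d", seq_len(d[3]))
  if (requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_parquet(tibble::as_tibble(m), file.path(path, "data.parquet"))
  } else {
    con <- file(file.path(path, "data.tsv"), "w")
    on.exit(close(con))
    writeLines(paste(colnames(m), collapse = "\t"), con)
    writeLines(apply(m, 1, function(r) {
      paste(sprintf("%.17g", r), collapse = "\t")
    }), con)
  }
  invisible(path)
}

#' Read an epoch collection from disk
#'
#' @param path Directory written by [write_epochs()].
#' @return The reconstructed [epoch_collection()].
#' @export
read_epochs <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not an epochs container (missing meta.json): ", path,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  needed <- c("schema_version", "fs", "t0_ms", "electrodes", "n_epochs",
              "n_electrodes", "n_samples")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0L) {
    stop("epochs container lacks attribute(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(meta$schema_version, EPOCHS_SCHEMA_VERSION)) {
    stop(sprintf("epochs schema version %s not supported (expected %s).",
                 meta$schema_version, EPOCHS_SCHEMA_VERSION), call. = FALSE)
  }
  if (length(meta$electrodes) != meta$n_electrodes) {
    stop("electrode names disagree with the stored tensor shape.",
         call. = FALSE)
  }
  pq <- file.path(path, "data.parquet")
  if (file.exists(pq)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the arrow package is required to read ", pq, call. = FALSE)
    }
    m <- as.matrix(arrow::read_parquet(pq))
  } else {
    m <- as.matrix(utils::read.delim(file.path(path, "data.tsv"),
                                     check.names = FALSE))
  }
  if (nrow(m) != meta$n_epochs * meta$n_electrodes ||
      ncol(m) != meta$n_samples) {
    stop("stored tensor shape disagrees with meta.json.", call. = FALSE)
  }
  data <- aperm(array(m, c(meta$n_electrodes, meta$n_epochs,
                           meta$n_samples)), c(2, 1, 3))
  info <- readr::read_tsv(file.path(path, "info.tsv"), progress = FALSE,
                          show_col_types = FALSE)
  for (nm in names(meta$info_classes)) {
    cls <- meta$info_classes[[nm]]
    if (nm %in% meta$list_columns) {
      info[[nm]] <- strsplit(info[[nm]], "|", fixed = TRUE)
    } else if (cls == "integer") {
      info[[nm]] <- as.integer(info[[nm]])
    } else if (cls == "numeric") {
      info[[nm]] <- as.numeric(info[[nm]])
    } else if (cls == "logical") {
      info[[nm]] <- as.logical(info[[nm]])
    } else if (cls == "character") {
      info[[nm]] <- as.character(info[[nm]])
    }
  }
  info <- info[, names(meta$info_classes)]
  epoch_collection(data, info, meta$electrodes, as.numeric(meta$fs),
                   as.numeric(meta$t0_ms))
}

#' Write or read trial records as TSV
#'
#' The `choices` list column is stored `|`-separated.
#'
#' @param trials A trial-record tibble from [simulate_behavior()].
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, the tibble.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  out$choices <- vapply(out$choices, paste, "", collapse = "|")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  out$choices <- strsplit(out$choices, "|", fixed = TRUE)
  out$trial <- as.integer(out$trial)
  out$symbol <- as.integer(out$symbol)
  out$exposure_index <- as.integer(out$exposure_index)
  out
}

#' Export an analysis report
#'
#' `write_report_tsv()` writes the report rows as TSV (for a searchlight
#' report this is the topography table: electrode, layout coordinates,
#' accuracy, p, significance). `write_report_json()` writes a
#' self-describing JSON object with the run configuration echo, the seed
#' and the rows.
#'
#' @param report A report from one of the `run_*()` analyses.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "semdec_report"))
  readr::write_tsv(tibble::as_tibble(report), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "semdec_report"))
  meta <- report_meta(report)
  jsonlite::write_json(
    list(type = class(report)[1],
         config = unclass(meta$config),
         seed = meta$seed,
         results = tibble::as_tibble(report)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
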