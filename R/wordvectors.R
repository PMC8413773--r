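#' Generate synthetic word vectors
#'
#' Draws independent standard-normal embedding rows as a stand-in for
#' corpus-trained word vectors. One row per symbol, labelled with the symbol's
#' word.
#'
#' @param ns Number of words (rows); at least 3.
#' @param v Embedding dimensionality (default 50).
#' @param seed Integer seed.
#' @param normalize If `TRUE`, rows are scaled to unit Euclidean norm.
#' @param labels Row labels; defaults to [symbol_words()].
#' @return A numeric matrix of class `word_vectors` with one labelled row per
#'   word.
#' @export
#' @examples
#' Y <- generate_word_vectors(60, 50, seed = 1)
#' dim(Y)
generate_word_vectors <- function(ns, v = 50, seed = 1L, normalize = FALSE,
                                  labels = NULL) {
  stop_if_not_scalar_number(ns, "ns", 3)
  stop_if_not_scalar_number(v, "v", 2)
  labels <- labels %||% symbol_words(ns)
  stopifnot(length(labels) == ns, !anyDuplicated(labels))
  Y <- with_seed(seed, matrix(stats::rnorm(ns * v), nrow = ns))
  if (normalize) {
    Y <- Y / sqrt(rowSums(Y^2))
  }
  rownames(Y) <- labels
  class(Y) <- c("word_vectors", class(Y))
  Y
}

#' Read word vectors in word2vec text format
#'
#' The file starts with a header line `"<count> <dim>"` followed by one line
#' per word: the label and `dim` numeric values, whitespace-separated.
#'
#' @param path Path to the text file.
#' @param words Optional character vector of required words; the returned
#'   rows are aligned to this order and any word missing from the file is an
#'   error naming it.
#' @return A `word_vectors` matrix with labelled rows.
#' @export
read_word_vectors <- function(path, words = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty word-vector file: ", path, call. = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("line 1: expected header \"<count> <dim>\".", call. = FALSE)
  }
  n <- as.integer(hdr[1]); v <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop(sprintf("header announces %d words but file has %d rows.",
                 n, length(body)), call. = FALSE)
  }
  labs <- character(n)
  Y <- matrix(NA_real_, n, v)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(parts) != v + 1L) {
      stop(sprintf("line %d: expected a label and %d values, found %d fields.",
                   i + 1L, v, length(parts)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) {
      stop(sprintf("line %d: non-numeric vector value.", i + 1L),
           call. = FALSE)
    }
    labs[i] <- parts[1]
    Y[i, ] <- vals
  }
  if (anyDuplicated(labs)) {
    stop("duplicate word label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  }
  rownames(Y) <- labs
  if (!is.null(words)) {
    Y <- align_vectors(Y, words)
  }
  class(Y) <- c("word_vectors", class(Y))
  Y
}

#' Write word vectors in word2vec text format
#'
#' @param x A labelled numeric matrix (rows = words).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word_vectors <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  hdr <- paste(nrow(x), ncol(x))
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(rownames(x)[i], paste(sprintf("%.17g", x[i, ]), collapse = " "))
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Align word-vector rows to a lexicon
#'
#' @param vectors Labelled word-vector matrix.
#' @param words Words required, in order.
#' @return The matrix restricted and reordered to `words`.
#' @export
align_vectors <- function(vectors, words) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  missing <- setdiff(words, rownames(vectors))
  if (length(missing) > 0L) {
    stop("word(s) missing from the vector set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- vectors[words, , drop = FALSE]
  class(out) <- c("word_vectors", "matrix", "array")
  out
}
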