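#' Construct an electrode montage
#'
#' A montage names the electrodes, gives 2-D scalp layout coordinates
#' (unitless, nose up) and an explicit neighbor map used by the searchlight
#' analysis. Adjacency is data: it is stored with the montage, not recomputed
#' from geometry. The neighbor relation must be symmetric and every electrode
#' must have at least one neighbor.
#'
#' @param electrodes Character vector of electrode names.
#' @param x,y Numeric layout coordinates, one per electrode.
#' @param neighbors Named list: electrode name -> character vector of
#'   neighboring electrode names.
#' @return A `montage` list.
#' @export
montage <- function(electrodes, x, y, neighbors) {
  stopifnot(length(x) == length(electrodes), length(y) == length(electrodes))
  stopifnot(!anyDuplicated(electrodes))
  if (!setequal(names(neighbors), electrodes)) {
    stop("`neighbors` must have exactly one entry per electrode.",
         call. = FALSE)
  }
  neighbors <- neighbors[electrodes]
  for (e in electrodes) {
    nb <- neighbors[[e]]
    if (length(nb) < 1L) {
      stop("electrode ", e, " has no neighbors.", call. = FALSE)
    }
    bad <- setdiff(nb, electrodes)
    if (length(bad) > 0L) {
      stop("unknown neighbor(s) of ", e, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  for (e in electrodes) {
    for (f in neighbors[[e]]) {
      if (!(e %in% neighbors[[f]])) {
        stop(sprintf("neighbor relation is not symmetric: %s -> %s.", e, f),
             call. = FALSE)
      }
    }
  }
  structure(
    list(electrodes = as.character(electrodes), x = as.numeric(x),
         y = as.numeric(y), neighbors = neighbors),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes, median %g neighbors\n",
              length(x$electrodes),
              stats::median(lengths(x$neighbors))))
  invisible(x)
}

#' Read or write a montage as JSON
#'
#' The JSON object holds `electrodes`, `x`, `y` and a `neighbors` map with
#' explicit adjacency lists.
#'
#' @param path File path.
#' @return For `read_montage`, a [montage()]; for `write_montage`, `path`
#'   invisibly.
#' @export
read_montage <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("electrodes", "x", "y", "neighbors")
  missing <- setdiff(needed, names(obj))
  if (length(missing) > 0L) {
    stop("montage file lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nb <- lapply(obj$neighbors, as.character)
  montage(obj$electrodes, obj$x, obj$y, nb)
}

#' @rdname read_montage
#' @param m A [montage()].
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "montage"))
  jsonlite::write_json(
    list(electrodes = m$electrodes, x = m$x, y = m$y,
         neighbors = m$neighbors),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' The packaged 32-channel 10-20 montage
#'
#' A standard 32-electrode extended 10-20 layout with 2-D coordinates and
#' hand-frozen neighbor lists, shipped with the package.
#'
#' @return A [montage()] of 32 electrodes.
#' @export
montage_1020_32 <- function() {
  path <- system.file("extdata", "montage_32.json", package = "semdecode",
                      mustWork = TRUE)
  read_montage(path)
}

#' A fully connected montage
#'
#' Every electrode neighbors every other one; with this montage each
#' searchlight group spans all electrodes, reproducing the whole-cap
#' accuracy. Mainly useful for validation.
#'
#' @param electrodes Electrode names.
#' @return A [montage()] (electrodes are laid out on a circle).
#' @export
full_montage <- function(electrodes) {
  k <- length(electrodes)
  th <- 2 * pi * (seq_len(k) - 1L) / k
  nb <- lapply(seq_len(k), function(i) electrodes[-i])
  names(nb) <- electrodes
  montage(electrodes, cos(th), sin(th), nb)
}
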