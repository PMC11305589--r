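#' Build the communication-pattern sequence Q(t)
#'
#' Turns an event stream into the T x n activation matrix at the heart of the
#' measures: row t holds the information amount q_i(t) of each vertex i at the
#' t-th time step. In `binary` mode (the default, and the convention used when
#' only participation is recorded) `q_i(t)` is 1 when vertex i takes part in at
#' least one event at that time and 0 otherwise; in `weighted` mode it is the
#' sum of the weights of i's events at that time.
#'
#' The timeline is either the `event` timeline — the distinct recorded
#' timestamps, so every row has at least one active vertex and the number of
#' rows equals [t_max()] — or a `grid` of consecutive bins of width
#' `grid_step` spanning the observation window, which may contain silent
#' (all-zero) rows.
#'
#' @inheritParams event_vertices
#' @param mode `"binary"` (0/1 participation) or `"weighted"` (sum of event
#'   weights).
#' @param timeline `"event"` (distinct recorded times) or `"grid"` (fixed-width
#'   bins).
#' @param grid_step Positive bin width, required when `timeline = "grid"`.
#' @param u Reference information unit (positive real, default 1); the
#'   normalising constant for the information-change and distance series.
#' @param roster Optional character vector of vertex identifiers to include as
#'   columns even if silent; can enlarge, never shrink, the registry.
#' @return A `pattern_sequence` object: a list with the matrix `Q`, the row
#'   `times`, the column `vertices`, the unit `u` and the mode/timeline flags.
#' @examples
#' ev <- event_stream(data.frame(time = c(20, 20, 40),
#'                               i = c("A", "A", "B"),
#'                               j = c("B", "C", "C")))
#' p <- build_pattern_sequence(ev)
#' as.matrix(p)
#' @export
build_pattern_sequence <- function(stream,
                                   mode = c("binary", "weighted"),
                                   timeline = c("event", "grid"),
                                   grid_step = NULL,
                                   u = 1,
                                   roster = NULL) {
  stopifnot(inherits(stream, "event_stream"))
  mode <- match.arg(mode)
  timeline <- match.arg(timeline)
  if (nrow(stream) == 0) abort("empty event stream")
  if (!is.numeric(u) || length(u) != 1 || u <= 0) {
    abort("u must be a single positive number")
  }
  vertices <- event_vertices(stream)
  if (!is.null(roster)) {
    vertices <- unique(c(vertices, as.character(roster)))
  }
  n <- length(vertices)

  # one long record per (event, actor); single-actor events contribute one row
  long <- tibble(
    time = rep(stream$time, 2L),
    v = c(stream$i, stream$j),
    w = rep(stream$weight, 2L)
  )
  long <- long[!is.na(long$v), , drop = FALSE]

  if (timeline == "event") {
    times <- sort(unique(stream$time))
    ti <- match(long$time, times)
  } else {
    if (is.null(grid_step) || !is.numeric(grid_step) || grid_step <= 0) {
      abort("grid timeline requires a positive grid_step")
    }
    t0 <- min(stream$time)
    t1 <- max(stream$time)
    n_bins <- floor((t1 - t0) / grid_step) + 1L
    times <- t0 + (seq_len(n_bins) - 1L) * grid_step
    ti <- pmin(floor((long$time - t0) / grid_step) + 1L, n_bins)
  }
  vi <- match(long$v, vertices)

  Q <- matrix(0, nrow = length(times), ncol = n,
              dimnames = list(NULL, vertices))
  if (mode == "binary") {
    idx <- unique(cbind(ti, vi))
    Q[idx] <- 1
  } else {
    agg <- rowsum(long$w, group = (ti - 1L) * n + vi)
    key <- as.integer(rownames(agg))
    Q[cbind((key - 1L) %/% n + 1L, (key - 1L) %% n + 1L)] <- agg[, 1]
  }
  new_pattern_sequence(Q, times, vertices, u, mode, timeline)
}

new_pattern_sequence <- function(Q, times, vertices, u, mode, timeline) {
  structure(
    list(Q = Q, times = as.numeric(times), vertices = vertices,
         u = u, mode = mode, timeline = timeline),
    class = "pattern_sequence"
  )
}

#' @export
print.pattern_sequence <- function(x, ...) {
  cat("# A pattern sequence: ", nrow(x$Q), " time steps x ", ncol(x$Q),
      " vertices (", x$mode, " mode, ", x$timeline, " timeline, u = ",
      x$u, ")\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.pattern_sequence <- function(x, ...) x$Q

#' @export
dim.pattern_sequence <- function(x) dim(x$Q)

#' Total information per time step
#'
#' The row sums of the pattern matrix: the total amount of information
#' circulating at each time step (the numerator of the information-change
#' series).
#'
#' @param pattern A [build_pattern_sequence()] result.
#' @return Numeric vector of length T.
#' @export
pattern_row_sums <- function(pattern) {
  stopifnot(inherits(pattern, "pattern_sequence"))
  unname(rowSums(pattern$Q))
}

#' Tidy a pattern sequence into sparse long form
#'
#' @param x A `pattern_sequence`.
#' @param ... Unused.
#' @return A tibble with one row per nonzero entry: `t_index`, `time`,
#'   `vertex`, `q`.
#' @export
tidy.pattern_sequence <- function(x, ...) {
  nz <- which(x$Q != 0, arr.ind = TRUE)
  out <- tibble(
    t_index = as.integer(nz[, 1]),
    time = x$times[nz[, 1]],
    vertex = x$vertices[nz[, 2]],
    q = x$Q[nz]
  )
  dplyr::arrange(out, .data$t_index, .data$vertex)
}

#' Export a pattern matrix as TSV
#'
#' Writes the dense T x n matrix with a leading `time` column; vertices are
#' the column header.
#'
#' @inheritParams pattern_row_sums
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pattern_tsv <- function(pattern, path) {
  stopifnot(inherits(pattern, "pattern_sequence"))
  df <- data.frame(time = pattern$times, pattern$Q, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
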