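#' Construct an event stream
#'
#' An event stream is the canonical container for timestamped contact or
#' message events: a tibble with columns `time` (numeric), `i` and `j`
#' (character vertex identifiers; `j` is `NA` for single-actor events such as
#' self-contacts) and `weight` (nonnegative information amount, default 1).
#' Events are kept sorted by time, with ties left in input order. The vertex
#' registry (every identifier ever observed, in first-appearance order along
#' the sorted stream) is stored as an attribute and may be enlarged — never
#' shrunk — with an explicit `vertices` roster, so that silent vertices still
#' count towards the community size `n`.
#'
#' @param events A data frame with columns `time`, `i`, `j` and optionally
#'   `weight`.
#' @param vertices Optional character vector of vertex identifiers that must at
#'   least cover every actor in `events`; extra identifiers are appended to the
#'   registry as silent vertices.
#' @return An `event_stream` tibble.
#' @examples
#' ev <- event_stream(data.frame(time = c(40, 20, 20),
#'                               i = c("B", "A", "A"),
#'                               j = c("C", "B", "C")))
#' t_count(ev) # 3 records
#' t_max(ev)   # 2 distinct times
#' @export
event_stream <- function(events, vertices = NULL) {
  events <- as_tibble(events)
  required <- c("time", "i", "j")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("events is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(events) == 0) {
    abort("an event stream must contain at least one event")
  }
  if (!("weight" %in% names(events))) events$weight <- 1
  events$time <- as.numeric(events$time)
  events$i <- as.character(events$i)
  events$j <- as.character(events$j)
  events$weight <- as.numeric(events$weight)
  if (anyNA(events$time)) abort("event times must be numeric and non-missing")
  if (anyNA(events$i)) abort("every event needs at least one actor (column i)")
  if (anyNA(events$weight) || any(events$weight < 0)) {
    abort("event weights must be nonnegative")
  }
  self <- !is.na(events$j) & events$i == events$j
  if (any(self)) {
    warn(paste0(sum(self), " self-contact(s) kept as single-actor events"))
    events$j[self] <- NA_character_
  }
  # stable sort: base order() leaves ties in input order
  events <- events[order(events$time), , drop = FALSE]
  observed <- unique(stats::na.omit(as.vector(rbind(events$i, events$j))))
  if (is.null(vertices)) {
    vertices <- observed
  } else {
    vertices <- as.character(vertices)
    vertices <- unique(c(observed, vertices))
  }
  new_event_stream(events, vertices)
}

new_event_stream <- function(events, vertices) {
  out <- new_tibble(events, vertices = vertices,
                    class = "event_stream", nrow = nrow(events))
  out
}

#' Vertex registry of an event stream
#' @param stream An [event_stream()].
#' @return Character vector of vertex identifiers in first-appearance order.
#' @export
event_vertices <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  attr(stream, "vertices")
}

#' Number of event records (`t_count`)
#'
#' Counts raw data rows, duplicate records included.
#' @inheritParams event_vertices
#' @return Integer.
#' @export
t_count <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  nrow(stream)
}

#' Number of distinct event times (`t_max`)
#'
#' Counts timestamps once however many events share them; this is the length of
#' the event-time timeline and always satisfies `t_max <= t_count`.
#' @inheritParams event_vertices
#' @return Integer.
#' @export
t_max <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  length(unique(stream$time))
}

#' @export
print.event_stream <- function(x, ...) {
  cat("# An event stream: ", t_count(x), " events, ",
      t_max(x), " distinct times, ",
      length(event_vertices(x)), " vertices\n", sep = "")
  NextMethod()
}

#' Read a temporal contact list
#'
#' Parses whitespace- (or comma-) separated temporal edge lists into an
#' [event_stream()]. Two field dialects are supported, matching the formats
#' used by the common public contact datasets, plus a configurable generic
#' layout:
#'
#' * `"sociopatterns"`: rows `t i j [metadata ...]` — the layout of the
#'   SocioPatterns face-to-face contact releases (high school, primary school,
#'   workplace, village, conference). Trailing metadata columns (e.g. class
#'   labels) are ignored.
#' * `"netrepo_edges"`: rows `i j t` or `i j w t` with an optional `%` comment
#'   header — the network-repository layout used by online-message and email
#'   edge lists. The third column of four-column rows is read as the weight.
#' * `"generic_tsv"`: rows `t i j [w]` by default; `column_map` can remap
#'   positions, e.g. `c(time = 4, i = 1, j = 2, weight = 3)`.
#'
#' Comment lines starting with `%` or `#` and blank lines are skipped.
#' Directed records (messages) are collapsed to undirected co-activation:
#' sender and receiver are both marked active at the send time. Self-contacts
#' (`i == j`) are kept as single-actor events with a warning. Duplicate rows
#' are retained (they count towards `t_count`).
#'
#' @param path Path to the file.
#' @param dialect One of `"sociopatterns"`, `"netrepo_edges"`, `"generic_tsv"`.
#' @param column_map Optional named integer vector with entries `time`, `i`,
#'   `j` and optionally `weight`, giving 1-based field positions
#'   (`generic_tsv` only).
#' @return An [event_stream()].
#' @export
read_contact_list <- function(path,
                              dialect = c("sociopatterns", "netrepo_edges",
                                          "generic_tsv"),
                              column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|[%#])", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort(paste0("no data rows in ", path))
  fields <- strsplit(trimws(lines), "[,\t ]+")
  nf <- lengths(fields)

  if (dialect == "generic_tsv" && !is.null(column_map)) {
    cm <- column_map
    if (!all(c("time", "i", "j") %in% names(cm))) {
      abort("column_map must name positions for time, i and j")
    }
    need <- max(unlist(cm))
  } else {
    cm <- switch(dialect,
      sociopatterns = c(time = 1, i = 2, j = 3),
      generic_tsv   = c(time = 1, i = 2, j = 3, weight = 4),
      netrepo_edges = NULL)
    need <- if (dialect == "netrepo_edges") 3 else 3
  }
  bad <- which(nf < need)
  if (length(bad) > 0) {
    abort(paste0("line ", line_no[bad[1]], ": expected at least ", need,
                 " fields, found ", nf[bad[1]]))
  }

  pick <- function(k) vapply(fields, `[[`, character(1), k)
  if (dialect == "netrepo_edges") {
    i <- pick(1)
    j <- pick(2)
    time_chr <- mapply(function(f, m) f[[m]], fields, nf)
    weight <- rep(1, length(fields))
    four <- nf >= 4
    if (any(four)) {
      w_chr <- vapply(fields[four], `[[`, character(1), 3)
      w <- suppressWarnings(as.numeric(w_chr))
      if (anyNA(w)) {
        k <- which(four)[which(is.na(w))[1]]
        abort(paste0("line ", line_no[k], ": non-numeric weight field"))
      }
      weight[four] <- w
    }
  } else {
    time_chr <- pick(cm[["time"]])
    i <- pick(cm[["i"]])
    j <- pick(cm[["j"]])
    weight <- rep(1, length(fields))
    if ("weight" %in% names(cm)) {
      has_w <- nf >= cm[["weight"]]
      if (dialect == "generic_tsv" && any(has_w)) {
        w_chr <- vapply(fields[has_w], `[[`, character(1), cm[["weight"]])
        w <- suppressWarnings(as.numeric(w_chr))
        if (anyNA(w)) {
          k <- which(has_w)[which(is.na(w))[1]]
          abort(paste0("line ", line_no[k], ": non-numeric weight field"))
        }
        weight[has_w] <- w
      }
    }
  }
  time <- suppressWarnings(as.numeric(time_chr))
  if (anyNA(time)) {
    abort(paste0("line ", line_no[which(is.na(time))[1]],
                 ": non-numeric timestamp"))
  }
  event_stream(tibble(time = time, i = i, j = j, weight = weight))
}

#' Write a contact list in the canonical TSV dialect
#'
#' Serialises an event stream as tab-separated rows `t i j` (with a fourth
#' `w` column whenever any weight differs from 1). Single-actor events are
#' written with `j = i`. Re-reading the file reproduces the original event
#' multiset, `t_count` and `t_max`.
#'
#' @inheritParams event_vertices
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contact_list <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  if (nrow(stream) == 0) abort("refusing to serialise an empty event stream")
  j <- ifelse(is.na(stream$j), stream$i, stream$j)
  num <- function(x) {
    vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE,
                                 digits = 15),
           character(1))
  }
  if (any(stream$weight != 1)) {
    lines <- paste(num(stream$time), stream$i, j, num(stream$weight),
                   sep = "\t")
  } else {
    lines <- paste(num(stream$time), stream$i, j, sep = "\t")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
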