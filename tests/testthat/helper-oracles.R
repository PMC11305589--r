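# Independent brute-force oracles used to cross-check the vectorised
# implementations. These deliberately loop element by element and share no
# code with the package internals.

# Naive per-element transition series (information change, Euclidean and
# relative distance, cosine similarity) on a raw matrix.
naive_transition_series <- function(Q, u = 1) {
  Tn <- nrow(Q)
  n <- ncol(Q)
  I <- L <- LR <- S <- numeric(Tn - 1)
  for (t in seq_len(Tn - 1)) {
    s1 <- 0; s2 <- 0; sq <- 0; n1 <- 0; n2 <- 0; dot <- 0
    for (i in seq_len(n)) {
      a <- Q[t, i]; b <- Q[t + 1, i]
      s1 <- s1 + a; s2 <- s2 + b
      sq <- sq + (b - a)^2
      n1 <- n1 + a^2; n2 <- n2 + b^2
      dot <- dot + a * b
    }
    I[t] <- (s2 - s1) / (n * u)
    L[t] <- sqrt(sq) / (u * sqrt(n))
    LR[t] <- sqrt(sq) / sqrt(n2)
    S[t] <- dot / (sqrt(n1) * sqrt(n2))
  }
  list(I = I, L = L, L_R = LR, S = S)
}

# Naive polar coordinates per row.
naive_polar <- function(Q) {
  Tn <- nrow(Q)
  n <- ncol(Q)
  r <- theta <- numeric(Tn)
  for (t in seq_len(Tn)) {
    ssq <- 0; s <- 0
    for (i in seq_len(n)) {
      ssq <- ssq + Q[t, i]^2
      s <- s + Q[t, i]
    }
    r[t] <- sqrt(ssq)
    theta[t] <- if (r[t] > 0) acos(min(1, s / (r[t] * sqrt(n)))) else NA_real_
  }
  list(r = r, theta = theta)
}

# All-pairs shortest paths on an adjacency matrix by repeated BFS.
naive_distances <- function(adj) {
  v <- nrow(adj)
  D <- matrix(Inf, v, v)
  for (s in seq_len(v)) {
    dist <- rep(Inf, v)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (node in frontier) {
        for (nb in which(adj[node, ] == 1)) {
          if (dist[nb] > d) {
            dist[nb] <- d
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# Per-vertex local clustering by explicit triangle counting; degree < 2 -> 0.
naive_local_clustering <- function(adj) {
  v <- nrow(adj)
  cc <- numeric(v)
  for (i in seq_len(v)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) {
      cc[i] <- 0
    } else {
      links <- 0
      for (a in seq_len(k - 1)) {
        for (b in (a + 1):k) {
          links <- links + adj[nb[a], nb[b]]
        }
      }
      cc[i] <- 2 * links / (k * (k - 1))
    }
  }
  cc
}

# Small random fixtures -------------------------------------------------------

# A pattern sequence with strictly positive row activity (event-time style).
random_pattern <- function(n, T, u = 1, binary = TRUE) {
  Q <- matrix(0, T, n)
  for (t in seq_len(T)) {
    k <- sample(n, 1)
    active <- sample(n, k)
    Q[t, active] <- if (binary) 1 else stats::runif(k, 0.5, 3)
  }
  pattern_from_matrix(Q, u = u)
}

# Wrap a raw matrix in a pattern_sequence via a synthetic weighted stream.
pattern_from_matrix <- function(Q, u = 1) {
  n <- ncol(Q)
  labels <- sprintf("x%03d", seq_len(n))
  nz <- which(Q != 0, arr.ind = TRUE)
  ev <- tibble::tibble(time = nz[, 1], i = labels[nz[, 2]],
                       j = NA_character_, weight = Q[nz])
  stream <- suppressWarnings(event_stream(ev, vertices = labels))
  build_pattern_sequence(stream, mode = "weighted", u = u)
}

# A random event stream for IO round-trip checks.
random_stream <- function(n_vertices = 8, n_events = 25, weighted = FALSE) {
  labels <- sprintf("p%02d", seq_len(n_vertices))
  pairs <- t(replicate(n_events, sample(n_vertices, 2)))
  tib <- tibble::tibble(
    time = sample(1:10, n_events, replace = TRUE),
    i = labels[pairs[, 1]],
    j = labels[pairs[, 2]],
    weight = if (weighted) sample(1:5, n_events, replace = TRUE) else 1
  )
  event_stream(tib)
}

# Canonical multiset representation of a stream for round-trip equality.
stream_multiset <- function(stream) {
  j <- ifelse(is.na(stream$j), stream$i, stream$j)
  key <- paste(stream$time,
               pmin(stream$i, j), pmax(stream$i, j),
               stream$weight)
  sort(key)
}

# A stream whose aggregated graph has exactly v vertices and e distinct
# edges, sampled uniformly among the choose(v, 2) possible pairs.
random_edge_stream <- function(v, e) {
  stopifnot(e <= v * (v - 1) / 2)
  labels <- sprintf("n%04d", seq_len(v))
  idx <- sample(v * (v - 1) / 2, e)
  # map linear index to an (a, b) pair with a < b
  b <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  a <- idx - (b - 1) * (b - 2) / 2
  ev <- tibble::tibble(time = seq_len(e), i = labels[a], j = labels[b])
  event_stream(ev, vertices = labels)
}

# A random simple graph as an event stream plus its adjacency matrix.
random_graph_stream <- function(v_max = 30) {
  v <- sample(4:v_max, 1)
  p <- stats::runif(1, 0.1, 0.5)
  adj <- matrix(0, v, v)
  for (a in seq_len(v - 1)) {
    for (b in (a + 1):v) {
      if (stats::runif(1) < p) adj[a, b] <- adj[b, a] <- 1
    }
  }
  if (sum(adj) == 0) adj[1, 2] <- adj[2, 1] <- 1
  labels <- sprintf("g%02d", seq_len(v))
  edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  ev <- tibble::tibble(time = seq_len(nrow(edges)),
                       i = labels[edges[, 1]],
                       j = labels[edges[, 2]])
  list(stream = event_stream(ev, vertices = labels), adj = adj)
}

# Fixed toy patterns used across tests ---------------------------------------

toy_constant <- function(reps = 5) {
  pattern_from_matrix(matrix(rep(c(1, 1, 0, 0), each = reps), nrow = reps))
}

toy_alternation <- function(rows = 6) {
  a <- c(1, 1, 0, 0)
  b <- c(0, 0, 1, 1)
  Q <- t(vapply(seq_len(rows), function(k) if (k %% 2 == 1) a else b,
                numeric(4)))
  pattern_from_matrix(Q)
}

toy_block <- function() {
  Q <- rbind(matrix(rep(c(1, 1, 0, 0), each = 3), nrow = 3),
             matrix(rep(c(0, 0, 1, 1), each = 3), nrow = 3))
  pattern_from_matrix(Q)
}
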