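#' Step-to-step transition series of a pattern sequence
#'
#' For each pair of consecutive pattern rows Q(t), Q(t+1) this computes the
#' four dynamics series that the community-phase measures summarise:
#'
#' * `I` — normalised information change,
#'   \eqn{(\sum_i q_i(t+1) - \sum_i q_i(t)) / (n u)}; may be negative.
#' * `L` — Euclidean distance normalised by the magnitude of the all-`u`
#'   reference vector, \eqn{\lVert Q(t+1)-Q(t)\rVert_2 / (u\sqrt n)}.
#' * `L_R` — relative distance change,
#'   \eqn{\lVert Q(t+1)-Q(t)\rVert_2 / \lVert Q(t+1)\rVert_2}.
#' * `S` — cosine similarity
#'   \eqn{\sum_i q_i(t+1) q_i(t) / (\lVert Q(t+1)\rVert \lVert Q(t)\rVert)},
#'   which lies in \[0, 1\] because activations are nonnegative.
#'
#' On the event timeline every row has positive norm, so all four series are
#' defined at every transition. On a grid timeline silent rows make `L_R`
#' and `S` undefined; by default the affected transitions are dropped from all
#' four series jointly (keeping them aligned), `zero_policy = "strict"` raises
#' an error instead.
#'
#' @inheritParams pattern_row_sums
#' @param zero_policy `"drop"` (default) or `"strict"`; only relevant for grid
#'   timelines with silent rows.
#' @return A `transition_series` tibble with columns `t_index` (1-based index
#'   of the transition's starting row), `I`, `L`, `L_R`, `S`.
#' @export
transition_series <- function(pattern, zero_policy = c("drop", "strict")) {
  stopifnot(inherits(pattern, "pattern_sequence"))
  zero_policy <- match.arg(zero_policy)
  Q <- pattern$Q
  Tn <- nrow(Q)
  if (Tn < 2) abort("need >= 2 time steps to compute transitions")
  n <- ncol(Q)
  u <- pattern$u

  from <- Q[-Tn, , drop = FALSE]
  to <- Q[-1, , drop = FALSE]
  d <- to - from
  dist <- sqrt(rowSums(d * d))
  norm_from <- sqrt(rowSums(from * from))
  norm_to <- sqrt(rowSums(to * to))

  I <- (rowSums(to) - rowSums(from)) / (n * u)
  L <- dist / (u * sqrt(n))
  L_R <- dist / norm_to
  S <- rowSums(to * from) / (norm_to * norm_from)

  undefined <- norm_to == 0 | norm_from == 0
  if (any(undefined)) {
    if (zero_policy == "strict") {
      abort("silent (all-zero) pattern rows make L_R/S undefined; use the event timeline or zero_policy = \"drop\"")
    }
    keep <- !undefined
  } else {
    keep <- rep(TRUE, Tn - 1)
  }
  S <- pmin(pmax(S, 0), 1) # guard floating-point spill just outside [0, 1]

  out <- tibble(
    t_index = which(keep),
    I = I[keep], L = L[keep], L_R = L_R[keep], S = S[keep]
  )
  new_tibble(out, n_steps = Tn, n_vertices = n, u = u,
             n_dropped = sum(undefined),
             class = "transition_series", nrow = nrow(out))
}

#' Information-change series
#' @inheritParams transition_series
#' @return Numeric vector of length T - 1 (minus any dropped transitions).
#' @export
information_change_series <- function(pattern,
                                      zero_policy = c("drop", "strict")) {
  transition_series(pattern, zero_policy)$I
}

#' Normalised Euclidean-distance series
#' @inheritParams transition_series
#' @return Numeric vector of nonnegative distances.
#' @export
euclidean_distance_series <- function(pattern,
                                      zero_policy = c("drop", "strict")) {
  transition_series(pattern, zero_policy)$L
}

#' Relative distance-change series
#' @inheritParams transition_series
#' @return Numeric vector of nonnegative relative changes.
#' @export
relative_distance_series <- function(pattern,
                                     zero_policy = c("drop", "strict")) {
  transition_series(pattern, zero_policy)$L_R
}

#' Cosine-similarity series
#' @inheritParams transition_series
#' @return Numeric vector in \[0, 1\].
#' @export
cosine_similarity_series <- function(pattern,
                                     zero_policy = c("drop", "strict")) {
  transition_series(pattern, zero_policy)$S
}

#' Mean and unbiased variance of a transition series
#'
#' The mean is the arithmetic mean over the transitions; the variance is the
#' unbiased (N - 1 divisor) sample variance.
#'
#' @param x Numeric vector (one of the transition series).
#' @param require_variance If `TRUE` (default) a length-1 series is an error,
#'   since the variance needs at least two transitions; if `FALSE` the
#'   variance is returned as `NA` in that case.
#' @return A one-row tibble with columns `mean` and `variance`.
#' @export
summarize_series <- function(x, require_variance = TRUE) {
  if (length(x) == 0) abort("cannot summarise an empty series")
  m <- sum(x) / length(x)
  if (length(x) < 2) {
    if (require_variance) abort("need >= 2 transitions for the variance")
    v <- NA_real_
  } else {
    v <- sum((x - m)^2) / (length(x) - 1)
  }
  tibble(mean = m, variance = v)
}

#' Mixbiotic society measures of a pattern sequence
#'
#' Computes the four transition series, their means and unbiased variances,
#' and the three community-phase measures:
#'
#' * `M_mob = mu_L` — mobism (in-group crowded communication: large ordered
#'   pattern swings);
#' * `M_atom = mu_LR` — atomism (separate, sporadic communication: large
#'   relative change);
#' * `M_mix = mu_S * var_S` — mixism (the balanced, "well-going" intermediate:
#'   similarity that also varies).
#'
#' All three close to zero signals nihilism (near silence). See
#' [classify_phase()].
#'
#' With T time steps there are T - 1 transitions; means divide by the number
#' of transitions actually used and variances by that number minus one.
#' `mean_divisor = "t_max"` instead divides means by T and variances by T - 1,
#' an alternative bookkeeping in which the (uncounted) transition into the
#' first observed step is treated as part of the record; the two conventions
#' differ by a factor (T-1)/T, negligible for the thousands of steps in real
#' recordings. `n_transitions` is reported so the convention in force is
#' always visible.
#'
#' @inheritParams transition_series
#' @param mean_divisor `"transitions"` (default) or `"t_max"`; see Details.
#' @return A one-row `measure_set` tibble with columns `mu_I`, `var_I`,
#'   `mu_L`, `var_L`, `mu_LR`, `var_LR`, `mu_S`, `var_S`, `M_mob`, `M_mix`,
#'   `M_atom`, `n_vertices`, `n_steps`, `n_transitions`.
#' @examples
#' ev <- generate_regime(regime_spec("mixism", seed = 1))
#' mixbiotic_measures(build_pattern_sequence(ev))
#' @export
mixbiotic_measures <- function(pattern,
                               zero_policy = c("drop", "strict"),
                               mean_divisor = c("transitions", "t_max")) {
  stopifnot(inherits(pattern, "pattern_sequence"))
  mean_divisor <- match.arg(mean_divisor)
  Tn <- nrow(pattern$Q)
  if (Tn < 3) abort("need >= 3 time steps so that variances exist")
  ts <- transition_series(pattern, zero_policy)
  m <- nrow(ts)
  if (m < 2) abort("need >= 2 usable transitions for the variances")
  div_mean <- if (mean_divisor == "transitions") m else Tn
  div_var <- if (mean_divisor == "transitions") m - 1 else Tn - 1

  stat <- function(x) {
    mu <- sum(x) / div_mean
    v <- sum((x - mu)^2) / div_var
    c(mu, v)
  }
  si <- stat(ts$I); sl <- stat(ts$L); sr <- stat(ts$L_R); ss <- stat(ts$S)

  out <- tibble(
    mu_I = si[1], var_I = si[2],
    mu_L = sl[1], var_L = sl[2],
    mu_LR = sr[1], var_LR = sr[2],
    mu_S = ss[1], var_S = ss[2],
    M_mob = sl[1],
    M_mix = ss[1] * ss[2],
    M_atom = sr[1],
    n_vertices = ncol(pattern$Q),
    n_steps = Tn,
    n_transitions = m
  )
  new_tibble(out, class = "measure_set", nrow = 1L)
}

#' Glance at a measure set
#' @param x A `measure_set`.
#' @param ... Unused.
#' @return The one-row tibble itself (already in glance form).
#' @export
glance.measure_set <- function(x, ...) as_tibble(x)

#' Tidy a measure set into long form
#' @param x A `measure_set`.
#' @param ... Unused.
#' @return A tibble with columns `statistic` and `value`.
#' @export
tidy.measure_set <- function(x, ...) {
  wide <- as_tibble(x)[, c("mu_I", "var_I", "mu_L", "var_L", "mu_LR",
                           "var_LR", "mu_S", "var_S",
                           "M_mob", "M_mix", "M_atom")]
  tidyr::pivot_longer(wide, cols = dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' Classify the community phase of a measure set
#'
#' A community whose three measures are all below `epsilon` is in the
#' *nihilism* phase (static and silent). Otherwise the phase is the measure
#' that is largest after per-measure min-max rescaling across a comparison set
#' of communities (`reference`); without a reference the raw values are
#' compared directly. The three measures live on different scales, so a
#' reference set of comparable communities is recommended whenever one is
#' available. Exact ties are broken in the fixed order mixism > mobism >
#' atomism. The decision rule itself is a pragmatic convention layered on top
#' of the measures, which only hypothesise which measure dominates each phase.
#'
#' @param measures A one-row `measure_set` (from [mixbiotic_measures()]).
#' @param reference Optional: a `measure_set` tibble with several rows, or a
#'   list of measure sets, defining the comparison set used for rescaling.
#'   `measures` is included automatically.
#' @param epsilon Positive threshold below which all measures count as zero
#'   (default `1e-3`).
#' @return One of `"nihilism"`, `"mobism"`, `"mixism"`, `"atomism"`.
#' @export
classify_phase <- function(measures, reference = NULL, epsilon = 1e-3) {
  stopifnot(inherits(measures, "measure_set") || is.data.frame(measures))
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("epsilon must be a single positive number")
  }
  raw <- c(mixism = measures$M_mix[1],
           mobism = measures$M_mob[1],
           atomism = measures$M_atom[1])
  if (max(raw) < epsilon) return("nihilism")

  if (!is.null(reference)) {
    ref <- if (is.data.frame(reference)) reference else bind_rows(reference)
    pool <- bind_rows(
      as_tibble(measures)[, c("M_mix", "M_mob", "M_atom")],
      as_tibble(ref)[, c("M_mix", "M_mob", "M_atom")]
    )
    rescale <- function(col, x) {
      lo <- min(pool[[col]]); hi <- max(pool[[col]])
      if (hi > lo) (x - lo) / (hi - lo) else 0
    }
    vals <- c(mixism = rescale("M_mix", raw[["mixism"]]),
              mobism = rescale("M_mob", raw[["mobism"]]),
              atomism = rescale("M_atom", raw[["atomism"]]))
  } else {
    vals <- raw
  }
  names(vals)[which.max(vals)] # first max wins: mixism > mobism > atomism
}

#' Normalise measures across communities for a radar chart
#'
#' Divides each item by its maximum across the supplied communities, so each
#' radar axis runs over \[0, 1\] and at least one community reaches 1 on every
#' axis. Items that are identically zero across all communities are reported
#' as all-zero with a warning.
#'
#' @param sets A data frame of communities by measure columns with a
#'   `community` identifier column, or a named list of one-row measure-set /
#'   feature tibbles.
#' @param items Character vector of column names to normalise (default the
#'   three phase measures).
#' @return A `radar_profile` tibble in long form: `community`, `item`,
#'   `value`, `normalized`.
#' @export
normalize_radar <- function(sets, items = c("M_mob", "M_mix", "M_atom")) {
  if (!is.data.frame(sets)) {
    if (is.null(names(sets)) || any(names(sets) == "")) {
      abort("a list of measure sets must be named by community")
    }
    sets <- bind_rows(lapply(sets, as_tibble), .id = "community")
  }
  sets <- as_tibble(sets)
  if (!("community" %in% names(sets))) {
    sets$community <- paste0("community_", seq_len(nrow(sets)))
  }
  missing_items <- setdiff(items, names(sets))
  if (length(missing_items) > 0) {
    abort(paste0("item(s) not present in every set: ",
                 paste(missing_items, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(sets[, c("community", items)],
                              cols = all_of(items),
                              names_to = "item", values_to = "value")
  long <- dplyr::group_by(long, .data$item)
  long <- dplyr::mutate(
    long,
    normalized = if (max(.data$value) > 0) .data$value / max(.data$value) else 0
  )
  long <- dplyr::ungroup(long)
  zero_items <- unique(long$item[ave_max_zero(long)])
  if (length(zero_items) > 0) {
    warn(paste0("item(s) with zero maximum reported as all-zero: ",
                paste(zero_items, collapse = ", ")))
  }
  new_tibble(long, class = "radar_profile", nrow = nrow(long))
}

ave_max_zero <- function(long) {
  mx <- tapply(long$value, long$item, max)
  mx[long$item] == 0
}
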