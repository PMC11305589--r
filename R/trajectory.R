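#' Polar communication trajectory
#'
#' Maps every pattern row to a point in polar coordinates: the moving radius
#' `r(t)` is the Euclidean norm of Q(t), and the declination angle `theta(t)`
#' is the angle between Q(t) and the all-ones direction,
#' \eqn{\arccos(\sum_i q_i(t) / (\lVert Q(t)\rVert \sqrt n))}. Because the
#' activations are nonnegative, theta always lies in the first quadrant,
#' \[0, pi/2\]; it is 0 exactly when all components are equal and positive.
#' Silent rows (grid timelines only) have `r = 0` and an undefined angle,
#' recorded as `NA` rather than as an arbitrary value.
#'
#' Connecting the points in time order (see [trajectory_segments()]) draws the
#' community's communication trajectory: mob-like communities sweep back and
#' forth along the diagonal, atom-like ones jitter near the origin at wide
#' angles.
#'
#' @inheritParams pattern_row_sums
#' @return A `polar_trajectory` tibble with columns `t_index`, `time`, `r`,
#'   `theta`.
#' @export
polar_trajectory <- function(pattern) {
  stopifnot(inherits(pattern, "pattern_sequence"))
  Q <- pattern$Q
  n <- ncol(Q)
  r <- sqrt(rowSums(Q * Q))
  ratio <- ifelse(r > 0, rowSums(Q) / (r * sqrt(n)), NA_real_)
  theta <- acos(pmin(pmax(ratio, 0), 1))
  out <- tibble(
    t_index = seq_len(nrow(Q)),
    time = pattern$times,
    r = unname(r),
    theta = unname(theta)
  )
  new_tibble(out, n_vertices = n, class = "polar_trajectory",
             nrow = nrow(out))
}

#' Cartesian segments of a polar trajectory
#'
#' Converts the trajectory points to Cartesian coordinates
#' `(x, y) = (r cos(theta), r sin(theta))` and returns the consecutive line
#' segments that draw it. Points with an undefined angle (silent rows) are
#' skipped; a segment that bridges across one or more skipped points is
#' flagged with `bridged = TRUE`.
#'
#' @param traj A [polar_trajectory()] result.
#' @return A tibble with one row per segment: `t_from`, `t_to`, `x`, `y`,
#'   `xend`, `yend`, `bridged`.
#' @export
trajectory_segments <- function(traj) {
  stopifnot(inherits(traj, "polar_trajectory"))
  usable <- !is.na(traj$theta)
  if (sum(usable) < 2) {
    abort("need >= 2 points with a defined angle to draw segments")
  }
  pts <- traj[usable, , drop = FALSE]
  px <- pts$r * cos(pts$theta)
  py <- pts$r * sin(pts$theta)
  k <- nrow(pts)
  tibble(
    t_from = pts$t_index[-k],
    t_to = pts$t_index[-1],
    x = px[-k], y = py[-k],
    xend = px[-1], yend = py[-1],
    bridged = diff(pts$t_index) > 1L
  )
}

#' Export a trajectory as CSV
#'
#' Columns `time`, `r`, `theta`, `x`, `y`; silent rows keep `r = 0` with
#' missing angle and coordinates.
#'
#' @inheritParams trajectory_segments
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "polar_trajectory"))
  df <- data.frame(
    time = traj$time,
    r = traj$r,
    theta = traj$theta,
    x = traj$r * cos(traj$theta),
    y = traj$r * sin(traj$theta)
  )
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
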