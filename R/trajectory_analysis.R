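#' Center-of-mass distance between two groups
#'
#' Euclidean distance between the mass-weighted centroids of two coordinate
#' groups in one frame.
#'
#' @param group_a,group_b Coordinate matrices (one row per point) or single
#'   coordinate vectors.
#' @param masses_a,masses_b Optional positive masses, one per row.
#' @return The distance (scalar).
#' @export
com_distance <- function(group_a, group_b, masses_a = NULL, masses_b = NULL) {
  com <- function(g, m) {
    if (is.null(dim(g))) g <- matrix(g, nrow = 1)
    g <- as.matrix(g)
    if (nrow(g) < 1) stop("empty group")
    if (is.null(m)) m <- rep(1, nrow(g))
    stopifnot(length(m) == nrow(g), all(m > 0))
    colSums(g * m) / sum(m)
  }
  a <- com(group_a, masses_a)
  b <- com(group_b, masses_b)
  if (length(a) != length(b)) stop("groups have different dimensionality")
  sqrt(sum((a - b)^2))
}

#' Distance series over a trajectory
#'
#' Evaluates a supervision metric on every frame of a trajectory.
#'
#' @param traj A `trajectory`.
#' @param metric A `supervision_metric`.
#' @return A `distance_series`: data frame with `time` and `value`, carrying
#'   the metric as an attribute.
#' @export
distance_series <- function(traj, metric) {
  stopifnot(inherits(traj, "trajectory"))
  out <- data.frame(time = traj$times,
                    value = eval_metric(metric, traj$coords))
  attr(out, "metric") <- metric
  class(out) <- c("distance_series", class(out))
  out
}

#' Pocket residence summary
#'
#' Fraction of frames with distance at or below `cutoff`, the number of
#' contiguous in-pocket visits, and the longest dwell. A dwell of length n
#' frames is scored as `n * dt` with `dt` the median frame spacing; no
#' smoothing is applied (a single below-cutoff frame counts as a visit).
#'
#' @param series A `distance_series` or data frame with `time` and `value`.
#' @param cutoff Positive distance cutoff.
#' @return List with `cutoff`, `fraction_within`, `longest_dwell`,
#'   `n_entries`, `median_value`.
#' @export
residence <- function(series, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (nrow(series) < 1) stop("empty series")
  inside <- series$value <= cutoff
  runs <- rle(inside)
  n_entries <- sum(runs$values)
  dt <- if (nrow(series) > 1) stats::median(diff(series$time)) else 1
  longest <- if (n_entries > 0) max(runs$lengths[runs$values]) * dt else 0
  list(cutoff = cutoff, fraction_within = mean(inside),
       longest_dwell = longest, n_entries = n_entries,
       median_value = stats::median(series$value))
}

#' Optimal superposition RMSD (Kabsch)
#'
#' Least-squares rigid superposition of `coords_b` onto `coords_a` using the
#' Kabsch singular-value-decomposition construction, with the determinant
#' constrained to +1 (proper rotations only — no reflections, the molecular
#' convention). Works in 2 or 3 dimensions.
#'
#' @param coords_a,coords_b Matrices of matching size (points in rows).
#' @param weights Optional positive per-point weights.
#' @return List with `rmsd`, `rotation` (applied to centered b), and
#'   `translation` such that `b %*% t(rotation) + translation` superposes
#'   onto a.
#' @export
superpose_rmsd <- function(coords_a, coords_b, weights = NULL) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b))) stop("mismatched point counts or dimensions")
  if (nrow(a) < 1) stop("need at least one point")
  if (is.null(weights)) weights <- rep(1, nrow(a))
  stopifnot(length(weights) == nrow(a), all(weights > 0))
  w <- weights / sum(weights)
  ca <- colSums(a * w); cb <- colSums(b * w)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- t(B * w) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(rep(1, ncol(a) - 1), d))
  R <- sv$v %*% D %*% t(sv$u)
  Brot <- B %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((Brot - A)^2)))
  list(rmsd = rmsd, rotation = R, translation = ca - cb %*% t(R))
}

#' Per-frame potential energy
#'
#' The toy analog of a ligand-complex interaction-energy series: the
#' potential energy of the ligand particle at each stored frame.
#'
#' @param traj A `trajectory`.
#' @param field A `potential_field`.
#' @return Data frame with `time` and `energy` (kT).
#' @export
frame_energy <- function(traj, field) {
  stopifnot(inherits(traj, "trajectory"), inherits(field, "potential_field"))
  if (any(abs(traj$coords) > field$box_half_width + 1e-9))
    stop("trajectory frame outside the field's box")
  data.frame(time = traj$times,
             energy = apply(traj$coords, 1, field$potential))
}
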