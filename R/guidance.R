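# Trajectory generation and color-coded entry-angle guidance: the straight
# segment from the surgical entry point to the target, the scalpel's angular
# deviation from it, the remaining insertion depth, and the red/yellow/green
# feedback color.

#' Build a surgical trajectory
#'
#' @param entry,target length-3 points (mm); must differ.
#' @return A `trajectory`: `entry`, `target`, `direction` (unit vector),
#'   `length` (mm).
#' @examples
#' build_trajectory(c(0, 0, 0), c(0, 0, 10))
#' @export
build_trajectory <- function(entry, target) {
  entry <- as.numeric(entry); target <- as.numeric(target)
  stopifnot(length(entry) == 3L, length(target) == 3L)
  d <- target - entry
  len <- sqrt(sum(d^2))
  if (len == 0) stop("degenerate trajectory: entry equals target")
  structure(list(entry = entry, target = target,
                 direction = d / len, length = len),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> length %.2f mm, direction (%.3f, %.3f, %.3f)\n",
    x$length, x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Angular deviation between the scalpel axis and the trajectory
#'
#' Arc cosine of the (clamped) dot product of the two unit directions, in
#' degrees.
#'
#' @param scalpel_direction length-3 unit vector of the scalpel shaft.
#' @param traj a [build_trajectory()] trajectory.
#' @return Deviation in degrees, in `[0, 180]`.
#' @export
angle_deviation <- function(scalpel_direction, traj) {
  stopifnot(inherits(traj, "trajectory"))
  d <- as.numeric(scalpel_direction)
  n <- sqrt(sum(d^2))
  if (n < 1e-12) stop("invalid direction: zero-norm scalpel axis")
  if (abs(n - 1) > 1e-9) d <- d / n
  dotp <- min(max(sum(d * traj$direction), -1), 1)
  acos(dotp) * 180 / pi
}

#' Guidance color for an angular deviation
#'
#' Green when aligned, yellow when close, red otherwise. Boundaries are
#' inclusive: a deviation exactly at `green_max` is green. The defaults
#' (green <= 2 deg, yellow <= 10 deg) reflect the few-degree alignment
#' tolerance expected during catheter insertion; both are configurable.
#'
#' @param deviation_deg deviation in degrees, `[0, 180]`.
#' @param thresholds named list/vector with `green_max` and `yellow_max`.
#' @return `"green"`, `"yellow"` or `"red"`.
#' @export
guidance_color <- function(deviation_deg,
                           thresholds = c(green_max = 2, yellow_max = 10)) {
  stopifnot(all(deviation_deg >= 0), all(deviation_deg <= 180),
            thresholds[["green_max"]] <= thresholds[["yellow_max"]])
  ifelse(deviation_deg <= thresholds[["green_max"]], "green",
         ifelse(deviation_deg <= thresholds[["yellow_max"]], "yellow", "red"))
}

#' Remaining insertion depth
#'
#' Signed projection of `target - tip` onto the trajectory direction: the
#' full length at the entry point, 0 when the tip reaches the target plane,
#' negative on overshoot. Lateral displacement of the tip does not change
#' the depth.
#'
#' @param tip length-3 scalpel tip position (mm).
#' @param traj a [build_trajectory()] trajectory.
#' @return Depth in mm.
#' @export
remaining_depth <- function(tip, traj) {
  stopifnot(inherits(traj, "trajectory"), length(tip) == 3L)
  sum((traj$target - as.numeric(tip)) * traj$direction)
}

#' Perpendicular distance of the tip from the trajectory line
#'
#' Complements [angle_deviation()]: how far the tip sits off the planned
#' line, regardless of shaft orientation.
#'
#' @inheritParams remaining_depth
#' @return Lateral offset in mm.
#' @export
lateral_offset <- function(tip, traj) {
  stopifnot(inherits(traj, "trajectory"), length(tip) == 3L)
  v <- as.numeric(tip) - traj$entry
  along <- sum(v * traj$direction)
  sqrt(max(sum(v^2) - along^2, 0))
}

#' Replay a tracked pose stream into per-sample guidance states
#'
#' For each tracked tip sample the scalpel shaft is taken as the direction
#' from the entry point to the tip; deviation, remaining depth, lateral
#' offset and feedback color are computed against the planned trajectory.
#' A tip still at the entry point has undefined shaft direction and reports
#' zero deviation.
#'
#' @param stream a `pose_stream` (columns `t`, `x`, `y`, `z`) of tip
#'   positions.
#' @param traj a [build_trajectory()] trajectory.
#' @param thresholds color thresholds, see [guidance_color()].
#' @return data.frame: `t`, `deviation_deg`, `depth_mm`, `lateral_mm`,
#'   `color`.
#' @export
replay_guidance <- function(stream, traj,
                            thresholds = c(green_max = 2, yellow_max = 10)) {
  stopifnot(inherits(traj, "trajectory"),
            all(c("t", "x", "y", "z") %in% names(stream)))
  tips <- as.matrix(stream[, c("x", "y", "z")])
  out <- data.frame(t = stream$t, deviation_deg = 0, depth_mm = 0,
                    lateral_mm = 0, color = "green",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tips))) {
    tip <- tips[i, ]
    shaft <- tip - traj$entry
    dev <- if (sqrt(sum(shaft^2)) < 1e-12) 0 else angle_deviation(shaft, traj)
    out$deviation_deg[i] <- dev
    out$depth_mm[i] <- remaining_depth(tip, traj)
    out$lateral_mm[i] <- lateral_offset(tip, traj)
    out$color[i] <- guidance_color(dev, thresholds)
  }
  out
}
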