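# Per-frame kinematic signals derived from tracked body points.
#
# All angles are in radians internally; degrees appear only at I/O.
# Conventions: Cartesian arena frame with y up; counter-clockwise positive.

#' Construct a larval trajectory
#'
#' Bundles per-frame tracked body-point coordinates with the acquisition
#' calibration. Coordinates are in pixels in a Cartesian (y-up) arena frame;
#' image-coordinate input (y down) is converted by [read_trajectory_csv()].
#'
#' @param frames data.frame with columns `frame` (integer, strictly
#'   increasing), `head_x`, `head_y`, `mid_x`, `mid_y`, `tail_x`, `tail_y`,
#'   `cm_x`, `cm_y` (pixels). An optional `t` column (seconds) is checked
#'   against `frame / frame_rate` and recomputed.
#' @param frame_rate frames per second (default 60).
#' @param px_per_mm spatial calibration, pixels per millimetre (default
#'   11.94).
#' @return An object of class `larva_trajectory`: a list with elements
#'   `frames`, `frame_rate`, `px_per_mm`.
#' @export
trajectory <- function(frames, frame_rate = 60, px_per_mm = 11.94) {
  stopifnot(is.data.frame(frames), frame_rate > 0, px_per_mm > 0)
  req <- c("frame", "head_x", "head_y", "mid_x", "mid_y",
           "tail_x", "tail_y", "cm_x", "cm_y")
  missing_cols <- setdiff(req, names(frames))
  if (length(missing_cols) > 0L) {
    stop("trajectory frames missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(frames) < 2L) {
    stop("trajectory too short: need at least 2 frames, got ", nrow(frames))
  }
  fr <- frames$frame
  if (any(fr < 0) || any(diff(fr) <= 0)) {
    bad <- which(c(FALSE, diff(fr) <= 0))[1]
    stop("frame index must be nonnegative and strictly increasing",
         if (!is.na(bad)) paste0(" (violated at row ", bad, ")") else "")
  }
  if (!is.null(frames$t)) {
    expect_t <- fr / frame_rate
    if (any(abs(frames$t - expect_t) > 1e-6, na.rm = TRUE)) {
      stop("column t inconsistent with frame / frame_rate")
    }
  }
  frames$t <- fr / frame_rate
  structure(list(frames = frames[c("frame", "t", req[-1])],
                 frame_rate = frame_rate, px_per_mm = px_per_mm),
            class = "larva_trajectory")
}

#' @export
print.larva_trajectory <- function(x, ...) {
  dur <- diff(range(x$frames$t))
  cat(sprintf("<larva_trajectory> %d frames, %.2f s at %g fps, %g px/mm\n",
              nrow(x$frames), dur, x$frame_rate, x$px_per_mm))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$frames)

point_matrix <- function(traj, which = c("head", "mid", "tail", "cm")) {
  which <- match.arg(which)
  as.matrix(traj$frames[paste0(which, c("_x", "_y"))])
}

# Signed angle from vector a to vector b (row-wise), CCW positive, (-pi, pi].
signed_angle <- function(a, b) {
  ang <- atan2(a[, 1] * b[, 2] - a[, 2] * b[, 1],
               a[, 1] * b[, 1] + a[, 2] * b[, 2])
  ang[!is.na(ang) & ang <= -pi] <- pi
  ang
}

#' Body-bend angle (headtheta)
#'
#' Signed angle between the head--midpoint axis and the midpoint--tail axis:
#' the angle from the tail-to-mid direction to the mid-to-head direction,
#' counter-clockwise positive, in (-pi, pi]. Zero for a straight body.
#' Frames with coincident points yield `NA` rather than an error.
#'
#' @param head,mid,tail n x 2 matrices (or length-2 vectors) of coordinates.
#' @return numeric vector of angles in radians.
#' @export
compute_headtheta <- function(head, mid, tail) {
  head <- rbind2cols(head); mid <- rbind2cols(mid); tail <- rbind2cols(tail)
  u <- mid - tail   # tail -> mid
  v <- head - mid   # mid -> head
  th <- signed_angle(u, v)
  deg <- rowSums(u * u) == 0 | rowSums(v * v) == 0
  th[deg] <- NA_real_
  th
}

#' Body-axis orientation (bodytheta)
#'
#' Angle of the tail-to-mid direction measured counter-clockwise from the
#' +x (horizontal) arena axis, in (-pi, pi]. Unwrapping across frames is the
#' job of [differentiate_angle()].
#'
#' @inheritParams compute_headtheta
#' @return numeric vector of angles in radians.
#' @export
compute_bodytheta <- function(mid, tail) {
  mid <- rbind2cols(mid); tail <- rbind2cols(tail)
  u <- mid - tail
  th <- atan2(u[, 2], u[, 1])
  th[rowSums(u * u) == 0] <- NA_real_
  th
}

rbind2cols <- function(p) {
  if (is.null(dim(p))) return(matrix(p, ncol = 2))
  p <- as.matrix(p)
  if (ncol(p) == 1L && nrow(p) == 2L) p <- t(p)   # column-vector point
  p
}

# Central differences on the interior, one-sided at the endpoints.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  d <- numeric(n)
  if (n == 2L) {
    d[] <- (x[2] - x[1]) / dt
    return(d)
  }
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  i <- 2:(n - 1)
  d[i] <- (x[i + 1] - x[i - 1]) / (2 * dt)
  d
}

#' Per-frame speed of a tracked point
#'
#' Finite-difference speed in mm/s: central differences on interior frames,
#' one-sided differences at the two endpoints.
#'
#' @param points n x 2 matrix of per-frame coordinates in pixels.
#' @param frame_rate frames per second.
#' @param px_per_mm pixels per millimetre.
#' @return numeric vector of nonnegative speeds (mm/s), one per frame.
#' @export
compute_speed <- function(points, frame_rate, px_per_mm) {
  points <- rbind2cols(points)
  if (nrow(points) < 2L) stop("trajectory too short: need at least 2 frames")
  dt <- 1 / frame_rate
  vx <- central_diff(points[, 1], dt)
  vy <- central_diff(points[, 2], dt)
  sqrt(vx^2 + vy^2) / px_per_mm
}

#' Angular speed of an angle series
#'
#' Phase-unwraps the series (removing 2*pi jumps) before central-difference
#' differentiation, so angular speed is continuous across the +/- pi wrap.
#'
#' @param theta angle series in radians.
#' @param frame_rate frames per second.
#' @return angular speed in rad/s, same length as `theta`.
#' @export
differentiate_angle <- function(theta, frame_rate) {
  if (length(theta) < 2L) stop("trajectory too short: need at least 2 frames")
  central_diff(signal::unwrap(theta), 1 / frame_rate)
}

#' Centred moving average with shrinking edge windows
#'
#' @param series numeric vector.
#' @param window odd window length in frames; `window = 1` is the identity.
#'   At the edges the window shrinks to the available frames (still centred
#'   on the output frame).
#' @return smoothed series, same length as the input.
#' @export
moving_average <- function(series, window) {
  n <- length(series)
  if (length(window) != 1L || is.na(window) || window < 1 ||
      window %% 2 == 0) {
    stop("window must be an odd positive integer")
  }
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  if (window == 1L) return(series)
  h <- (window - 1L) %/% 2L
  s <- cumsum(c(0, series))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

# Linear interpolation of NA runs no longer than max_gap frames; errors on
# longer runs or NA at the series ends.
fill_short_gaps <- function(x, max_gap, what = "coordinate") {
  if (!anyNA(x)) return(x)
  idx <- which(is.na(x))
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad_runs <- which(r$values & r$lengths > max_gap)
  if (length(bad_runs) > 0L) {
    stop("invalid ", what, " gap of ", r$lengths[bad_runs[1]],
         " frames (max tolerated ", max_gap, ") starting at row ",
         starts[bad_runs[1]])
  }
  if (is.na(x[1]) || is.na(x[length(x)])) {
    stop("invalid ", what, " at trajectory boundary cannot be interpolated")
  }
  x[idx] <- stats::approx(seq_along(x), x, xout = idx)$y
  x
}

#' Compute the full kinematic series of a trajectory
#'
#' Derives tailspeed/headspeed/midspeed/cmspeed (mm/s), headtheta and
#' bodytheta (rad) and their angular speeds headomega and bodyomega (rad/s)
#' from tracked body points.
#'
#' Numerical pipeline: frames with missing or degenerate (coincident)
#' points are linearly interpolated when the gap is at most
#' `config$max_gap_frames`; positions are moving-average smoothed
#' (`config$smooth_window`) before differentiation; tailspeed is the norm
#' of the component-wise smoothed tail velocity; headomega and bodyomega
#' are moving-average smoothed after differentiation. headspeed, midspeed
#' and cmspeed are left unsmoothed beyond the position smoothing.
#'
#' @param traj a [trajectory()].
#' @param config a [cast_config()]; `smooth_window` and `max_gap_frames`
#'   are used here.
#' @return data.frame of class `larva_kinematics` with columns `frame`,
#'   `t`, `headspeed`, `midspeed`, `tailspeed`, `cmspeed`, `headtheta`,
#'   `headomega`, `bodytheta`, `bodyomega`. Attributes `frame_rate` and
#'   `px_per_mm` echo the trajectory calibration.
#' @export
compute_kinematics <- function(traj, config = cast_config()) {
  stopifnot(inherits(traj, "larva_trajectory"))
  fps <- traj$frame_rate
  ppm <- traj$px_per_mm
  w <- config$smooth_window
  f <- traj$frames

  pts <- list(head = point_matrix(traj, "head"),
              mid  = point_matrix(traj, "mid"),
              tail = point_matrix(traj, "tail"),
              cm   = point_matrix(traj, "cm"))

  # flag degenerate frames (coincident points) as invalid, then interpolate
  deg <- rowSums((pts$head - pts$mid)^2) == 0 |
         rowSums((pts$mid - pts$tail)^2) == 0
  deg[is.na(deg)] <- FALSE
  for (nm in names(pts)) {
    p <- pts[[nm]]
    p[deg, ] <- NA_real_
    p[, 1] <- fill_short_gaps(p[, 1], config$max_gap_frames)
    p[, 2] <- fill_short_gaps(p[, 2], config$max_gap_frames)
    # position smoothing: suppresses tracker jitter before differentiation
    p[, 1] <- moving_average(p[, 1], w)
    p[, 2] <- moving_average(p[, 2], w)
    pts[[nm]] <- p
  }

  dt <- 1 / fps
  smooth_speed <- function(p) {
    vx <- moving_average(central_diff(p[, 1], dt), w)
    vy <- moving_average(central_diff(p[, 2], dt), w)
    sqrt(vx^2 + vy^2) / ppm
  }

  headtheta <- compute_headtheta(pts$head, pts$mid, pts$tail)
  bodytheta <- compute_bodytheta(pts$mid, pts$tail)
  headomega <- moving_average(differentiate_angle(headtheta, fps), w)
  bodyomega <- moving_average(differentiate_angle(bodytheta, fps), w)

  out <- data.frame(
    frame = f$frame,
    t = f$t,
    headspeed = compute_speed(pts$head, fps, ppm),
    midspeed  = compute_speed(pts$mid, fps, ppm),
    tailspeed = smooth_speed(pts$tail),
    cmspeed   = compute_speed(pts$cm, fps, ppm),
    headtheta = headtheta,
    headomega = headomega,
    bodytheta = bodytheta,
    bodyomega = bodyomega
  )
  class(out) <- c("larva_kinematics", "data.frame")
  attr(out, "frame_rate") <- fps
  attr(out, "px_per_mm") <- ppm
  out
}

#' Diagnostic traces of the four event-defining signals
#'
#' Plots tailspeed, headomega, headtheta and bodyomega against time, with
#' detected stop periods shaded, in the layout conventionally used for
#' single turn events.
#'
#' @param x a `larva_kinematics` data.frame.
#' @param stops optional stop-period table from [detect_stop_periods()].
#' @param config a [cast_config()]; thresholds are drawn as dashed lines.
#' @param ... passed to [plot()].
#' @export
plot.larva_kinematics <- function(x, stops = NULL, config = cast_config(),
                                  ...) {
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 0.5, 0.5))
  on.exit(graphics::par(op))
  panels <- list(
    tailspeed = list(x$tailspeed, "tailspeed (mm/s)",
                     config$tailspeed_stop_thresh),
    headomega = list(x$headomega, "headomega (rad/s)",
                     c(-1, 1) * config$headomega_peak_thresh),
    headtheta = list(x$headtheta, "headtheta (rad)", NULL),
    bodyomega = list(x$bodyomega, "bodyomega (rad/s)",
                     c(-1, 1) * config$bodyomega_turn_thresh)
  )
  for (nm in names(panels)) {
    p <- panels[[nm]]
    plot(x$t, p[[1]], type = "l", xlab = "", ylab = p[[2]], ...)
    if (!is.null(stops) && nrow(stops) > 0) {
      graphics::rect(x$t[stops$start], graphics::par("usr")[3],
                     x$t[stops$end], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("grey", 0.3), border = NA)
    }
    if (!is.null(p[[3]])) graphics::abline(h = p[[3]], lty = 2, col = "red")
  }
  invisible(x)
}
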