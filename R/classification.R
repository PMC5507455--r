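# Turn assembly, light-relatedness, success scoring.

#' Assemble turn events from stops, casts and bodyomega
#'
#' The anatomy of a turn: a drop of tailspeed below threshold (stop
#' onset), one or more supra-threshold headomega peaks (the casts), and
#' finally a supra-threshold |bodyomega| peak marking the reorientation of
#' the midpoint-tail axis. For each stop period containing at least one
#' cast, the first |bodyomega| peak exceeding `bodyomega_turn_thresh` at
#' or after the last cast's peak and before the next stop period becomes
#' the turn peak; stop periods whose casts are not followed by such a peak
#' emit no turn.
#'
#' @param kin a `larva_kinematics` data.frame.
#' @param stops stop periods from [detect_stop_periods()].
#' @param casts cast table from [detect_head_casts()].
#' @param config a [cast_config()].
#' @return data.frame with one row per turn: `turn_id`, `stop_id`,
#'   `stop_start`, `turn_peak` (1-based frame rows), `n_casts`, `kind`
#'   ("1-cast"/"n-cast").
#' @export
assemble_turns <- function(kin, stops, casts, config = cast_config()) {
  empty <- data.frame(turn_id = integer(), stop_id = integer(),
                      stop_start = integer(), turn_peak = integer(),
                      n_casts = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  if (nrow(stops) == 0L || nrow(casts) == 0L) return(empty)
  omega <- kin$bodyomega
  n <- length(omega)
  rows <- list()
  for (s in seq_len(nrow(stops))) {
    sc <- casts[casts$stop_id == stops$stop_id[s], , drop = FALSE]
    if (nrow(sc) == 0L) next
    last_peak <- max(sc$peak)
    nxt <- stops$start[stops$start > stops$end[s]]
    hi <- if (length(nxt) > 0) min(nxt) - 1L else n
    if (hi <= last_peak) next
    win <- last_peak:hi
    pd <- peakdet(abs(omega[win]), config$peak_delta, x = win)
    qual <- pd$maxima[pd$maxima$value > config$bodyomega_turn_thresh, ,
                      drop = FALSE]
    if (nrow(qual) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      stop_id = stops$stop_id[s],
      stop_start = stops$start[s],
      turn_peak = as.integer(qual$pos[1]),
      n_casts = nrow(sc),
      kind = if (nrow(sc) == 1L) "1-cast" else "n-cast",
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- cbind(turn_id = seq_len(nrow(out)), out)
  out
}

#' Light-relatedness of a turn
#'
#' A turn is light-avoidance related iff its initiation distance (signed
#' head-to-spot-edge distance at stop start, nominal edge) lies within
#' 20 px when initiated outside the spot or within 50 px when initiated
#' inside, and the total light exposure accumulated by stop start is
#' below the 5 s cutoff (excluding light-adaptation effects).
#'
#' @param init_distance signed px from head to the nominal spot edge at
#'   the stop-period start (positive outside, negative inside).
#' @param exposure_at_start cumulative light exposure at stop start, s.
#' @param config a [cast_config()].
#' @return logical vector.
#' @export
is_light_related <- function(init_distance, exposure_at_start,
                             config = cast_config()) {
  near <- ifelse(init_distance >= 0,
                 init_distance <= config$relate_out_px,
                 -init_distance <= config$relate_in_px)
  near & exposure_at_start < config$exposure_cutoff_s
}

#' Score light-avoidance success of a head cast
#'
#' A cast succeeds iff the head is out of the light at the end of the
#' cast (the time headomega drops back to zero), judged against the spot
#' expanded outward by the scatter margin.
#'
#' @param head_end n x 2 matrix (or length-2 vector): head position at
#'   the cast end frame, px.
#' @param spot a [light_spot()].
#' @param config a [cast_config()].
#' @return logical vector.
#' @export
score_cast_success <- function(head_end, spot, config = cast_config()) {
  !head_in_light(head_end, spot, config$success_margin_px)
}

#' Score light-avoidance success of a turn
#'
#' A successful turn brings the head out of the light region by the end
#' of the turn (the qualifying bodyomega peak frame), judged against the
#' same scatter-expanded edge as cast success.
#'
#' @param head_at_peak head position at the turn peak frame, px.
#' @inheritParams score_cast_success
#' @return logical vector.
#' @export
score_turn_success <- function(head_at_peak, spot, config = cast_config()) {
  !head_in_light(head_at_peak, spot, config$success_margin_px)
}

#' Per-trial light-avoidance escape
#'
#' A trial (larva) escapes iff any of its light-related turns succeeded.
#' Trials with no light-related turn are excluded from escape-rate
#' denominators (`NA`).
#'
#' @param turns turn table with logical columns `light_related`,
#'   `success`.
#' @return single logical, or `NA` if the trial has no light-related
#'   turn.
#' @export
score_trial_escape <- function(turns) {
  rel <- turns[turns$light_related %in% TRUE, , drop = FALSE]
  if (nrow(rel) == 0L) return(NA)
  any(rel$success %in% TRUE)
}

#' Heading angle toward the spot edge
#'
#' Acute angle between the larval heading (mid-to-head direction) and the
#' tangent line of the spot boundary at the boundary point nearest the
#' head, in degrees within [0, 90]. 0 deg = heading along the edge,
#' 90 deg = heading radially.
#'
#' @param traj a [trajectory()].
#' @param spot a circular [light_spot()].
#' @param at_frame 1-based frame row at which to evaluate.
#' @return angle in degrees, or `NA` if undefined (head at the spot
#'   centre, or degenerate heading).
#' @export
compute_heading_angle <- function(traj, spot, at_frame) {
  stopifnot(inherits(traj, "larva_trajectory"), spot$shape == "circle")
  h <- point_matrix(traj, "head")[at_frame, , drop = FALSE]
  m <- point_matrix(traj, "mid")[at_frame, , drop = FALSE]
  heading <- h - m
  radial <- h - matrix(spot$center, nrow(h), 2, byrow = TRUE)
  hn <- sqrt(rowSums(heading^2))
  rn <- sqrt(rowSums(radial^2))
  out <- asin(pmin(1, abs(rowSums(heading * radial)) / (hn * rn))) * 180 / pi
  out[hn == 0 | rn == 0] <- NA_real_
  out
}

#' Run the full event analysis on one trajectory
#'
#' Kinematics, stop periods, head casts, turn assembly, light-relatedness
#' and success scoring for a single trial. Success and relatedness use
#' raw (unsmoothed) head positions at the detected event frames.
#'
#' @param traj a [trajectory()].
#' @param spot a [light_spot()] (nominal geometry).
#' @param config a [cast_config()].
#' @param trial_id identifier copied into the output tables.
#' @return list with elements `kin`, `stops`, `casts`, `turns`,
#'   `escaped`. `casts` gains `turn_id` (NA when the stop produced no
#'   turn), `head_end_x/y`, `success`; `turns` gain `init_distance`,
#'   `init_inside`, `exposure_at_start`, `light_related`, `success`,
#'   `heading_angle`.
#' @export
classify_trial <- function(traj, spot, config = cast_config(),
                           trial_id = "trial") {
  kin <- compute_kinematics(traj, config)
  stops <- detect_stop_periods(kin$tailspeed, config, traj$frame_rate)
  casts <- detect_head_casts(kin, stops, config)
  turns <- assemble_turns(kin, stops, casts, config)
  head <- point_matrix(traj, "head")
  exposure <- cumulative_exposure(traj, spot, config$success_margin_px)

  casts$turn_id <- turns$turn_id[match(casts$stop_id, turns$stop_id)]
  if (nrow(casts) > 0L) {
    casts$head_end_x <- head[casts$end, 1]
    casts$head_end_y <- head[casts$end, 2]
    casts$success <- score_cast_success(head[casts$end, , drop = FALSE],
                                        spot, config)
  } else {
    casts$head_end_x <- numeric(0)
    casts$head_end_y <- numeric(0)
    casts$success <- logical(0)
  }

  if (nrow(turns) > 0L) {
    turns$init_distance <- signed_distance(
      head[turns$stop_start, , drop = FALSE], spot)
    turns$init_inside <- turns$init_distance < 0
    turns$exposure_at_start <- exposure[turns$stop_start]
    turns$light_related <- is_light_related(turns$init_distance,
                                            turns$exposure_at_start, config)
    turns$success <- score_turn_success(head[turns$turn_peak, , drop = FALSE],
                                        spot, config)
    turns$heading_angle <- compute_heading_angle(traj, spot,
                                                 turns$stop_start)
  } else {
    turns$init_distance <- numeric(0)
    turns$init_inside <- logical(0)
    turns$exposure_at_start <- numeric(0)
    turns$light_related <- logical(0)
    turns$success <- logical(0)
    turns$heading_angle <- numeric(0)
  }

  stops$trial_id <- rep(trial_id, nrow(stops))
  casts$trial_id <- rep(trial_id, nrow(casts))
  turns$trial_id <- rep(trial_id, nrow(turns))
  list(kin = kin, stops = stops, casts = casts, turns = turns,
       escaped = score_trial_escape(turns))
}
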