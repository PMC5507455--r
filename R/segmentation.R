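# Stop-period, peak and head-cast detection.

#' Analysis configuration
#'
#' Thresholds and windows for the whole pipeline. Defaults follow the
#' published assay calibration (60 fps, 11.94 px/mm): stop threshold
#' 0.21 mm/s (2.5 px/s), head-cast and turn angular-speed thresholds
#' 0.35 rad/s (20.05 deg/s), relatedness windows 20 px outside / 50 px
#' inside the spot edge, 10 px scatter expansion for success scoring and
#' a 5 s total-exposure cutoff.
#'
#' @param tailspeed_stop_thresh stop threshold on tailspeed, mm/s.
#' @param headomega_peak_thresh head-cast peak threshold, rad/s.
#' @param bodyomega_turn_thresh body-turn peak threshold, rad/s.
#' @param min_stop_duration shortest retained stop period, s.
#' @param max_stop_gap longest supra-threshold gap merged into a
#'   surrounding stop period, s; wider than the tailspeed excursions
#'   produced by smoothing-correlated tracking noise, far below genuine
#'   inter-stop crawl phases.
#' @param peak_delta commit delta of [peakdet()], rad/s; well below the
#'   0.35 rad/s event threshold so no qualifying peak is missed, above
#'   post-smoothing jitter.
#' @param smooth_window moving-average window (odd frames) for positions,
#'   tailspeed components, headomega and bodyomega.
#' @param success_margin_px outward spot expansion when scoring success
#'   and accumulating exposure, px.
#' @param relate_out_px,relate_in_px light-relatedness windows for turns
#'   initiated outside / inside the spot, px.
#' @param exposure_cutoff_s turns initiated after this much total light
#'   exposure are not counted as light-related, s.
#' @param straighten_drop_rad net decrease in |headtheta| over a candidate
#'   span that marks it as body straightening rather than a head cast, rad.
#' @param min_cast_sweep_rad smallest net headtheta change over a
#'   candidate span that counts as a head cast, rad; a supra-threshold
#'   angular-speed fluctuation that barely displaces the head is tracking
#'   noise, not a lateral sweep.
#' @param max_gap_frames longest invalid-frame gap interpolated rather
#'   than rejected, frames.
#' @return list of class `cast_config`.
#' @export
cast_config <- function(tailspeed_stop_thresh = 0.21,
                        headomega_peak_thresh = 0.35,
                        bodyomega_turn_thresh = 0.35,
                        min_stop_duration = 0.25,
                        max_stop_gap = 0.25,
                        peak_delta = 0.1,
                        smooth_window = 11,
                        success_margin_px = 10,
                        relate_out_px = 20,
                        relate_in_px = 50,
                        exposure_cutoff_s = 5,
                        straighten_drop_rad = 0.05,
                        min_cast_sweep_rad = 0.1,
                        max_gap_frames = 3) {
  cfg <- list(tailspeed_stop_thresh = tailspeed_stop_thresh,
              headomega_peak_thresh = headomega_peak_thresh,
              bodyomega_turn_thresh = bodyomega_turn_thresh,
              min_stop_duration = min_stop_duration,
              max_stop_gap = max_stop_gap,
              peak_delta = peak_delta,
              smooth_window = smooth_window,
              success_margin_px = success_margin_px,
              relate_out_px = relate_out_px,
              relate_in_px = relate_in_px,
              exposure_cutoff_s = exposure_cutoff_s,
              straighten_drop_rad = straighten_drop_rad,
              min_cast_sweep_rad = min_cast_sweep_rad,
              max_gap_frames = max_gap_frames)
  num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1, logical(1))
  if (!all(num)) stop("all configuration fields must be scalar numeric")
  pos <- c("tailspeed_stop_thresh", "headomega_peak_thresh",
           "bodyomega_turn_thresh", "peak_delta", "smooth_window")
  bad <- pos[vapply(cfg[pos], function(x) x <= 0, logical(1))]
  if (length(bad) > 0) stop("configuration fields must be > 0: ",
                            paste(bad, collapse = ", "))
  if (cfg$smooth_window %% 2 == 0) stop("smooth_window must be odd")
  structure(cfg, class = "cast_config")
}

#' Read / write configuration JSON
#'
#' Unspecified fields take the documented defaults, so a partial JSON file
#' overrides only the fields it names.
#'
#' @param path file path.
#' @return a [cast_config()] (`read_config_json`) or `path` invisibly.
#' @export
read_config_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(j), names(formals(cast_config)))
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(cast_config, j)
}

#' @rdname read_config_json
#' @param config a [cast_config()] to serialise.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "cast_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Detect stop periods from the smoothed tailspeed
#'
#' Maximal runs of frames with tailspeed below the stop threshold.
#' Sub-threshold runs separated by supra-threshold gaps no longer than
#' `max_stop_gap` are merged (short interruptions belong to one continuous
#' stop); merged runs shorter than `min_stop_duration` are discarded
#' (very short sub-threshold dips are not stops).
#'
#' @param tailspeed smoothed tailspeed series, mm/s.
#' @param config a [cast_config()].
#' @param frame_rate frames per second.
#' @return data.frame with columns `stop_id`, `start`, `end` (1-based
#'   frame rows, inclusive) and `duration` (s), ordered by `start`.
#' @export
detect_stop_periods <- function(tailspeed, config = cast_config(),
                                frame_rate = 60) {
  empty <- data.frame(stop_id = integer(), start = integer(),
                      end = integer(), duration = numeric())
  n <- length(tailspeed)
  if (n == 0L) return(empty)
  sub <- tailspeed < config$tailspeed_stop_thresh
  sub[is.na(sub)] <- FALSE
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(empty)
  max_gap <- config$max_stop_gap * frame_rate
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= max_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  dur <- (merged$end - merged$start + 1L) / frame_rate
  keep <- dur >= config$min_stop_duration
  out <- merged[keep, , drop = FALSE]
  data.frame(stop_id = seq_len(nrow(out)), start = out$start,
             end = out$end, duration = dur[keep], row.names = NULL)
}

#' Delta-commit peak detection
#'
#' Alternating local-extremum detector: a maximum is committed at the
#' position of the running maximum once the series falls more than
#' `delta` below it; minima symmetrically. Committed maxima and minima
#' strictly alternate in time. This is the standard delta-commit peak
#' detector used for angular-speed event peaks.
#'
#' @param series numeric vector.
#' @param delta commit threshold, > 0.
#' @param x positions reported for extrema (default indices).
#' @return list with data.frames `maxima` and `minima`, each with columns
#'   `pos` and `value`.
#' @export
peakdet <- function(series, delta, x = seq_along(series)) {
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta <= 0) {
    stop("peakdet delta must be a positive number")
  }
  maxtab <- list()
  mintab <- list()
  mn <- Inf; mx <- -Inf
  mnpos <- NA_real_; mxpos <- NA_real_
  lookformax <- TRUE
  for (i in seq_along(series)) {
    this <- series[i]
    if (this > mx) { mx <- this; mxpos <- x[i] }
    if (this < mn) { mn <- this; mnpos <- x[i] }
    if (lookformax) {
      if (this < mx - delta) {
        maxtab[[length(maxtab) + 1L]] <- c(mxpos, mx)
        mn <- this; mnpos <- x[i]
        lookformax <- FALSE
      }
    } else {
      if (this > mn + delta) {
        mintab[[length(mintab) + 1L]] <- c(mnpos, mn)
        mx <- this; mxpos <- x[i]
        lookformax <- TRUE
      }
    }
  }
  to_df <- function(l) {
    if (length(l) == 0L) {
      data.frame(pos = numeric(), value = numeric())
    } else {
      m <- do.call(rbind, l)
      data.frame(pos = m[, 1], value = m[, 2])
    }
  }
  list(maxima = to_df(maxtab), minima = to_df(mintab))
}

#' Detect head casts within stop periods
#'
#' Within each stop period, candidate peaks of `|headomega|` are found
#' with [peakdet()]; candidates at or below `headomega_peak_thresh` are
#' dropped. Each retained cast spans from the preceding zero-crossing of
#' signed headomega (or the stop start) to the first zero-crossing after
#' the peak (or the stop end). Candidates sharing one zero-crossing-
#' delimited lobe are merged into a single cast (largest peak kept).
#' Candidates over which `|headtheta|` net-decreases by more than
#' `straighten_drop_rad` are excluded as body straightening. Ordinals are
#' assigned per stop period in time order and acceptance labels set with
#' [label_acceptance()].
#'
#' @param kin a `larva_kinematics` data.frame.
#' @param stops stop periods from [detect_stop_periods()].
#' @param config a [cast_config()].
#' @return data.frame with one row per head cast: `stop_id`, `ordinal`,
#'   `start`, `peak`, `end` (1-based frame rows), `peak_omega` (signed
#'   rad/s), `amplitude` (rad/s), `direction` ("left"/"right"),
#'   `acceptance` ("accepted"/"rejected").
#' @export
detect_head_casts <- function(kin, stops, config = cast_config()) {
  empty <- data.frame(stop_id = integer(), ordinal = integer(),
                      start = integer(), peak = integer(), end = integer(),
                      peak_omega = numeric(), amplitude = numeric(),
                      direction = character(), acceptance = character(),
                      stringsAsFactors = FALSE)
  if (nrow(stops) == 0L) return(empty)
  omega <- kin$headomega
  theta <- kin$headtheta
  rows <- list()
  for (s in seq_len(nrow(stops))) {
    lo <- stops$start[s]
    hi <- stops$end[s]
    seg <- omega[lo:hi]
    pd <- peakdet(abs(seg), config$peak_delta, x = lo:hi)
    cand <- pd$maxima
    cand <- cand[cand$value > config$headomega_peak_thresh, , drop = FALSE]
    if (nrow(cand) == 0L) next
    # "dropped to zero": sign change or magnitude within a numerical
    # tolerance of zero (smoothed signals carry rounding residue)
    zero_eps <- 1e-9
    spans <- lapply(cand$pos, function(p) {
      sgn <- sign(omega[p])
      before <- lo:p
      z <- before[omega[before] * sgn <= zero_eps]
      st <- if (length(z) > 0) max(z) + 1L else lo
      after <- p:hi
      z2 <- after[omega[after] * sgn <= zero_eps]
      en <- if (length(z2) > 0) min(z2) else hi
      c(st, en)
    })
    spans <- do.call(rbind, spans)
    # one cast per lobe of signed headomega: merge candidates whose spans
    # coincide, keeping the largest peak
    key <- paste(spans[, 1], spans[, 2])
    keep <- unlist(lapply(split(seq_len(nrow(cand)), key), function(ii) {
      ii[which.max(cand$value[ii])]
    }), use.names = FALSE)
    keep <- sort(keep)
    cand <- cand[keep, , drop = FALSE]
    spans <- spans[keep, , drop = FALSE]
    # body-straightening exclusion: |headtheta| net-decreasing over span;
    # noise exclusion: no appreciable head sweep over the span
    straighten <- abs(theta[spans[, 2]]) <
      abs(theta[spans[, 1]]) - config$straighten_drop_rad
    no_sweep <- abs(theta[spans[, 2]] - theta[spans[, 1]]) <=
      config$min_cast_sweep_rad
    drop <- straighten | no_sweep
    cand <- cand[!drop, , drop = FALSE]
    spans <- spans[!drop, , drop = FALSE]
    if (nrow(cand) == 0L) next
    ord <- order(cand$pos)
    cand <- cand[ord, , drop = FALSE]
    spans <- spans[ord, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      stop_id = stops$stop_id[s],
      ordinal = seq_len(nrow(cand)),
      start = as.integer(spans[, 1]),
      peak = as.integer(cand$pos),
      end = as.integer(spans[, 2]),
      peak_omega = omega[cand$pos],
      amplitude = cand$value,
      direction = ifelse(omega[cand$pos] >= 0, "left", "right"),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(empty)
  casts <- do.call(rbind, rows)
  label_acceptance(casts)
}

#' Label cast acceptance within stop periods
#'
#' A head cast is accepted if no further head cast occurs during the same
#' stop period, rejected if another cast follows: every cast except the
#' last in its stop period is rejected.
#'
#' @param casts cast table (rows sharing `stop_id` must be time-ordered).
#' @return the cast table with an `acceptance` column.
#' @export
label_acceptance <- function(casts) {
  if (nrow(casts) == 0L) {
    casts$acceptance <- character(0)
    return(casts)
  }
  casts$acceptance <- "rejected"
  last <- !duplicated(casts$stop_id, fromLast = TRUE)
  casts$acceptance[last] <- "accepted"
  casts
}
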