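# Scripted trajectory simulator with ground-truth event labels.
#
# Body model: three collinear-at-rest points (head, mid, tail) with rigid
# 2-mm segments. Internally positions are complex numbers (x + iy);
# rotations are multiplications by exp(i*theta). Runs translate the body
# along its axis with a small peristaltic tailspeed ripple; stops hold the
# tail fixed; casts rotate the head--mid segment about the midpoint with a
# raised-cosine angular-velocity pulse; body turns rotate the mid--tail
# axis about the midpoint (head stays put) until the body aligns with the
# final head direction.

SEG_MM <- 2           # head-mid and mid-tail segment length, mm
RUN_SPEED <- 1.0      # crawl speed, mm/s
RIPPLE_MM_S <- 0.095  # peristaltic tailspeed ripple amplitude (< 0.5x stop
                      # threshold so runs never dip into stop range)
HOLD_FRAMES <- 12     # still frames at stop onset and after the last cast
CAST_GAP_FRAMES <- 26 # still frames between consecutive cast pulses:
                      # longer than the full smoothing support (position
                      # moving average +/-5, central difference +/-1,
                      # omega moving average +/-5) so smoothed headomega
                      # returns to exactly zero between pulses and
                      # consecutive same-direction casts stay separable
CAST_T_MIN <- 1.2     # minimum cast duration, s
CAST_OMEGA_MAX <- 3.0 # cap on scripted peak headomega, rad/s
TURN_OMEGA <- 0.8     # scripted peak bodyomega of turns, rad/s
PHI_MIN <- 0.45       # smallest scripted |headtheta| change per cast, rad
PHI_MAX <- 2.7        # largest scripted |headtheta|, rad
PHI_STEP <- 0.1       # |headtheta| must grow by this much per cast (keeps
                      # genuine casts clear of the straightening exclusion)
END_MARGIN_PX <- 3    # min gap between cast-end head and the expanded edge

#' Script one head cast
#'
#' @param target how the cast end point is scripted: `phi` (unsigned
#'   head-bend angle, rad), `s` (absolute signed head-to-edge distance at
#'   cast end, px) or `s_rel` (distance relative to the turn's initiation
#'   distance, px).
#' @param value the target value.
#' @param end_in_light expected membership of the head in the 10-px
#'   expanded spot at cast end (ground-truth success is its negation);
#'   validated against the realised geometry at generation time.
#' @param straighten if TRUE this is a body-straightening pulse (head
#'   returns to zero bend): a scripted non-event exercising the
#'   straightening exclusion, absent from the ground-truth cast list.
#' @return list of class `cast_script`.
#' @export
cast_script <- function(target = c("phi", "s", "s_rel"), value = NULL,
                        end_in_light = NA, straighten = FALSE) {
  if (straighten) {
    return(structure(list(straighten = TRUE), class = "cast_script"))
  }
  target <- match.arg(target)
  stopifnot(is.numeric(value), length(value) == 1, is.logical(end_in_light))
  structure(list(straighten = FALSE, target = target, value = value,
                 end_in_light = end_in_light), class = "cast_script")
}

#' Script one turn event
#'
#' @param init_distance signed head-to-spot-edge distance (px) at stop
#'   start; for the first turn of a trial the approach run is cut when the
#'   head reaches it, for later turns it is ignored (the realised distance
#'   is recorded as ground truth).
#' @param casts list of [cast_script()]s, time-ordered.
#' @param do_body_turn emit the bodyomega turn pulse after the last cast.
#' @param pre_bend initial headtheta (rad) held during the approach
#'   (nonzero only in straightening scenarios).
#' @param run_before_s for turns after the first in a trial: run duration
#'   (s) separating this stop from the previous turn.
#' @return list of class `turn_script`.
#' @export
turn_script <- function(init_distance, casts, do_body_turn = TRUE,
                        pre_bend = 0, run_before_s = 0.4) {
  stopifnot(is.list(casts))
  structure(list(init_distance = init_distance, casts = casts,
                 do_body_turn = do_body_turn, pre_bend = pre_bend,
                 run_before_s = run_before_s), class = "turn_script")
}

# raised-cosine pulse shape over nf frames (nf odd: unique centre peak)
pulse_shape <- function(nf) {
  i <- seq_len(nf)
  0.5 * (1 - cos(2 * pi * i / (nf + 1)))
}

odd_frames <- function(dur_s, fps, minimum = 5L) {
  nf <- max(minimum, round(dur_s * fps))
  if (nf %% 2 == 0) nf <- nf + 1L
  as.integer(nf)
}

# Solve the signed head-bend angle phi bringing the head to distance
# r_target from the spot centre. m: mid-to-centre distance; alpha: signed
# angle from the body axis to the centre direction; L: segment length.
# Returns both solutions (alpha -/+ acos(q)) or NULL if unreachable.
solve_cast_phi <- function(m, L, alpha, r_target) {
  q <- (m^2 + L^2 - r_target^2) / (2 * m * L)
  if (abs(q) > 1) return(NULL)
  a <- acos(q)
  c(alpha - a, alpha + a)
}

#' Simulate one scripted trial
#'
#' Generates a trajectory realising a sequence of [turn_script()]s around
#' a circular light spot, together with ground-truth labels for every
#' scripted stop, cast and turn. The approach run starts with the head
#' ~30 px outside the first scripted initiation distance and is cut the
#' frame the head reaches it. Geometrically unsatisfiable scripts (e.g. a
#' cast that cannot reach darkness from the scripted depth) raise an
#' error naming the trial.
#'
#' @param turns list of [turn_script()]s (may be empty for a pure run).
#' @param arena a circular [light_spot()].
#' @param approach_angle direction (rad) from the spot centre to the
#'   approach start point.
#' @param frame_rate frames per second.
#' @param px_per_mm pixels per millimetre.
#' @param noise_sd Gaussian positional jitter added independently to every
#'   tracked point and frame, px (drawn from the current RNG stream).
#' @param trial_id identifier used in labels and error messages.
#' @param run_out_s trailing run after the last turn, s.
#' @param success_margin_px scatter expansion used for the scripted
#'   success geometry (default 10).
#' @return list with `traj` (a [trajectory()]), `stops`, `casts`, `turns`
#'   (ground-truth data.frames; frame columns are 1-based rows) and
#'   `escaped`.
#' @export
simulate_trial <- function(turns, arena, approach_angle = 0,
                           frame_rate = 60, px_per_mm = 11.94,
                           noise_sd = 0, trial_id = "trial",
                           run_out_s = 1.2,
                           success_margin_px = 10) {
  stopifnot(inherits(arena, "light_spot"), arena$shape == "circle")
  fps <- frame_rate
  L <- SEG_MM * px_per_mm
  R <- arena$radius
  C <- complex(real = arena$center[1], imaginary = arena$center[2])
  fail <- function(...) stop("trial ", trial_id, ": ", ..., call. = FALSE)

  blocks <- list()
  # state: mid position M (complex), body axis b (unit complex, mid->head
  # side), head bend theta (rad)
  st <- list(M = C, b = complex(real = 1), theta = 0)
  head_of <- function(s) s$M + L * s$b * exp(1i * s$theta)
  tail_of <- function(s) s$M - L * s$b
  emit <- function(s, n = 1L) {
    blocks[[length(blocks) + 1L]] <<- cbind(rep(head_of(s), n),
                                            rep(s$M, n), rep(tail_of(s), n))
  }
  n_emitted <- function() sum(vapply(blocks, nrow, integer(1)))
  head_s <- function(s) Mod(head_of(s) - C) - R

  run_frames <- function(s, n) {
    t0 <- n_emitted() / fps
    out <- matrix(complex(1), n, 3)
    for (i in seq_len(n)) {
      v <- RUN_SPEED + RIPPLE_MM_S * sin(2 * pi * 1.5 * (t0 + i / fps))
      s$M <- s$M + (v * px_per_mm / fps) * s$b
      out[i, ] <- c(head_of(s), s$M, tail_of(s))
    }
    blocks[[length(blocks) + 1L]] <<- out
    s
  }
  run_until_head_at <- function(s, target_s) {
    max_n <- 90 * fps
    out <- vector("list", 0)
    n <- 0L
    t0 <- n_emitted() / fps
    while (head_s(s) > target_s) {
      n <- n + 1L
      if (n > max_n) fail("approach never reaches init distance ", target_s)
      v <- RUN_SPEED + RIPPLE_MM_S * sin(2 * pi * 1.5 * (t0 + n / fps))
      s$M <- s$M + (v * px_per_mm / fps) * s$b
      out[[n]] <- c(head_of(s), s$M, tail_of(s))
    }
    if (n == 0L) fail("head already past init distance at approach start")
    blocks[[length(blocks) + 1L]] <<- do.call(rbind, out)
    s
  }
  cast_frames <- function(s, theta_to) {
    delta <- theta_to - s$theta
    dur <- max(CAST_T_MIN, 2 * abs(delta) / CAST_OMEGA_MAX)
    nf <- odd_frames(dur, fps)
    sh <- pulse_shape(nf)
    th <- s$theta + delta * cumsum(sh) / sum(sh)
    out <- matrix(complex(1), nf, 3)
    for (i in seq_len(nf)) {
      si <- s; si$theta <- th[i]
      out[i, ] <- c(head_of(si), si$M, tail_of(si))
    }
    blocks[[length(blocks) + 1L]] <<- out
    s$theta <- theta_to
    peak_rel <- (nf + 1L) %/% 2L
    amp <- abs(delta) * max(sh) / sum(sh) * fps
    list(state = s, nf = nf, peak_rel = peak_rel, amplitude = amp)
  }
  turn_frames <- function(s) {
    # rotate the mid-tail axis about the midpoint until aligned with the
    # head direction; the head does not move
    psi <- s$theta
    dur <- 2 * abs(psi) / TURN_OMEGA
    nf <- odd_frames(dur, fps)
    sh <- pulse_shape(nf)
    rot <- psi * cumsum(sh) / sum(sh)
    out <- matrix(complex(1), nf, 3)
    h <- head_of(s)
    for (i in seq_len(nf)) {
      bi <- s$b * exp(1i * rot[i])
      out[i, ] <- c(h, s$M, s$M - L * bi)
    }
    blocks[[length(blocks) + 1L]] <<- out
    s$b <- s$b * exp(1i * psi)
    s$theta <- 0
    list(state = s, nf = nf, peak_rel = (nf + 1L) %/% 2L)
  }

  truth_stops <- list(); truth_casts <- list(); truth_turns <- list()

  if (length(turns) > 0) {
    ts1 <- turns[[1]]
    u <- exp(1i * approach_angle)
    st$b <- -u
    st$theta <- ts1$pre_bend
    start_s <- max(ts1$init_distance, 0) + 30
    st$M <- C + (R + start_s + L) * u
    if (head_s(st) <= ts1$init_distance) {
      st$M <- C + (R + ts1$init_distance + L + 60) * u
    }
  }

  count_exposure <- function() {
    # frames so far with the head inside the expanded spot
    h <- unlist(lapply(blocks, function(bl) bl[, 1]))
    sum(Mod(h - C) - R < success_margin_px)
  }

  for (k in seq_along(turns)) {
    ts <- turns[[k]]
    if (k == 1L) {
      st <- run_until_head_at(st, ts$init_distance)
    } else {
      st <- run_frames(st, odd_frames(ts$run_before_s, fps))
    }
    stop_start <- n_emitted() + 1L
    init_d <- head_s(st)
    exposure_at_start <- count_exposure() / fps
    if (exposure_at_start >= 5 - 0.3) {
      fail("turn ", k, " starts with ", round(exposure_at_start, 2),
           " s light exposure; too close to the 5 s cutoff")
    }
    if (!(init_d >= -45 && init_d <= 15)) {
      fail("turn ", k, " initiation distance ", round(init_d, 1),
           " px leaves no safety margin inside the relatedness windows")
    }
    emit(st, HOLD_FRAMES)

    n_real <- sum(!vapply(ts$casts, `[[`, logical(1), "straighten"))
    if (ts$do_body_turn && n_real == 0L) {
      fail("a body turn requires at least one head cast")
    }
    cast_rows <- list()
    prev_abs <- abs(st$theta)
    prev_sign <- if (st$theta != 0) sign(st$theta) else
      (if (Arg(( C - st$M) / st$b) >= 0) 1 else -1)
    ordinal <- 0L
    for (ci in seq_along(ts$casts)) {
      cs <- ts$casts[[ci]]
      gap <- if (ci < length(ts$casts)) CAST_GAP_FRAMES else HOLD_FRAMES
      if (cs$straighten) {
        if (abs(st$theta) < 0.3) {
          fail("straightening pulse needs an initial bend >= 0.3 rad")
        }
        res <- cast_frames(st, 0)
        st <- res$state
        prev_abs <- 0
        emit(st, gap)
        next
      }
      # resolve the target bend angle
      m <- Mod(C - st$M)
      alpha <- Arg((C - st$M) / st$b)
      want_sign <- -prev_sign
      theta_to <- NA_real_
      if (cs$target == "phi") {
        cand <- c(want_sign, -want_sign) * abs(cs$value)
      } else {
        sv <- if (cs$target == "s") cs$value else init_d + cs$value
        sols <- solve_cast_phi(m, L, alpha, R + sv)
        if (is.null(sols)) {
          fail("cast ", ordinal + 1L, " cannot reach ", round(sv, 1),
               " px from the spot edge (depth ", round(init_d, 1), " px)")
        }
        cand <- sols[order(sign(sols) != want_sign, abs(sols))]
      }
      for (th in cand) {
        ok <- abs(th) >= PHI_MIN && abs(th) <= PHI_MAX &&
          abs(th) >= prev_abs + PHI_STEP &&
          abs(th - st$theta) >= PHI_MIN
        if (ok) { theta_to <- th; break }
      }
      if (is.na(theta_to)) {
        fail("cast ", ordinal + 1L, " has no feasible bend angle ",
             "(previous |headtheta| ", round(prev_abs, 2), " rad)")
      }
      res <- cast_frames(st, theta_to)
      st <- res$state
      end_frame <- n_emitted()
      end_s <- head_s(st)
      in_light <- end_s - success_margin_px < 0
      if (abs(end_s - success_margin_px) < END_MARGIN_PX) {
        fail("cast ", ordinal + 1L, " ends ", round(end_s, 1),
             " px from the edge: within ", END_MARGIN_PX,
             " px of the expanded boundary")
      }
      if (!is.na(cs$end_in_light) && in_light != cs$end_in_light) {
        fail("cast ", ordinal + 1L, " scripted end_in_light=",
             cs$end_in_light, " but realised geometry gives ", in_light)
      }
      ordinal <- ordinal + 1L
      cast_rows[[ordinal]] <- data.frame(
        trial_id = trial_id, stop_ord = k, ordinal = ordinal,
        start = end_frame - res$nf + 1L,
        peak = end_frame - res$nf + res$peak_rel,
        end = end_frame,
        amplitude = res$amplitude,
        direction = if (theta_to - prev_sign * prev_abs >= 0) "left"
                    else "right",
        success = !in_light,
        stringsAsFactors = FALSE
      )
      prev_abs <- abs(theta_to)
      prev_sign <- sign(theta_to)
      emit(st, gap)
    }
    if (length(cast_rows) == 0L && !any(vapply(ts$casts, `[[`, logical(1),
                                               "straighten"))) {
      fail("turn script without casts")
    }
    casts_df <- if (length(cast_rows) > 0) do.call(rbind, cast_rows) else NULL
    if (!is.null(casts_df)) {
      casts_df$acceptance <- c(rep("rejected", nrow(casts_df) - 1),
                               "accepted")
    }

    turn_peak <- NA_integer_
    if (ts$do_body_turn) {
      res <- turn_frames(st)
      st <- res$state
      turn_peak <- n_emitted() - res$nf + res$peak_rel
    }
    stop_end <- if (ts$do_body_turn) n_emitted() - res$nf else n_emitted()
    truth_stops[[k]] <- data.frame(trial_id = trial_id, stop_ord = k,
                                   start = stop_start, end = stop_end,
                                   stringsAsFactors = FALSE)
    if (!is.null(casts_df)) truth_casts[[k]] <- casts_df
    if (ts$do_body_turn) {
      truth_turns[[k]] <- data.frame(
        trial_id = trial_id, stop_ord = k,
        n_casts = nrow(casts_df),
        kind = if (nrow(casts_df) == 1L) "1-cast" else "n-cast",
        init_distance = init_d,
        success = casts_df$success[nrow(casts_df)],
        turn_peak = turn_peak,
        stringsAsFactors = FALSE
      )
    }
  }
  st <- run_frames(st, odd_frames(run_out_s, fps))

  pos <- do.call(rbind, blocks)
  n <- nrow(pos)
  cm <- (pos[, 1] + pos[, 2] + pos[, 3]) / 3
  coords <- cbind(Re(pos[, 1]), Im(pos[, 1]), Re(pos[, 2]), Im(pos[, 2]),
                  Re(pos[, 3]), Im(pos[, 3]), Re(cm), Im(cm))
  if (noise_sd > 0) {
    coords <- coords + matrix(stats::rnorm(n * 8, 0, noise_sd), n, 8)
  }
  frames <- data.frame(frame = 0:(n - 1L))
  frames[c("head_x", "head_y", "mid_x", "mid_y", "tail_x", "tail_y",
           "cm_x", "cm_y")] <- as.data.frame(coords)
  traj <- trajectory(frames, frame_rate = fps, px_per_mm = px_per_mm)

  bind_or_empty <- function(l, proto) {
    if (length(l) > 0) do.call(rbind, l) else proto
  }
  turns_df <- bind_or_empty(truth_turns, data.frame(
    trial_id = character(), stop_ord = integer(), n_casts = integer(),
    kind = character(), init_distance = numeric(), success = logical(),
    turn_peak = integer(), stringsAsFactors = FALSE))
  list(
    traj = traj,
    stops = bind_or_empty(truth_stops, data.frame(
      trial_id = character(), stop_ord = integer(), start = integer(),
      end = integer(), stringsAsFactors = FALSE)),
    casts = bind_or_empty(truth_casts, data.frame(
      trial_id = character(), stop_ord = integer(), ordinal = integer(),
      start = integer(), peak = integer(), end = integer(),
      amplitude = numeric(), direction = character(), success = logical(),
      acceptance = character(), stringsAsFactors = FALSE)),
    turns = turns_df,
    escaped = if (nrow(turns_df) > 0) any(turns_df$success) else NA
  )
}
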