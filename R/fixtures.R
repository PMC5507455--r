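# Named ground-truth fixtures and recovery scoring.

# Evaluate code with a temporarily fixed RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

default_arena <- function(px_per_mm = 11.94) {
  light_spot(center = c(300, 300), radius = 10 * px_per_mm)
}

# --- scripted turn roles -------------------------------------------------
# Depth ranges and bend angles are chosen so every scripted cast clears the
# detection threshold by >= 2x, ends >= 3 px clear of the expanded spot
# edge, and keeps |headtheta| growing across casts within a stop.

r_one_success_in <- function() turn_script(
  init_distance = stats::runif(1, -18, -6),
  casts = list(cast_script("s", 18 + stats::runif(1, 0, 5), FALSE)))

r_one_success_out <- function() turn_script(
  init_distance = stats::runif(1, 1, 12),
  casts = list(cast_script("s", 18 + stats::runif(1, 0, 5), FALSE)))

r_one_fail_in <- function(depth = c(-32, -8)) turn_script(
  init_distance = stats::runif(1, depth[1], depth[2]),
  casts = list(cast_script("phi", stats::runif(1, 0.55, 0.75), TRUE)))

r_one_fail_out <- function() turn_script(
  init_distance = stats::runif(1, 0.5, 2),
  casts = list(cast_script("phi", stats::runif(1, 0.48, 0.52), TRUE)))

r_two_first_success <- function() {
  s1 <- 16 + stats::runif(1, 0, 3)
  turn_script(
    init_distance = stats::runif(1, -10, -4),
    casts = list(cast_script("s", s1, FALSE),
                 cast_script("s", s1 + 5, FALSE)))
}

r_two_fs <- function() turn_script(
  init_distance = stats::runif(1, -14, -4),
  casts = list(cast_script("phi", stats::runif(1, 0.55, 0.65), TRUE),
               cast_script("s", 18 + stats::runif(1, 0, 4), FALSE)))

r_two_ff <- function(phi2 = c(0.83, 0.87), depth = c(-28, -10)) turn_script(
  init_distance = stats::runif(1, depth[1], depth[2]),
  casts = list(cast_script("phi", stats::runif(1, 0.53, 0.57), TRUE),
               cast_script("phi", stats::runif(1, phi2[1], phi2[2]), TRUE)))

r_three_s <- function() turn_script(
  init_distance = stats::runif(1, -12, -4),
  casts = list(cast_script("phi", stats::runif(1, 0.48, 0.52), TRUE),
               cast_script("phi", stats::runif(1, 0.78, 0.82), TRUE),
               cast_script("s", 18 + stats::runif(1, 0, 4), FALSE)))

r_three_f <- function() turn_script(
  init_distance = stats::runif(1, -26, -12),
  casts = list(cast_script("phi", stats::runif(1, 0.48, 0.52), TRUE),
               cast_script("phi", stats::runif(1, 0.78, 0.82), TRUE),
               cast_script("phi", stats::runif(1, 1.08, 1.12), TRUE)))

r_four_s <- function() turn_script(
  init_distance = stats::runif(1, -14, -8),
  casts = list(cast_script("phi", stats::runif(1, 0.48, 0.52), TRUE),
               cast_script("phi", stats::runif(1, 0.73, 0.77), TRUE),
               cast_script("phi", stats::runif(1, 0.98, 1.02), TRUE),
               cast_script("s", 18 + stats::runif(1, 0, 4), FALSE)))

r_four_f <- function() turn_script(
  init_distance = stats::runif(1, -24, -14),
  casts = list(cast_script("phi", stats::runif(1, 0.48, 0.52), TRUE),
               cast_script("phi", stats::runif(1, 0.73, 0.77), TRUE),
               cast_script("phi", stats::runif(1, 0.98, 1.02), TRUE),
               cast_script("phi", stats::runif(1, 1.23, 1.27), TRUE)))

r_straight <- function() turn_script(
  init_distance = stats::runif(1, -12, -6),
  pre_bend = 0.9,
  casts = list(cast_script(straighten = TRUE),
               cast_script("s", 18 + stats::runif(1, 0, 4), FALSE)))

# failed 1-cast turn followed by a successful 2-cast turn in one trial;
# the first turn is shallow and quick so the second still starts well
# under the 5-s exposure cutoff
r_double_trial <- function() list(
  turn_script(init_distance = stats::runif(1, -5.5, -3.5),
              casts = list(cast_script("phi", stats::runif(1, 0.48, 0.52),
                                       TRUE))),
  turn_script(init_distance = NA, run_before_s = 0.3,
              casts = list(cast_script("s_rel", 3, TRUE),
                           cast_script("s", 18 + stats::runif(1, 0, 3),
                                       FALSE)))
)

fixture_compositions <- list(
  # 46 light-related turns: 28 one-cast (14 successful), 11 two-cast,
  # 7 three-or-more-cast; 9 successful n-cast turns, 2 successful first
  # casts within n-casts (16 successful first casts pooled)
  F46 = function() c(
    replicate(9, list(r_one_success_in())),
    replicate(5, list(r_one_success_out())),
    replicate(10, list(r_one_fail_in())),
    replicate(4, list(r_one_fail_out())),
    replicate(2, list(r_two_first_success())),
    replicate(4, list(r_two_fs())),
    replicate(5, list(r_two_ff())),
    replicate(2, list(r_three_s())),
    replicate(2, list(r_three_f())),
    replicate(1, list(r_four_s())),
    replicate(2, list(r_four_f()))
  ),
  # 35 trials, 46 turns (28 one-cast / 18 n-cast), 25 trials escape
  F35 = function() c(
    replicate(9, list(r_one_success_in())),
    replicate(5, list(r_one_success_out())),
    replicate(3, list(r_one_fail_in())),
    replicate(5, list(r_two_ff())),
    replicate(1, list(r_three_f())),
    replicate(1, list(r_four_f())),
    replicate(11, r_double_trial(), simplify = FALSE)
  ),
  # 30 turns whose first cast fails: 13 accepted (1-cast), 17 rejected
  FIG3B = function() c(
    replicate(9, list(r_one_fail_in())),
    replicate(4, list(r_one_fail_out())),
    replicate(9, list(r_two_fs())),
    replicate(8, list(r_two_ff()))
  ),
  # 16 turns whose first cast succeeds: 13 accepted (1-cast), 3 rejected
  FIG3C = function() c(
    replicate(9, list(r_one_success_in())),
    replicate(4, list(r_one_success_out())),
    replicate(3, list(r_two_first_success()))
  ),
  # second-cast amplitudes scripted well above first-cast amplitudes
  AMP = function() replicate(
    12, list(r_two_ff(phi2 = c(1.12, 1.18), depth = c(-26, -14)))),
  # straightening-artifact scenarios for the exclusion rule
  STRAIGHT = function() replicate(6, list(r_straight()))
)

#' Build a named ground-truth fixture
#'
#' Generates a reproducible set of scripted trials around the canonical
#' 2-cm light spot. Available fixtures:
#' \describe{
#'   \item{F46}{46 single-turn trials: 28 one-cast turns (14 successful),
#'     11 two-cast and 7 three-or-more-cast turns, 9 successful n-cast
#'     turns, 2 successful first casts within n-casts.}
#'   \item{F35}{35 trials carrying 46 turns (28 one-cast / 18 n-cast), 25
#'     trials escaping; 11 trials perform a failed 1-cast turn followed by
#'     a successful 2-cast turn.}
#'   \item{FIG3B}{30 turns whose first cast fails: 13 accepted, 17
#'     rejected.}
#'   \item{FIG3C}{16 turns whose first cast succeeds: 13 accepted, 3
#'     rejected.}
#'   \item{AMP}{12 two-cast turns with second-cast amplitudes scripted
#'     much larger than first-cast amplitudes.}
#'   \item{STRAIGHT}{6 trials opening their stop with a body-straightening
#'     pulse followed by one genuine (successful) cast.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed controlling both the scripted jitter and the
#'   positional noise stream; identical seeds give bit-identical output.
#' @param noise_sd Gaussian positional jitter, px (0 = noise-free).
#' @return list of class `larva_fixture` with elements `name`, `seed`,
#'   `noise_sd`, `arena`, `frame_rate`, `px_per_mm`, `trials` (named list
#'   of [trajectory()] objects) and `truth` (data.frames `stops`, `casts`,
#'   `turns`, `trials`).
#' @export
make_fixture <- function(name = c("F46", "F35", "FIG3B", "FIG3C", "AMP",
                                  "STRAIGHT"),
                         seed = 1, noise_sd = 0) {
  name <- match.arg(name)
  arena <- default_arena()
  with_seed(seed, {
    specs <- fixture_compositions[[name]]()
    # a trial spec is either a single turn_script or a list of them
    specs <- lapply(specs, function(sp) {
      if (inherits(sp, "turn_script")) list(sp) else sp
    })
    ids <- sprintf("t%02d", seq_along(specs))
    trials <- vector("list", length(specs))
    names(trials) <- ids
    truth <- list(stops = list(), casts = list(), turns = list())
    escaped <- logical(length(specs))
    for (i in seq_along(specs)) {
      sim <- simulate_trial(specs[[i]], arena,
                            approach_angle = stats::runif(1, 0, 2 * pi),
                            noise_sd = noise_sd, trial_id = ids[i])
      trials[[i]] <- sim$traj
      truth$stops[[i]] <- sim$stops
      truth$casts[[i]] <- sim$casts
      truth$turns[[i]] <- sim$turns
      escaped[i] <- sim$escaped
    }
    structure(list(
      name = name, seed = seed, noise_sd = noise_sd, arena = arena,
      frame_rate = 60, px_per_mm = 11.94, trials = trials,
      truth = list(stops = do.call(rbind, truth$stops),
                   casts = do.call(rbind, truth$casts),
                   turns = do.call(rbind, truth$turns),
                   trials = data.frame(trial_id = ids, escaped = escaped,
                                       stringsAsFactors = FALSE))),
      class = "larva_fixture")
  })
}

#' @export
print.larva_fixture <- function(x, ...) {
  cat(sprintf(
    "<larva_fixture> %s: %d trials, %d scripted turns, noise %g px, seed %d\n",
    x$name, length(x$trials), nrow(x$truth$turns), x$noise_sd, x$seed))
  invisible(x)
}

#' Score pipeline recovery of scripted ground truth
#'
#' Matches detected stops, casts and turns against a fixture's scripted
#' labels. A scripted stop is recovered when a detected stop overlaps at
#' least half of its span; a scripted cast when the matched stop contains
#' a detected cast of the same ordinal with peak frame within `peak_tol`,
#' matching direction, success and acceptance (and amplitude within
#' `amp_tol` relative when `check_amplitude`); a scripted turn when the
#' matched stop carries a detected light-related turn with the same cast
#' count, kind and success.
#'
#' @param fixture a [make_fixture()] result.
#' @param result a [run_pipeline()] result on `fixture$trials`.
#' @param peak_tol cast/turn peak frame tolerance, frames.
#' @param check_amplitude also require amplitude agreement.
#' @param amp_tol relative amplitude tolerance.
#' @return list with per-category counts (`*_total`, `*_ok`), `escape_ok`
#'   / `escape_total`, and `fraction` = recovered events / scripted
#'   events over stops, casts and turns.
#' @export
evaluate_recovery <- function(fixture, result, peak_tol = 1,
                              check_amplitude = FALSE, amp_tol = 0.05) {
  tr <- fixture$truth
  det_stops <- result$stops
  det_casts <- result$casts
  det_turns <- result$turns

  stops_ok <- 0L; casts_ok <- 0L; turns_ok <- 0L
  match_key <- rep(NA_integer_, nrow(tr$stops))  # row in det_stops

  for (i in seq_len(nrow(tr$stops))) {
    ts <- tr$stops[i, ]
    ds <- det_stops[det_stops$trial_id == ts$trial_id, , drop = FALSE]
    if (nrow(ds) == 0L) next
    ov <- pmin(ds$end, ts$end) - pmax(ds$start, ts$start) + 1L
    ov <- pmax(ov, 0L) / (ts$end - ts$start + 1L)
    j <- which.max(ov)
    if (ov[j] >= 0.5) {
      stops_ok <- stops_ok + 1L
      match_key[i] <- which(det_stops$trial_id == ts$trial_id)[j]
    }
  }
  stop_lookup <- function(trial_id, stop_ord) {
    i <- which(tr$stops$trial_id == trial_id & tr$stops$stop_ord == stop_ord)
    if (length(i) != 1L || is.na(match_key[i])) return(NULL)
    det_stops[match_key[i], ]
  }

  for (i in seq_len(nrow(tr$casts))) {
    tc <- tr$casts[i, ]
    ms <- stop_lookup(tc$trial_id, tc$stop_ord)
    if (is.null(ms)) next
    dc <- det_casts[det_casts$trial_id == tc$trial_id &
                    det_casts$stop_id == ms$stop_id &
                    det_casts$ordinal == tc$ordinal, , drop = FALSE]
    if (nrow(dc) != 1L) next
    ok <- abs(dc$peak - tc$peak) <= peak_tol &&
      identical(dc$direction, tc$direction) &&
      identical(dc$success, tc$success) &&
      identical(dc$acceptance, tc$acceptance)
    if (ok && check_amplitude) {
      ok <- abs(dc$amplitude - tc$amplitude) <= amp_tol * tc$amplitude
    }
    if (ok) casts_ok <- casts_ok + 1L
  }

  for (i in seq_len(nrow(tr$turns))) {
    tt <- tr$turns[i, ]
    ms <- stop_lookup(tt$trial_id, tt$stop_ord)
    if (is.null(ms)) next
    dt <- det_turns[det_turns$trial_id == tt$trial_id &
                    det_turns$stop_id == ms$stop_id, , drop = FALSE]
    if (nrow(dt) != 1L) next
    if (dt$n_casts == tt$n_casts && identical(dt$kind, tt$kind) &&
        identical(dt$success, tt$success) && isTRUE(dt$light_related)) {
      turns_ok <- turns_ok + 1L
    }
  }

  esc <- merge(tr$trials, result$trials, by = "trial_id",
               suffixes = c("_true", "_det"))
  escape_ok <- sum(esc$escaped_true == esc$escaped_det, na.rm = TRUE)

  total <- nrow(tr$stops) + nrow(tr$casts) + nrow(tr$turns)
  list(stops_total = nrow(tr$stops), stops_ok = stops_ok,
       casts_total = nrow(tr$casts), casts_ok = casts_ok,
       turns_total = nrow(tr$turns), turns_ok = turns_ok,
       escape_total = nrow(esc), escape_ok = escape_ok,
       fraction = (stops_ok + casts_ok + turns_ok) / total)
}
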