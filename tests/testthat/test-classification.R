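cfg <- cast_config()
arena_c <- light_spot(center = c(300, 300), radius = 119.4)

test_that("turn assembly follows the stop-cast-bodyomega anatomy", {
  # 1-cast then body turn: one ONE_CAST turn
  sim <- scripted_trial(list(cast_script("s", 18, FALSE)))
  res <- classify_trial(sim$traj, arena_c, cfg, "a")
  expect_equal(nrow(res$turns), 1)
  expect_equal(res$turns$kind, "1-cast")
  expect_lte(abs(res$turns$turn_peak - sim$turns$turn_peak), 1)
  expect_gte(res$turns$turn_peak, max(res$casts$peak))

  # 4 casts then body turn: one N_CAST turn with n_casts = 4
  sim <- scripted_trial(list(cast_script("phi", 0.5, TRUE),
                             cast_script("phi", 0.75, TRUE),
                             cast_script("phi", 1.0, TRUE),
                             cast_script("s", 18, FALSE)),
                        init_distance = -10)
  res <- classify_trial(sim$traj, arena_c, cfg, "b")
  expect_equal(res$turns$n_casts, 4)
  expect_equal(res$turns$kind, "n-cast")
  expect_equal(res$casts$acceptance,
               c("rejected", "rejected", "rejected", "accepted"))

  # casts without body reorientation yield no turn
  sim <- scripted_trial(list(cast_script("phi", 0.6, TRUE)),
                        do_body_turn = FALSE)
  res <- classify_trial(sim$traj, arena_c, cfg, "c")
  expect_equal(nrow(res$casts), 1)
  expect_equal(nrow(res$turns), 0)
})

test_that("light-relatedness applies the 20/50 px windows and 5 s cutoff", {
  expect_false(is_light_related(30, 0, cfg))    # outside the 20 px window
  expect_true(is_light_related(15, 0, cfg))
  expect_true(is_light_related(-40, 1, cfg))    # inside, within 50 px
  expect_false(is_light_related(-55, 1, cfg))
  expect_false(is_light_related(-10, 6, cfg))   # after the exposure cutoff
  expect_true(is_light_related(0, 0, cfg))
  # monotone in the windows: enlarging them never removes a related turn
  set.seed(9)
  d <- stats::runif(200, -80, 40)
  ex <- stats::runif(200, 0, 8)
  narrow <- is_light_related(d, ex, cfg)
  wide <- is_light_related(d, ex, cast_config(relate_out_px = 35,
                                              relate_in_px = 70))
  expect_true(all(wide[narrow]))
})

test_that("cast and turn success use the 10-px expanded edge", {
  R <- 119.4
  ctr <- c(300, 300)
  at <- function(s) ctr + c(R + s, 0)
  expect_true(score_cast_success(at(20), arena_c, cfg))
  expect_false(score_cast_success(at(0), arena_c, cfg))   # nominal edge
  expect_true(score_cast_success(at(11), arena_c, cfg))
  expect_false(score_cast_success(at(9), arena_c, cfg))
  expect_false(score_turn_success(ctr, arena_c, cfg))     # spot centre
  expect_true(score_turn_success(at(10.001), arena_c, cfg))
  expect_false(score_turn_success(at(9.999), arena_c, cfg))
})

test_that("a trial escapes iff any light-related turn succeeded", {
  t1 <- data.frame(light_related = c(TRUE, TRUE), success = c(FALSE, TRUE))
  expect_true(score_trial_escape(t1))   # failed 1-cast then successful n-cast
  t2 <- data.frame(light_related = c(TRUE, TRUE), success = c(FALSE, FALSE))
  expect_false(score_trial_escape(t2))
  t3 <- data.frame(light_related = FALSE, success = TRUE)
  expect_true(is.na(score_trial_escape(t3)))
  expect_true(is.na(score_trial_escape(t1[0, ])))
})

test_that("heading angle is the acute angle to the local spot tangent", {
  R <- 119.4
  mk <- function(head, mid) {
    trajectory(data.frame(frame = 0:1, head_x = head[1], head_y = head[2],
                          mid_x = mid[1], mid_y = mid[2], tail_x = mid[1] - 5,
                          tail_y = mid[2], cm_x = mid[1], cm_y = mid[2]))
  }
  ctr <- c(300, 300)
  # heading radially at the edge
  tr <- mk(ctr + c(R, 0), ctr + c(R + 10, 0))
  expect_equal(compute_heading_angle(tr, arena_c, 1), 90)
  # heading along the tangent (head on the boundary, heading vertical)
  tr <- mk(ctr + c(R, 0), ctr + c(R, -10))
  expect_equal(compute_heading_angle(tr, arena_c, 1), 0, tolerance = 1e-6)
  # 45 degrees to the radius: dot-product oracle
  h <- ctr + c(R, 0)
  dirv <- c(cos(pi / 4), sin(pi / 4))
  tr <- mk(h, h - 10 * dirv)
  radial <- (h - ctr) / sqrt(sum((h - ctr)^2))
  oracle <- asin(abs(sum(dirv * radial))) * 180 / pi
  expect_equal(compute_heading_angle(tr, arena_c, 1), oracle,
               tolerance = 1e-9)
  expect_equal(oracle, 45)
  # undefined at the spot centre
  tr <- mk(ctr, ctr + c(10, 0))
  expect_true(is.na(compute_heading_angle(tr, arena_c, 1)))
})

test_that("kind is a pure function of cast count across all fixtures", {
  for (nm in c("F46", "F35")) {
    run <- cached_fixture(nm)
    tt <- run$res$turns
    expect_true(all((tt$n_casts == 1) == (tt$kind == "1-cast")))
    expect_true(all((tt$n_casts >= 2) == (tt$kind == "n-cast")))
    # success of a turn whose final cast succeeded and whose head stays out
    key <- paste(run$res$casts$trial_id, run$res$casts$turn_id)
    last <- run$res$casts[run$res$casts$acceptance == "accepted" &
                          !is.na(run$res$casts$turn_id), ]
    m <- match(paste(tt$trial_id, tt$turn_id),
               paste(last$trial_id, last$turn_id))
    expect_equal(tt$success, last$success[m])
  }
})

test_that("the noise-free F46 fixture is recovered event-for-event", {
  run <- cached_fixture("F46")
  ev <- evaluate_recovery(run$fx, run$res, peak_tol = 1,
                          check_amplitude = TRUE)
  expect_equal(ev$turns_ok, 46)
  expect_equal(ev$casts_ok, ev$casts_total)
  expect_equal(ev$stops_ok, 46)
  expect_equal(ev$fraction, 1.0)
})
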