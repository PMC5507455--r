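cfg <- cast_config()

test_that("stop detection merges short gaps and drops short runs", {
  # all frames above threshold
  expect_equal(nrow(detect_stop_periods(rep(1, 100), cfg, 60)), 0)
  expect_equal(nrow(detect_stop_periods(numeric(0), cfg, 60)), 0)
  # a single 60-frame sub-threshold run at 60 fps is a 1.0 s stop
  ts <- c(rep(1, 20), rep(0.05, 60), rep(1, 20))
  st <- detect_stop_periods(ts, cfg, 60)
  expect_equal(nrow(st), 1)
  expect_equal(st$duration, 1.0)
  expect_equal(c(st$start, st$end), c(21, 80))
  # two sub-threshold runs split by a 3-frame excursion merge into one
  ts <- c(rep(1, 20), rep(0.05, 30), rep(1, 3), rep(0.05, 30), rep(1, 20))
  st <- detect_stop_periods(ts, cfg, 60)
  expect_equal(nrow(st), 1)
  expect_equal(c(st$start, st$end), c(21, 83))
  # a run shorter than min_stop_duration is discarded
  ts <- c(rep(1, 30), rep(0.05, 10), rep(1, 30))
  expect_equal(nrow(detect_stop_periods(ts, cfg, 60)), 0)
})

test_that("stop detection matches a run-painting oracle on random series", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(3:200, 1)
    ts <- stats::runif(n, 0, 0.5)
    st <- detect_stop_periods(ts, cfg, 60)
    or <- oracle_stops(ts, cfg$tailspeed_stop_thresh, cfg$min_stop_duration,
                       cfg$max_stop_gap, 60)
    expect_equal(st$start, or$start)
    expect_equal(st$end, or$end)
  }
})

test_that("stop detection ignores noise well away from threshold", {
  set.seed(42)
  base <- c(rep(1, 40), rep(0.05, 60), rep(1, 40))  # > 2x from threshold
  ref <- detect_stop_periods(base, cfg, 60)
  for (i in 1:20) {
    noisy <- base + stats::runif(length(base), -0.02, 0.02)
    st <- detect_stop_periods(noisy, cfg, 60)
    expect_equal(st$start, ref$start)
    expect_equal(st$end, ref$end)
  }
})

test_that("peakdet commits extrema by the delta rule", {
  # strictly monotone series commit nothing
  pd <- peakdet(1:50, 0.5)
  expect_equal(nrow(pd$maxima), 0)
  expect_equal(nrow(pd$minima), 0)
  # hand-traced commit
  pd <- peakdet(c(0, 1, 0), 0.5)
  expect_equal(pd$maxima$pos, 2)
  expect_equal(pd$maxima$value, 1)
  expect_error(peakdet(1:10, 0), "positive")
})

test_that("peakdet equals the scanning oracle on random series", {
  set.seed(43)
  for (i in 1:300) {
    n <- sample(3:150, 1)
    v <- stats::rnorm(n)
    delta <- 10^stats::runif(1, -2, 0.5)
    a <- peakdet(v, delta)
    b <- oracle_peakdet(v, delta)
    expect_identical(a$maxima$pos, b$maxima$pos)
    expect_equal(a$maxima$value, b$maxima$value)
    expect_identical(a$minima$pos, b$minima$pos)
    expect_equal(a$minima$value, b$minima$value)
    # committed maxima and minima strictly alternate
    ev <- rbind(
      if (nrow(a$maxima) > 0) data.frame(pos = a$maxima$pos, kind = 1),
      if (nrow(a$minima) > 0) data.frame(pos = a$minima$pos, kind = -1))
    if (!is.null(ev) && nrow(ev) > 1) {
      ev <- ev[order(ev$pos), ]
      expect_true(all(diff(ev$kind) != 0))
    }
  }
})

test_that("head casts are detected inside stops with the scripted anatomy", {
  # flat headomega in a stop yields nothing
  kin <- data.frame(headomega = rep(0, 100), headtheta = rep(0, 100))
  stops <- data.frame(stop_id = 1L, start = 10L, end = 90L, duration = 1.35)
  expect_equal(nrow(detect_head_casts(kin, stops, cfg)), 0)

  # scripted single cast: one event, amplitude within 5%, end near scripted
  sim <- scripted_trial(list(cast_script("s", 18, FALSE)))
  k <- compute_kinematics(sim$traj)
  st <- detect_stop_periods(k$tailspeed, cfg, 60)
  casts <- detect_head_casts(k, st, cfg)
  expect_equal(nrow(casts), 1)
  expect_lt(abs(casts$amplitude - sim$casts$amplitude) / sim$casts$amplitude,
            0.05)
  expect_lte(abs(casts$peak - sim$casts$peak), 1)
  # the smoothed pulse reaches zero within the post-cast hold (12 still
  # frames), during which the head is stationary
  expect_lte(abs(casts$end - sim$casts$end), 12)
  expect_gt(casts$amplitude, cfg$headomega_peak_thresh)

  # scripted straightening pulse (|headtheta| 0.9 -> 0) is excluded; only
  # the genuine cast that follows remains
  sim <- scripted_trial(list(cast_script(straighten = TRUE),
                             cast_script("s", 18, FALSE)),
                        init_distance = -8, pre_bend = 0.9)
  k <- compute_kinematics(sim$traj)
  st <- detect_stop_periods(k$tailspeed, cfg, 60)
  casts <- detect_head_casts(k, st, cfg)
  expect_equal(nrow(casts), 1)
  expect_lte(abs(casts$peak - sim$casts$peak), 1)
})

test_that("casts stay inside their stop period and never overlap", {
  run <- cached_fixture("F46")
  casts <- run$res$casts
  stops <- run$res$stops
  for (tid in unique(casts$trial_id)) {
    cc <- casts[casts$trial_id == tid, ]
    ss <- stops[stops$trial_id == tid, ]
    for (i in seq_len(nrow(cc))) {
      s <- ss[ss$stop_id == cc$stop_id[i], ]
      expect_gte(cc$start[i], s$start)
      expect_lte(cc$end[i], s$end)
      expect_true(cc$start[i] <= cc$peak[i] && cc$peak[i] <= cc$end[i])
    }
    # within a stop, time-ordered and non-overlapping
    for (sid in unique(cc$stop_id)) {
      cs <- cc[cc$stop_id == sid, ]
      if (nrow(cs) > 1) {
        expect_true(all(diff(cs$peak) > 0))
        expect_true(all(cs$start[-1] >= cs$end[-nrow(cs)]))
      }
    }
  }
})

test_that("acceptance labels mark only the last cast of each stop", {
  base <- data.frame(stop_id = 1L, ordinal = 1L)
  expect_equal(label_acceptance(base)$acceptance, "accepted")
  two <- data.frame(stop_id = c(1L, 1L), ordinal = 1:2)
  expect_equal(label_acceptance(two)$acceptance, c("rejected", "accepted"))
  # the 4-cast anatomy: three rejections then one acceptance
  four <- data.frame(stop_id = rep(1L, 4), ordinal = 1:4)
  expect_equal(label_acceptance(four)$acceptance,
               c("rejected", "rejected", "rejected", "accepted"))
  empty <- label_acceptance(data.frame(stop_id = integer(),
                                       ordinal = integer()))
  expect_equal(nrow(empty), 0)
  # exactly one accepted cast per non-empty stop on the full fixture
  run <- cached_fixture("F46")
  acc <- tapply(run$res$casts$acceptance == "accepted",
                paste(run$res$casts$trial_id, run$res$casts$stop_id), sum)
  expect_true(all(acc == 1))
})
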