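test_that("headtheta matches geometric expectations and an atan2 oracle", {
  # straight body, right-angle bend, axis symmetry
  expect_equal(compute_headtheta(c(2, 0), c(1, 0), c(0, 0)), 0)
  expect_equal(compute_headtheta(c(1, 1), c(1, 0), c(0, 0)), pi / 2)
  expect_equal(compute_headtheta(c(1, -1), c(1, 0), c(0, 0)), -pi / 2)
  # oracle: two-argument arctangent of cross/dot of the direction vectors
  u <- c(1, 0); v <- c(1, 1) / sqrt(2)
  expect_equal(compute_headtheta(c(2, 1), c(1, 0), c(0, 0)),
               atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2]))
  set.seed(11)
  for (i in 1:50) {
    tail <- stats::runif(2, -5, 5)
    mid <- tail + stats::runif(2, -3, 3)
    head <- mid + stats::runif(2, -3, 3)
    u <- (mid - tail) / sqrt(sum((mid - tail)^2))
    v <- (head - mid) / sqrt(sum((head - mid)^2))
    expect_equal(compute_headtheta(head, mid, tail),
                 atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)),
                 tolerance = 1e-12)
  }
  # degenerate points flag NA, no error
  expect_true(is.na(compute_headtheta(c(1, 0), c(1, 0), c(0, 0))))
})

test_that("bodytheta is the axis angle from arena horizontal", {
  expect_equal(compute_bodytheta(c(1, 0), c(0, 0)), 0)
  expect_equal(compute_bodytheta(c(0, 1), c(0, 0)), pi / 2)
  expect_equal(compute_bodytheta(c(-1, 1), c(0, 0)), 3 * pi / 4)
  expect_true(is.na(compute_bodytheta(c(0, 0), c(0, 0))))
})

test_that("angle computations are rotation-equivariant, speeds invariant", {
  set.seed(21)
  for (i in 1:20) {
    tail <- stats::runif(2); mid <- tail + stats::runif(2, 0.5, 1)
    head <- mid + stats::runif(2, 0.5, 1)
    phi <- stats::runif(1, -pi, pi)
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    th0 <- compute_headtheta(head, mid, tail)
    th1 <- compute_headtheta(rot %*% head, rot %*% mid, rot %*% tail)
    expect_equal(th1, th0, tolerance = 1e-9)
    b0 <- compute_bodytheta(mid, tail)
    b1 <- compute_bodytheta(rot %*% mid, rot %*% tail)
    diffang <- (b1 - b0 - phi + pi) %% (2 * pi) - pi
    expect_equal(diffang, 0, tolerance = 1e-9)
  }
  # speeds: translation + rotation invariant
  pts <- matrix(stats::runif(40), ncol = 2)
  phi <- 1.1
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  moved <- t(rot %*% t(pts)) + matrix(c(5, -3), 20, 2, byrow = TRUE)
  expect_equal(compute_speed(moved, 60, 11.94),
               compute_speed(pts, 60, 11.94), tolerance = 1e-9)
})

test_that("speed matches calibration and a finite-difference oracle", {
  # stationary
  expect_equal(compute_speed(matrix(1, 10, 2), 60, 11.94), rep(0, 10))
  # 11.94 px per frame at 60 fps and 11.94 px/mm is 60 mm/s
  pts <- cbind(11.94 * (0:9), 0)
  expect_equal(compute_speed(pts, 60, 11.94), rep(60, 10))
  # random walk vs oracle
  set.seed(31)
  pts <- apply(matrix(stats::rnorm(60), ncol = 2), 2, cumsum)
  expect_equal(compute_speed(pts, 60, 11.94), oracle_speed(pts, 60, 11.94),
               tolerance = 1e-9)
  expect_error(compute_speed(matrix(1, 1, 2), 60, 11.94), "too short")
})

test_that("angular differentiation unwraps across the pi boundary", {
  expect_equal(differentiate_angle(rep(0.4, 20), 60), rep(0, 20))
  # ramp at the head-cast threshold scale: 0.35 rad/s
  theta <- (0:59) * 0.35 / 60
  om <- differentiate_angle(theta, 60)
  expect_equal(om[2:59], rep(0.35, 58), tolerance = 1e-12)
  # crossing +/- pi: wrapped input, continuous output
  raw <- seq(2.9, 3.9, length.out = 50)          # passes pi
  wrapped <- (raw + pi) %% (2 * pi) - pi
  om <- differentiate_angle(wrapped, 60)
  expect_equal(om, oracle_omega(wrapped, 60), tolerance = 1e-9)
  expect_true(all(om > 0))                        # no spurious 2 pi jumps
})

test_that("moving average is a centred mean with shrinking edges", {
  x <- stats::rnorm(30)
  expect_identical(moving_average(x, 1), x)
  expect_equal(moving_average(rep(3.5, 10), 5), rep(3.5, 10))
  expect_equal(moving_average(c(0, 0, 1, 0, 0), 3),
               c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  # mean preserved up to edges
  expect_equal(mean(moving_average(x, 5)[3:28]),
               mean(sapply(3:28, function(i) mean(x[(i - 2):(i + 2)]))))
  expect_error(moving_average(x, 4), "odd")
  expect_error(moving_average(x, 31), "exceeds")
})

test_that("full kinematics recovers scripted signals on clean fixtures", {
  # straight run: no bend, tailspeed near the scripted crawl speed
  arena <- light_spot(center = c(300, 300), radius = 119.4)
  sim <- with_test_seed(3,
    simulate_trial(list(), arena, approach_angle = 0, trial_id = "run",
                   run_out_s = 4))
  kin <- compute_kinematics(sim$traj)
  mid <- 30:(nrow(kin) - 30)
  expect_lt(max(abs(kin$headtheta[mid])), 1e-9)
  expect_lt(abs(mean(kin$tailspeed[mid]) - 1.0), 0.05)
  expect_lt(max(abs(kin$headomega[mid])), 1e-6)

  # single scripted cast (no body turn): exactly one supra-threshold
  # headomega interval, peak within 5% of the scripted amplitude
  sim <- scripted_trial(list(cast_script("s", 18, FALSE)),
                        do_body_turn = FALSE)
  kin <- compute_kinematics(sim$traj)
  above <- abs(kin$headomega) > 0.35
  runs <- rle(above)
  expect_equal(sum(runs$values), 1)
  expect_lt(abs(max(abs(kin$headomega)) - sim$casts$amplitude) /
              sim$casts$amplitude, 0.05)
  expect_equal(which.max(abs(kin$headomega)), sim$casts$peak)

  # all-stationary input: zero speeds and omegas
  frames <- data.frame(frame = 0:19, head_x = 10, head_y = 0, mid_x = 5,
                       mid_y = 0, tail_x = 0, tail_y = 0, cm_x = 5,
                       cm_y = 0)
  kin <- compute_kinematics(trajectory(frames))
  expect_equal(kin$tailspeed, rep(0, 20))
  expect_equal(kin$headomega, rep(0, 20))
  expect_equal(kin$bodyomega, rep(0, 20))
})

test_that("degenerate frames are interpolated up to the gap tolerance", {
  frames <- data.frame(frame = 0:19, head_x = 10 + (0:19), head_y = 0,
                       mid_x = 5 + (0:19), mid_y = 0, tail_x = 0 + (0:19),
                       tail_y = 0, cm_x = 5 + (0:19), cm_y = 0)
  # two coincident-point frames inside the gap tolerance
  frames$head_x[8:9] <- frames$mid_x[8:9]
  frames$head_y[8:9] <- frames$mid_y[8:9]
  kin <- compute_kinematics(trajectory(frames))
  expect_true(all(is.finite(kin$headtheta)))
  # a 5-frame degenerate run exceeds the tolerance
  frames$head_x[5:9] <- frames$mid_x[5:9]
  frames$head_y[5:9] <- frames$mid_y[5:9]
  expect_error(compute_kinematics(trajectory(frames)), "gap")
})
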