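test_that("fisher_exact matches symmetry, composition and the oracle", {
  expect_equal(fisher_exact(5, 5, 5, 5), 1.0)
  # the 1-cast vs n-cast success composition: identical proportions
  expect_equal(fisher_exact(14, 14, 9, 9), 1.0)
  expect_equal(fisher_exact(14, 14, 9, 9),
               oracle_fisher(14, 14, 9, 9), tolerance = 1e-12)
  # random small tables vs the enumeration oracle
  set.seed(51)
  for (i in 1:200) {
    t4 <- as.integer(stats::runif(4, 0, 12))
    if (min(t4[1] + t4[2], t4[3] + t4[4], t4[1] + t4[3],
            t4[2] + t4[4]) == 0) next
    expect_equal(fisher_exact(t4[1], t4[2], t4[3], t4[4]),
                 do.call(oracle_fisher, as.list(t4)), tolerance = 1e-10)
  }
})

test_that("fisher_exact is invariant to transposition and row/col swaps", {
  set.seed(52)
  for (i in 1:50) {
    t4 <- as.integer(stats::runif(4, 1, 15))
    p <- fisher_exact(t4[1], t4[2], t4[3], t4[4])
    expect_equal(fisher_exact(t4[1], t4[3], t4[2], t4[4]), p,
                 tolerance = 1e-12)                       # transpose
    expect_equal(fisher_exact(t4[4], t4[3], t4[2], t4[1]), p,
                 tolerance = 1e-12)                       # both swaps
  }
  # a zero row admits one table only
  expect_warning(p0 <- fisher_exact(0, 0, 3, 4), "zero margin")
  expect_equal(p0, 1)
})

test_that("fisher_exact agrees with the standard exact test", {
  for (t4 in list(c(3, 7, 8, 2), c(1, 9, 5, 5), c(12, 2, 3, 9),
                  c(2, 2, 10, 1))) {
    m <- matrix(t4, 2, byrow = TRUE)
    expect_equal(fisher_exact(m), stats::fisher.test(m)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("students_t is the pooled-variance statistic", {
  r <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # closed form: x = {1,2,3}, y = {4,5,6} gives t = -3.674...
  r <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  # cross-check against the standard implementation
  set.seed(53)
  for (i in 1:25) {
    x <- stats::rnorm(sample(2:20, 1))
    y <- stats::rnorm(sample(2:20, 1), mean = stats::runif(1, -1, 1))
    r <- students_t(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
  # degenerate zero-variance samples are signalled, not errors
  expect_equal(students_t(c(1, 1), c(1, 1))$p, 1)
  expect_equal(students_t(c(1, 1), c(2, 2))$p, 0)
  expect_error(students_t(1, c(1, 2)), "at least 2")
})

test_that("the F46 report reproduces the scripted composition exactly", {
  s <- cached_fixture("F46")$res$summary
  expect_equal(s$composition$one_cast$num, 28)
  expect_equal(s$composition$one_cast$percent, 100 * 28 / 46)
  expect_equal(s$composition$two_cast$percent, 100 * 11 / 46)
  expect_equal(s$composition$three_plus_cast$percent, 100 * 7 / 46)
  expect_equal(s$success$one_cast$percent, 50)
  expect_equal(s$success$n_cast$percent, 50)
  expect_equal(s$first_cast_success$n_cast$percent, 100 * 2 / 18)
  expect_equal(s$first_cast_success$pooled$percent, 100 * 16 / 46)
  # 1-cast vs n-cast success is an even comparison here
  expect_equal(s$tests$success_one_vs_n, 1.0)
})

test_that("report percentages are consistent count ratios in [0, 100]", {
  walk_rates <- function(x) {
    if (is.list(x) && all(c("num", "den", "percent") %in% names(x))) {
      expect_gte(x$num, 0)
      expect_lte(x$num, x$den)
      if (x$den > 0) {
        expect_equal(x$percent, 100 * x$num / x$den, tolerance = 1e-9)
        expect_gte(x$percent, 0)
        expect_lte(x$percent, 100)
      } else {
        expect_true(is.na(x$percent))
      }
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, walk_rates)
    }
    invisible(NULL)
  }
  for (nm in c("F46", "F35", "FIG3B", "FIG3C")) {
    walk_rates(unclass(cached_fixture(nm)$res$summary))
  }
})

test_that("a fixture with no n-cast turns reports n-cast fields undefined", {
  s <- cached_fixture("FIG3C")$res$summary
  # FIG3C has 3 n-cast turns; build a 1-cast-only subset via STRAIGHT
  s1 <- cached_fixture("STRAIGHT")$res$summary
  expect_equal(s1$composition$one_cast$num, 6)
  expect_true(is.na(s1$success$n_cast$percent))
  expect_true(is.na(s1$first_cast_success$n_cast$percent))
  expect_false(is.na(s1$success$one_cast$percent))
  # and the populated FIG3C panels match their scripted compositions
  expect_equal(s$successful_first$accepted$percent, 81.25)
  expect_equal(s$successful_first$accepted$num, 13)
  expect_equal(s$successful_first$accepted$den, 16)
})

test_that("scripted larger second casts test significant, second > first", {
  s <- cached_fixture("AMP")$res$summary
  tt <- s$tests$amplitude_first_vs_second
  expect_lt(tt$p, 0.05)
  expect_lt(tt$mean_x, tt$mean_y)  # first-cast mean below second-cast mean
})
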