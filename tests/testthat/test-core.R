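p0 <- aaei_params()

test_that("MET-minutes are level times duration, summed over sessions", {
  expect_equal(met_minutes(5, 30), 150)
  expect_equal(met_minutes(numeric(0), numeric(0)), 0)
  expect_equal(met_minutes(c(10, 5), c(20, 10)), 250)
  expect_error(met_minutes(-5, 30), "activity_level")
  expect_error(met_minutes(5, 0), "duration")
  expect_error(met_minutes(c(5, 5), 30), "same length")
})

test_that("history coefficient: null start, single rest day, geometric limit", {
  expect_true(is.na(alpha_coefficient(numeric(0), p0)))
  expect_equal(alpha_coefficient(-1, p0), -1)
  # all-rest history approaches -1/(1-w) = -2
  expect_equal(alpha_coefficient(rep(-1, 200), p0), -2, tolerance = 1e-9)
  # weights below tail_epsilon are dropped but the truncation is tiny
  full <- sum(0.5^(0:199) * rep(0.7, 200))
  expect_equal(alpha_coefficient(rep(0.7, 200), p0), full, tolerance = 1e-8)
})

test_that("exercise expectance maps the coefficient range onto [0, A*C^2]", {
  expect_equal(exercise_expectance(0, -1.3, p0), 0)
  expect_equal(exercise_expectance(100, NA, p0), 0)
  # all-rest maximum
  expect_equal(exercise_expectance(100, -2, p0), 400)
  expect_error(exercise_expectance(-1, 0, p0), ">= 0")
})

test_that("steady everyday exercise forces E = MT = A (fixed point)", {
  # iterate the recursion on constant input until stationary, independently
  # of the expectance formula under test
  s <- compute_aaei(const_log(120, 100), p0)
  expect_equal(tail(s$aaei, 1), 700, tolerance = 1e-9)
  expect_equal(tail(s$e, 1), 100, tolerance = 1e-9)
  expect_equal(tail(s$a, 1), 100, tolerance = 1e-9)
  expect_equal(exercise_expectance(100, 0, p0), 100)
})

test_that("the first recorded activity passes through unchanged", {
  s <- aaei_update(aaei_state(), 100, p0)
  expect_equal(s$aaei, 100)
  expect_equal(s$e, 0)
  expect_error(aaei_update(s, -5, p0), ">= 0")
})

test_that("rest-day decay from the everyday steady state follows the
           hand-unrolled recursion", {
  # unroll by hand: on rest days x = -1, so alpha follows
  # 0, -1, -1.5, -1.75, ... and E = (prev/7) * 2^(-alpha)
  alpha_seq <- c(0, -1, -1.5, -1.75, -1.875, -1.9375, -1.96875)
  val <- 700
  expected <- numeric(7)
  for (i in 1:7) {
    val <- val - (val / 7) * 2^(-alpha_seq[i])
    expected[i] <- val
  }
  expect_equal(round(expected, 1),
               c(600, 428.6, 255.4, 132.7, 63.2, 28.6, 12.6))

  s <- compute_aaei(rbind(const_log(120, 100),
                          const_log(7, 0, as.Date("2024-01-01") + 120)), p0)
  expect_equal(tail(s$aaei, 7), expected, tolerance = 1e-9)
  expect_equal(tail(s$alpha, 7), alpha_seq, tolerance = 1e-9)
  # principle: near zero after a week of rest
  expect_lt(tail(s$aaei, 1), 0.02 * 700)
})

test_that("series covers every calendar day, filling gaps as rest", {
  log <- data.frame(date = as.Date(c("2024-03-01", "2024-03-05")),
                    met_minutes = c(100, 50))
  s <- compute_aaei(log, p0)
  expect_equal(nrow(s), 5L)
  expect_equal(s$mt, c(100, 0, 0, 0, 50))
  expect_equal(diff(as.integer(s$date)), rep(1L, 4))
  # first day has a null coefficient
  expect_true(is.na(s$alpha[1]))
  expect_false(anyNA(s$alpha[-1]))
})

test_that("single-record and all-rest logs behave trivially", {
  s1 <- compute_aaei(data.frame(date = "2024-01-01", met_minutes = 100), p0)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$aaei, 100)

  s0 <- compute_aaei(const_log(30, 0), p0)
  expect_equal(s0$aaei, rep(0, 30))
  expect_true(all(is.na(s0$alpha)))
})

test_that("log validation rejects duplicates, bad dates and negatives", {
  expect_error(compute_aaei(data.frame(date = c("2024-01-01", "2024-01-01"),
                                       met_minutes = c(100, 50)), p0),
               "duplicate date")
  expect_error(compute_aaei(data.frame(date = c("2024-01-01", "not-a-date"),
                                       met_minutes = c(1, 2)), p0),
               "row 2")
  expect_error(compute_aaei(data.frame(date = "2024-01-01",
                                       met_minutes = -1), p0),
               "met_minutes")
  expect_error(compute_aaei(data.frame(date = character(0),
                                       met_minutes = numeric(0)), p0),
               "empty")
})

test_that("periodic everyday input rises in week 1, then is stationary", {
  daily <- 14.3  # 100 MET-minutes spread evenly over 7 days
  s <- compute_aaei(const_log(28, daily), p0)
  wa <- weekly_average(s)
  expect_equal(nrow(wa), 4L)
  expect_gt(wa$value[2], wa$value[1])
  expect_equal(wa$value[3], wa$value[4], tolerance = 5e-3)
  expect_equal(tail(s$aaei, 1), 7 * daily, tolerance = 5e-3)
})
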