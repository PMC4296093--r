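p0 <- aaei_params()

test_that("the index is non-negative and the clamp never fires on random logs", {
  set.seed(101)
  for (i in 1:25) {
    log <- random_log(sample(10:90, 1), p_exercise = stats::runif(1, 0.1, 1))
    expect_silent(s <- compute_aaei(log, p0))   # clamp would warn
    expect_true(all(s$aaei >= 0))
    expect_equal(attr(s, "clamped"), 0L)
    # decrement bound behind the clamp: k * E <= AAEI(prev)
    prev <- c(0, head(s$aaei, -1))
    expect_true(all(p0$k * s$e <= prev + 1e-9))
  }
})

test_that("more activity on a day never lowers that day's index; rest never
           raises it", {
  set.seed(202)
  for (i in 1:10) {
    log <- random_log(40)
    s <- compute_aaei(log, p0)
    j <- sample(40, 1)
    bumped <- log
    bumped$met_minutes[j] <- bumped$met_minutes[j] + 50
    sb <- compute_aaei(bumped, p0)
    expect_gt(sb$aaei[j], s$aaei[j])
    # a rest day can only keep or lower the index
    rest <- which(s$mt == 0)
    prev <- c(0, head(s$aaei, -1))
    expect_true(all(s$aaei[rest] <= prev[rest] + 1e-12))
  }
})

test_that("consecutive rest days decay by a strictly increasing fraction", {
  s <- compute_aaei(rbind(const_log(60, 150),
                          const_log(7, 0, as.Date("2024-01-01") + 60)), p0)
  tail_vals <- tail(s$aaei, 8)            # steady value then 7 rest days
  frac <- -diff(tail_vals) / head(tail_vals, -1)
  expect_true(all(diff(frac) > 0))
  expect_lt(tail(tail_vals, 1), 0.02 * tail_vals[1])
})

test_that("a richer exercise history softens the rest-day penalty", {
  # two states with identical index but different history coefficients
  mk <- function(alpha) {
    st <- aaei_state()
    st$aaei <- 700; st$alpha <- alpha; st$started <- TRUE
    st
  }
  for (pair in list(c(0, 1), c(-1, 0), c(-1.5, 2))) {
    lo <- aaei_update(mk(pair[1]), 0, p0)
    hi <- aaei_update(mk(pair[2]), 0, p0)
    expect_gt(hi$aaei, lo$aaei)
  }
})

test_that("constant everyday input m converges to the 7m fixed point", {
  for (m in c(14.3, 100, 750)) {
    s <- compute_aaei(const_log(150, m), p0)
    expect_equal(tail(s$aaei, 1), 7 * m, tolerance = 1e-9)
    # ratio of steady index to weekly MET-minutes is exactly 1
    expect_equal(mean(tail(s$aaei, 7)) / (7 * m), 1, tolerance = 1e-9)
  }
})

test_that("the recursion is exactly scale-equivariant in MET-minutes", {
  set.seed(303)
  log <- random_log(50)
  s1 <- compute_aaei(log, p0)
  # powers of two rescale without any floating-point rounding at all
  for (lambda in c(0.25, 1024)) {
    scaled <- log
    scaled$met_minutes <- scaled$met_minutes * lambda
    s2 <- compute_aaei(scaled, p0)
    expect_identical(s2$aaei, s1$aaei * lambda)
    expect_identical(s2$alpha, s1$alpha)  # the coefficient is scale-free
  }
  for (lambda in c(3, 0.017)) {
    scaled <- log
    scaled$met_minutes <- scaled$met_minutes * lambda
    s2 <- compute_aaei(scaled, p0)
    expect_equal(s2$aaei, s1$aaei * lambda, tolerance = 1e-12)
  }
})

test_that("incremental recursion matches from-scratch recomputation", {
  set.seed(404)
  for (i in 1:12) {
    n <- sample(10:60, 1)
    log <- random_log(n, p_exercise = stats::runif(1, 0.2, 0.9))
    s <- compute_aaei(log, p0)
    o <- oracle_series(log$met_minutes)
    expect_equal(s$aaei, o$aaei, tolerance = 1e-9)
    expect_equal(s$e, o$e, tolerance = 1e-9)
    expect_equal(s$alpha, o$alpha, tolerance = 1e-9)
  }
})

test_that("state-by-state updates agree with the whole-series computation", {
  set.seed(505)
  log <- random_log(30)
  s <- compute_aaei(log, p0)
  st <- aaei_state()
  for (i in seq_len(nrow(s))) {
    st <- aaei_update(st, log$met_minutes[i], p0)
    expect_equal(st$aaei, s$aaei[i], tolerance = 1e-12)
  }
})

test_that("tail truncation of the history sum is numerically immaterial", {
  set.seed(606)
  log <- random_log(400)
  s <- compute_aaei(log, p0)                                 # exact carry
  o <- oracle_series(log$met_minutes, tail_eps = 1e-9)        # truncated sum
  rel <- abs(s$aaei - o$aaei) / pmax(abs(o$aaei), 1)
  expect_lt(max(rel), 1e-6)
})

test_that("the coefficient and expectance respect their analytic bounds", {
  set.seed(707)
  for (i in 1:10) {
    log <- random_log(60, p_exercise = stats::runif(1, 0.05, 1))
    s <- compute_aaei(log, p0)
    ok <- !is.na(s$alpha)
    expect_true(all(s$alpha[ok] >= -1 / (1 - p0$w) - 1e-12))
    expect_true(all(s$e >= 0))
    expect_true(all(s$e <= s$a * p0$c^(1 / (1 - p0$w)) + 1e-9))
  }
})
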