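#' Ideal periodic weekly activity pattern
#'
#' Distributes a fixed weekly MET-minute total evenly over `days_per_week`
#' exercise days of a 7-day week. The canonical placements for 1, 3, 5 and 7
#' days put the positive days at day 7; days 2, 4, 7; days 2, 3, 5, 6, 7; and
#' every day, respectively. The remaining counts (2, 4, 6) are spread
#' maximally evenly with the last exercise day on day 7, in the same style:
#' days 4, 7; days 2, 4, 6, 7; days 2-7.
#'
#' @param days_per_week Integer 1-7.
#' @param weekly_total Weekly physical activity in MET-minutes, `> 0`.
#' @return An object of class `ideal_pattern`: list with `days_per_week`,
#'   `weekly_total` and `daily_mt` (length-7 vector, day 7 last).
#' @examples
#' ideal_pattern(1, 100)$daily_mt  # 0 0 0 0 0 0 100
#' ideal_pattern(3, 100)$daily_mt  # 100/3 on days 2, 4, 7
#' @export
ideal_pattern <- function(days_per_week, weekly_total = 100) {
  if (!is.numeric(days_per_week) || length(days_per_week) != 1L ||
      is.na(days_per_week) || days_per_week != round(days_per_week) ||
      days_per_week < 1 || days_per_week > 7)
    stop("'days_per_week' must be an integer between 1 and 7", call. = FALSE)
  if (!is.numeric(weekly_total) || length(weekly_total) != 1L ||
      !is.finite(weekly_total) || weekly_total <= 0)
    stop("'weekly_total' must be > 0 MET-minutes", call. = FALSE)
  days_per_week <- as.integer(days_per_week)
  placement <- list(7L, c(4L, 7L), c(2L, 4L, 7L), c(2L, 4L, 6L, 7L),
                    c(2L, 3L, 5L, 6L, 7L), 2:7, 1:7)[[days_per_week]]
  daily <- numeric(7)
  daily[placement] <- weekly_total / days_per_week
  structure(list(days_per_week = days_per_week, weekly_total = weekly_total,
                 daily_mt = daily),
            class = "ideal_pattern")
}

#' Steady-state AAEI-to-activity ratio of a periodic pattern
#'
#' Repeats a weekly pattern until the week-over-week mean index is stationary
#' (relative change below `tol`, at least 4 weeks) and returns the ratio of
#' the mean daily AAEI over one stationary week to the weekly MET-minute
#' total. Everyday exercise gives exactly 1 (the `7m` fixed point); fewer
#' exercise days give smaller ratios because rest days are penalised.
#'
#' @param pattern An [ideal_pattern()].
#' @param params An [aaei_params()] object.
#' @param tol Relative convergence tolerance on the weekly mean.
#' @param max_weeks Iteration cap; exceeding it is an error.
#' @return A single dimensionless ratio in `(0, 1]` for the default
#'   parameters.
#' @examples
#' steady_state_ratio(ideal_pattern(7, 100))  # 1
#' @export
steady_state_ratio <- function(pattern, params = aaei_params(),
                               tol = 1e-9, max_weeks = 200L) {
  if (!inherits(pattern, "ideal_pattern"))
    stop("'pattern' must come from ideal_pattern()", call. = FALSE)
  params <- as_aaei_params(params)
  st <- list(aaei = 0, alpha = NA_real_, started = FALSE)
  prev_mean <- -Inf
  for (week in seq_len(max_weeks)) {
    wk_vals <- numeric(7)
    for (d in 1:7) {
      step <- aaei_step(st, pattern$daily_mt[d], params)
      wk_vals[d] <- step$aaei
      st <- list(aaei = step$aaei, alpha = step$alpha_next,
                 started = step$started)
    }
    m <- mean(wk_vals)
    if (week >= 4L &&
        abs(m - prev_mean) <= tol * max(abs(m), .Machine$double.eps))
      return(m / pattern$weekly_total)
    prev_mean <- m
  }
  stop("steady state not reached within ", max_weeks, " weeks", call. = FALSE)
}

#' Ideal AAEI/PA ratio curve over exercise days per week
#'
#' Evaluates [steady_state_ratio()] for every `days_per_week` from 1 to 7
#' under one parameter set. The curve is monotone increasing and reaches 1 at
#' 7 days: the same weekly amount of activity scores higher when spread over
#' more days.
#'
#' @param params An [aaei_params()] object.
#' @param weekly_total Weekly MET-minutes used for the patterns; the ratios
#'   do not depend on it (the recursion is scale-equivariant).
#' @return An object of class `ideal_curve`: data frame with columns
#'   `days_per_week` (1-7) and `ratio`.
#' @examples
#' curve <- ideal_curve()
#' curve$ratio[7]  # 1
#' @export
ideal_curve <- function(params = aaei_params(), weekly_total = 100) {
  params <- as_aaei_params(params)
  ratios <- vapply(1:7, function(d)
    steady_state_ratio(ideal_pattern(d, weekly_total), params), numeric(1))
  structure(data.frame(days_per_week = 1:7, ratio = ratios),
            class = c("ideal_curve", "data.frame"))
}

#' Interpolate the ideal ratio at a fractional number of exercise days
#'
#' Realised adherence is rarely integer (a simulated year may average, say,
#' 4.8 exercise days/week); the ideal reference ratio at such values is
#' obtained by linear interpolation between the adjacent integer days.
#'
#' @param curve An [ideal_curve()].
#' @param days Number in `[1, 7]`.
#' @return The interpolated dimensionless ratio.
#' @examples
#' interpolate_ratio(ideal_curve(), 4.8)
#' @export
interpolate_ratio <- function(curve, days) {
  if (!inherits(curve, "ideal_curve"))
    stop("'curve' must come from ideal_curve()", call. = FALSE)
  if (!is.numeric(days) || length(days) != 1L || is.na(days) ||
      days < 1 || days > 7)
    stop("'days' must lie in [1, 7]", call. = FALSE)
  stats::approx(curve$days_per_week, curve$ratio, xout = days)$y
}
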