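#' Total MET-minutes of a set of exercise sessions
#'
#' A day's amount of physical activity, `MT`, is the activity level (MET)
#' multiplied by the exercise duration (minutes), summed over the day's
#' sessions.
#'
#' @param activity_level Numeric vector of session intensities in MET, all
#'   `> 0`.
#' @param duration Numeric vector of session durations in minutes, all `> 0`,
#'   same length as `activity_level`.
#' @return A single non-negative number, MET-minutes. Zero for no sessions.
#' @examples
#' met_minutes(5, 30)                 # one 30-min session at 5 MET -> 150
#' met_minutes(c(10, 5), c(20, 10))   # 250
#' met_minutes(numeric(0), numeric(0)) # a rest day -> 0
#' @export
met_minutes <- function(activity_level, duration) {
  stopifnot(is.numeric(activity_level), is.numeric(duration))
  if (length(activity_level) != length(duration))
    stop("'activity_level' and 'duration' must have the same length",
         call. = FALSE)
  if (length(activity_level) == 0L) return(0)
  if (any(!is.finite(activity_level)) || any(!is.finite(duration)))
    stop("sessions must be finite", call. = FALSE)
  if (any(activity_level <= 0))
    stop("'activity_level' must be > 0 MET for every session", call. = FALSE)
  if (any(duration <= 0))
    stop("'duration' must be > 0 minutes for every session", call. = FALSE)
  sum(activity_level * duration)
}

#' History coefficient from explicit per-day contributions
#'
#' Evaluates the attenuated sum `alpha = sum_i w^(i-1) * x[i]` over past days'
#' stored history contributions, most recent day first. Terms whose weight
#' `w^(i-1)` falls below `params$tail_epsilon` are dropped; with `|w| < 1` the
#' truncation error is below `tail_epsilon / (1 - |w|)` times the largest
#' remaining contribution.
#'
#' Each day's contribution is its MET-minutes relative to that day's basic
#' value: `x = MT/A - 1`, so a rest day contributes exactly `-1` and the
#' coefficient is bounded below by `-1/(1-w)` (`-2` for the default
#' `w = 0.5`). Days before the first recorded activity contribute nothing and
#' the coefficient is undefined (`NA`) while no activity has ever been
#' recorded.
#'
#' @param x Numeric vector of per-day history contributions, most recent day
#'   first (yesterday is `x[1]`).
#' @param params An [aaei_params()] object.
#' @param started Has any physical activity been recorded on or before the
#'   most recent history day? When `FALSE` the coefficient is `NA` (null).
#' @return A single number, or `NA_real_` when no activity precedes the day.
#' @examples
#' p <- aaei_params()
#' alpha_coefficient(numeric(0), p)        # no history -> NA (null)
#' alpha_coefficient(-1, p)                # one prior rest day -> -1
#' alpha_coefficient(rep(-1, 60), p)       # long rest -> approaches -2
#' @export
alpha_coefficient <- function(x, params = aaei_params(),
                              started = length(x) > 0L) {
  params <- as_aaei_params(params)
  stopifnot(is.numeric(x))
  if (!isTRUE(started)) return(NA_real_)
  if (length(x) == 0L) return(0)
  weights <- abs(params$w)^(seq_along(x) - 1L)
  keep <- weights >= params$tail_epsilon
  if (!any(keep)) return(0)
  n <- max(which(keep))
  idx <- seq_len(n)
  sum(params$w^(idx - 1L) * x[idx])
}

#' Exercise expectance
#'
#' The amount of physical activity "expected" on a day, given the previous
#' index level and the rest/exercise history: `E = A * c^(-alpha)`, where
#' `A` is the basic value (previous AAEI divided by 7) and `alpha` the history
#' coefficient. A low (rest-dominated) `alpha` raises the expectance, so the
#' index is penalised harder; a large `alpha` (recent heavy exercise) lowers
#' it. When the index is zero or no activity has ever been recorded
#' (`alpha` null/`NA`), the expectance is zero.
#'
#' @param a Basic value `A >= 0` in MET-minutes (previous AAEI / 7).
#' @param alpha History coefficient, or `NA` when undefined.
#' @param params An [aaei_params()] object.
#' @return Expectance in MET-minutes, within `[0, a * c^(1/(1-w))]`.
#' @examples
#' p <- aaei_params()
#' exercise_expectance(0, NA, p)    # nothing recorded yet -> 0
#' exercise_expectance(100, -2, p)  # all-rest maximum: A * C^2 = 400
#' exercise_expectance(100, 0, p)   # steady state: E = A = 100
#' @export
exercise_expectance <- function(a, alpha, params = aaei_params()) {
  params <- as_aaei_params(params)
  stopifnot(is.numeric(a), length(a) == 1L)
  if (!is.finite(a) || a < 0)
    stop("basic value 'a' must be finite and >= 0", call. = FALSE)
  if (is.null(alpha) || is.na(alpha) || a == 0) return(0)
  a * params$c^(-alpha)
}

#' Initial day state of the AAEI recursion
#'
#' The starting point before any activity has been recorded: index zero,
#' expectance zero, history coefficient null.
#'
#' @return An object of class `aaei_state` with fields `aaei`, `alpha`
#'   (`NA` = null), `started`, and the trace fields `mt`, `a`, `e`, `x` of the
#'   most recent day (all zero initially).
#' @examples
#' aaei_state()
#' @export
aaei_state <- function() {
  structure(list(aaei = 0, alpha = NA_real_, started = FALSE,
                 mt = 0, a = 0, e = 0, x = 0),
            class = "aaei_state")
}

#' @export
print.aaei_state <- function(x, ...) {
  cat(sprintf("AAEI day state: aaei = %.6g, alpha = %s, E = %.6g%s\n",
              x$aaei,
              if (is.na(x$alpha)) "null" else format(x$alpha, digits = 6),
              x$e,
              if (x$started) "" else " (no activity recorded yet)"))
  invisible(x)
}

# One day of the recursion. `state` carries the running attenuated history sum
# in `alpha_next` (exact, no truncation; the truncated explicit sum is
# alpha_coefficient()). Returns the post-update state for the day.
aaei_step <- function(state, mt, params) {
  a <- state$aaei / 7
  alpha <- if (state$started) {
    if (is.na(state$alpha)) 0 else state$alpha
  } else NA_real_
  e <- if (!is.na(alpha) && a > 0) a * params$c^(-alpha) else 0
  raw <- state$aaei + params$k * (mt - e)
  clamped <- raw < 0
  aaei_new <- max(0, raw)
  # today's history contribution: MET-minutes relative to today's basic value
  x <- if (aaei_new > 0) mt / (aaei_new / 7) - 1 else 0
  list(aaei = aaei_new,
       alpha = if (is.na(alpha)) NA_real_ else alpha, # value used today
       alpha_next = x + params$w * (if (is.na(alpha)) 0 else alpha),
       started = state$started || mt > 0,
       mt = mt, a = a, e = e, x = x, clamped = clamped)
}

#' Advance the AAEI by one day
#'
#' Applies one step of the recursion
#' `AAEI(t) = max(0, AAEI(t-1) + k * (MT(t) - E(t)))`, where the expectance
#' `E(t)` uses the basic value `A = AAEI(t-1)/7` and the history coefficient
#' accumulated over the days strictly before `t`. Under the parameter
#' constraint `k * c^(1/(1-w)) <= 7` the clamp at zero can never activate; a
#' warning is emitted if it ever does.
#'
#' @param prev An `aaei_state` (from [aaei_state()] or a previous update).
#' @param mt Today's physical activity in MET-minutes, `>= 0`.
#' @param params An [aaei_params()] object.
#' @return The new `aaei_state`. Its `aaei`, `a`, `e`, `mt` and `x` fields
#'   trace the day; `alpha` is the rolled-forward history coefficient that
#'   will apply to the *next* day (the value used for this day's expectance
#'   is in attribute `"alpha_used"`).
#' @examples
#' p <- aaei_params()
#' s <- aaei_update(aaei_state(), 100, p)  # first activity passes through
#' s$aaei                                  # 100
#' @export
aaei_update <- function(prev, mt, params = aaei_params()) {
  params <- as_aaei_params(params)
  if (!inherits(prev, "aaei_state"))
    stop("'prev' must be an aaei_state", call. = FALSE)
  stopifnot(is.numeric(mt), length(mt) == 1L)
  if (!is.finite(mt) || mt < 0)
    stop("'mt' (MET-minutes) must be finite and >= 0", call. = FALSE)
  st <- aaei_step(unclass(prev), mt, params)
  if (st$clamped)
    warning("AAEI clamped at zero; parameters violate k * c^(1/(1-w)) <= 7?",
            call. = FALSE)
  # roll the history sum forward so the next call sees alpha over days < t+1
  out <- structure(list(aaei = st$aaei, alpha = st$alpha_next,
                        started = st$started,
                        mt = st$mt, a = st$a, e = st$e, x = st$x),
                   class = "aaei_state")
  attr(out, "alpha_used") <- st$alpha
  attr(out, "clamped") <- st$clamped
  out
}

#' Compute the AAEI series of an activity log
#'
#' Runs the daily recursion over a MET-minute log. Every calendar day from the
#' first to the last log date is evaluated; dates absent from the log are rest
#' days (`MT = 0`). The per-day trace exposes the amount of activity `mt`, the
#' basic value `a`, the history coefficient `alpha` (`NA` until the first
#' activity has been recorded), the expectance `e` and the index `aaei`.
#'
#' @param log A data frame with columns `date` (`Date` or ISO-8601 strings)
#'   and `met_minutes` (`>= 0`). Dates must be unique; aggregate sessions
#'   first (see [read_activity_log()]).
#' @param params An [aaei_params()] object.
#' @return An `aaei_series`: a data frame with columns
#'   `date, mt, a, alpha, e, aaei, x`, one row per calendar day, with the
#'   parameters attached as attribute `"params"`.
#' @examples
#' log <- data.frame(date = as.Date("2024-01-01") + 0:6,
#'                   met_minutes = rep(100, 7))
#' s <- compute_aaei(log)
#' s$aaei  # 100, 200, ... climbing towards the 700 fixed point
#' @export
compute_aaei <- function(log, params = aaei_params()) {
  params <- as_aaei_params(params)
  if (!is.data.frame(log) || !all(c("date", "met_minutes") %in% names(log)))
    stop("'log' must be a data frame with columns 'date' and 'met_minutes'",
         call. = FALSE)
  if (nrow(log) == 0L) stop("'log' is empty", call. = FALSE)
  dates <- parse_log_dates(log$date)
  mt <- as.numeric(log$met_minutes)
  if (any(!is.finite(mt)) || any(mt < 0))
    stop("'met_minutes' must be finite and >= 0", call. = FALSE)
  if (anyDuplicated(dates)) {
    dup <- dates[duplicated(dates)][1]
    stop("duplicate date in log: ", format(dup),
         " (aggregate sessions per day first)", call. = FALSE)
  }
  o <- order(dates)
  dates <- dates[o]; mt <- mt[o]
  all_days <- seq(dates[1], dates[length(dates)], by = "day")
  mt_full <- numeric(length(all_days))
  mt_full[match(dates, all_days)] <- mt

  n <- length(all_days)
  out_mt <- out_a <- out_alpha <- out_e <- out_aaei <- out_x <- numeric(n)
  st <- list(aaei = 0, alpha = NA_real_, started = FALSE)
  clamped <- 0L
  for (i in seq_len(n)) {
    step <- aaei_step(st, mt_full[i], params)
    out_mt[i] <- step$mt; out_a[i] <- step$a
    out_alpha[i] <- step$alpha; out_e[i] <- step$e
    out_aaei[i] <- step$aaei; out_x[i] <- step$x
    clamped <- clamped + step$clamped
    st <- list(aaei = step$aaei, alpha = step$alpha_next,
               started = step$started)
  }
  if (clamped > 0L)
    warning(clamped, " day(s) clamped at zero; parameters violate ",
            "k * c^(1/(1-w)) <= 7?", call. = FALSE)
  res <- data.frame(date = all_days, mt = out_mt, a = out_a,
                    alpha = out_alpha, e = out_e, aaei = out_aaei, x = out_x)
  attr(res, "params") <- params
  attr(res, "clamped") <- clamped
  class(res) <- c("aaei_series", "data.frame")
  res
}

#' @export
print.aaei_series <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("AAEI series: %d days (%s to %s)%s\n",
              nrow(x), format(x$date[1]), format(x$date[nrow(x)]),
              if (is.null(p)) ""
              else sprintf(", k = %g, W = %g, C = %g", p$k, p$w, p$c)))
  cat(sprintf("  final AAEI %.4g, mean %.4g, %d exercise day(s)\n",
              x$aaei[nrow(x)], mean(x$aaei), sum(x$mt > 0)))
  NextMethod()
}

parse_log_dates <- function(x) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))[1]
    stop("unparseable date at row ", bad, ": '", as.character(x)[bad],
         "' (expected ISO-8601 YYYY-MM-DD)", call. = FALSE)
  }
  d
}
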