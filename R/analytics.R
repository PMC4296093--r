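#' Trailing moving average of the AAEI
#'
#' @param series An `aaei_series` from [compute_aaei()].
#' @param window Positive integer window length in days. The average is
#'   trailing (each day summarises itself and the `window - 1` days before
#'   it); the first `window - 1` days are omitted.
#' @return A data frame with columns `date` and `value`.
#' @examples
#' log <- data.frame(date = as.Date("2024-01-01") + 0:13,
#'                   met_minutes = rep(c(100, 0), 7))
#' ma <- moving_average(compute_aaei(log), 7)
#' @export
moving_average <- function(series, window) {
  series <- as_aaei_series(series)
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 1 || window != round(window))
    stop("'window' must be a positive integer number of days", call. = FALSE)
  window <- as.integer(window)
  if (window > nrow(series))
    return(data.frame(date = series$date[0], value = numeric(0)))
  vals <- zoo::rollmeanr(series$aaei, k = window)
  data.frame(date = series$date[window:nrow(series)], value = vals)
}

#' Weekly averages of the AAEI
#'
#' Mean index per consecutive 7-day block starting at the first day of the
#' series. A trailing block shorter than 7 days is reported with its actual
#' length in the `days` column.
#'
#' @param series An `aaei_series`.
#' @return A data frame with columns `week` (1-based block index), `value`
#'   (mean AAEI in the block) and `days` (block length, 7 except possibly for
#'   the final partial week).
#' @export
weekly_average <- function(series) {
  series <- as_aaei_series(series)
  wk <- (seq_len(nrow(series)) - 1L) %/% 7L + 1L
  agg <- tapply(series$aaei, wk, mean)
  len <- tapply(series$aaei, wk, length)
  data.frame(week = as.integer(names(agg)), value = as.numeric(agg),
             days = as.integer(len), row.names = NULL)
}

#' Crossovers between a short-term and a long-term moving average
#'
#' Scans two date-aligned moving-average tracks and emits an event wherever
#' the sign of `short - long` changes: an upward crossover signals that
#' recent physical activity rose above its longer-term level, a downward one
#' that it fell below.
#'
#' @param short_ma,long_ma Data frames with columns `date` and `value`, as
#'   returned by [moving_average()]. Only the common date range is compared;
#'   the overlapping dates must align exactly.
#' @return A data frame with columns `date` (day the new sign first holds) and
#'   `direction` (`"upward"` or `"downward"`). Zero rows when no crossover
#'   occurs. Days where the two tracks tie are carried over (no event until
#'   the sign actually flips).
#' @export
detect_crossovers <- function(short_ma, long_ma) {
  for (nm in list(short_ma, long_ma))
    if (!is.data.frame(nm) || !all(c("date", "value") %in% names(nm)))
      stop("moving-average inputs need columns 'date' and 'value'",
           call. = FALSE)
  common <- intersect(short_ma$date, long_ma$date)
  if (length(common) == 0L)
    stop("moving-average tracks share no dates", call. = FALSE)
  common <- sort(as.Date(common, origin = "1970-01-01"))
  if (any(diff(as.integer(common)) != 1L))
    stop("misaligned dates: the shared range is not contiguous",
         call. = FALSE)
  s <- short_ma$value[match(common, short_ma$date)]
  l <- long_ma$value[match(common, long_ma$date)]
  sgn <- sign(s - l)
  # propagate last nonzero sign through ties
  run <- sgn
  for (i in seq_along(run)[-1]) if (run[i] == 0) run[i] <- run[i - 1]
  flip <- which(run[-1] != run[-length(run)] & run[-1] != 0 &
                  run[-length(run)] != 0) + 1L
  data.frame(date = common[flip],
             direction = ifelse(run[flip] > 0, "upward", "downward"))
}

#' Goal achievement over an AAEI series
#'
#' Flags every day whose index meets a goal value and summarises the fraction
#' of such days. The conventional goal for a WHO-level exercise pattern is an
#' index of 600.
#'
#' @param series An `aaei_series`.
#' @param goal Non-negative goal value (default 600).
#' @return A list with `daily` (data frame `date`, `aaei`, `met`) and
#'   `fraction` (share of days with `aaei >= goal`).
#' @export
goal_check <- function(series, goal = 600) {
  series <- as_aaei_series(series)
  if (!is.numeric(goal) || length(goal) != 1L || is.na(goal) || goal < 0)
    stop("'goal' must be a single non-negative number", call. = FALSE)
  met <- series$aaei >= goal
  list(daily = data.frame(date = series$date, aaei = series$aaei, met = met),
       fraction = mean(met))
}

as_aaei_series <- function(series) {
  if (inherits(series, "aaei_series")) return(series)
  if (is.data.frame(series) && all(c("date", "aaei") %in% names(series)))
    return(series)
  stop("expected an 'aaei_series' (see compute_aaei())", call. = FALSE)
}
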