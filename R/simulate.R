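#' Stochastic exercise-adherence scenario
#'
#' Describes a behaviour pattern for the Poisson simulator: on each day,
#' independently, exercise occurs with probability `nominal_days_per_week/7`;
#' on exercise days one session is drawn with activity level
#' `~ Poisson(mean_met)` and duration `~ Poisson(mean_duration)`, both
#' conditioned to be at least 1, and the day's MET-minutes are their product.
#'
#' @param nominal_days_per_week Integer 1-7, target exercise days per week.
#' @param mean_duration Mean session duration in minutes, `> 0`.
#' @param mean_met Mean session activity level in MET, `> 0`.
#' @param weeks Number of simulated weeks (default 52, one year).
#' @param seed Integer RNG seed; every draw of the scenario is reproducible
#'   from it.
#' @param replicates Number of independent year-long replicates used by
#'   replicate-averaged summaries (default 20).
#' @return An object of class `sim_scenario`.
#' @examples
#' sim_scenario(5, 30, 5, seed = 42)  # the WHO recommendation
#' @export
sim_scenario <- function(nominal_days_per_week, mean_duration, mean_met,
                         weeks = 52L, seed = 1L, replicates = 20L) {
  if (!is.numeric(nominal_days_per_week) ||
      length(nominal_days_per_week) != 1L ||
      is.na(nominal_days_per_week) ||
      nominal_days_per_week != round(nominal_days_per_week) ||
      nominal_days_per_week < 1 || nominal_days_per_week > 7)
    stop("'nominal_days_per_week' must be an integer in 1..7", call. = FALSE)
  for (v in list(mean_duration = mean_duration, mean_met = mean_met))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("session means must be positive numbers", call. = FALSE)
  if (!is.numeric(weeks) || length(weeks) != 1L || weeks < 1 ||
      weeks != round(weeks))
    stop("'weeks' must be a positive integer", call. = FALSE)
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1 ||
      replicates != round(replicates))
    stop("'replicates' must be a positive integer", call. = FALSE)
  structure(list(nominal_days_per_week = as.integer(nominal_days_per_week),
                 mean_duration = mean_duration, mean_met = mean_met,
                 weeks = as.integer(weeks), seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("Simulation scenario: %d day(s)/week nominal, ",
                     "%g min x %g MET per session, %d weeks, seed %d, ",
                     "%d replicate(s)\n"),
              x$nominal_days_per_week, x$mean_duration, x$mean_met,
              x$weeks, x$seed, x$replicates))
  invisible(x)
}

# Poisson conditioned on >= 1, by rejection.
rpois_pos <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(zero <- x < 1L)) x[zero] <- stats::rpois(sum(zero), lambda)
  x
}

#' Simulate a daily activity log
#'
#' Draws one log of `7 * weeks` days from a scenario. Deterministic given the
#' scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @param start_date First calendar day of the log.
#' @return A data frame with columns `date` and `met_minutes` (0 on rest
#'   days), suitable for [compute_aaei()].
#' @examples
#' log <- simulate_log(sim_scenario(5, 30, 5, weeks = 4, seed = 1))
#' @export
simulate_log <- function(scenario, start_date = as.Date("2024-01-01")) {
  if (!inherits(scenario, "sim_scenario"))
    stop("'scenario' must come from sim_scenario()", call. = FALSE)
  set.seed(scenario$seed)
  simulate_log_draw(scenario, start_date)
}

# One draw from the current RNG stream (no re-seeding); used for replicates.
simulate_log_draw <- function(scenario, start_date = as.Date("2024-01-01")) {
  n <- 7L * scenario$weeks
  exercised <- stats::runif(n) < scenario$nominal_days_per_week / 7
  mt <- numeric(n)
  ne <- sum(exercised)
  if (ne > 0L) {
    level <- rpois_pos(ne, scenario$mean_met)
    duration <- rpois_pos(ne, scenario$mean_duration)
    mt[exercised] <- level * duration
  }
  data.frame(date = start_date + seq_len(n) - 1L, met_minutes = mt)
}

#' Summarise a simulated (or real) year of activity
#'
#' Computes the scenario-level statistics: average weekly physical activity,
#' realised exercise days per week, average daily AAEI, the AAEI/PA ratio
#' (average daily index over average weekly MET-minutes), the ideal reference
#' ratio interpolated at the realised days/week, and the percent deviation of
#' the realised ratio from that reference.
#'
#' @param log A data frame with `date` and `met_minutes` covering at least
#'   one week.
#' @param params An [aaei_params()] object.
#' @param curve An [ideal_curve()] for the same parameters (computed if
#'   omitted).
#' @return A list of class `sim_summary` with fields `avg_weekly_pa`,
#'   `avg_days_per_week`, `avg_aaei`, `aaei_pa_ratio`,
#'   `ideal_ratio_at_realized_days` and `deviation_pct`. For an all-rest log
#'   the ratio fields are `NA` with a warning.
#' @export
summarize_sim <- function(log, params = aaei_params(), curve = NULL) {
  params <- as_aaei_params(params)
  if (!is.data.frame(log) || nrow(log) < 7L)
    stop("'log' must span at least one week", call. = FALSE)
  if (is.null(curve)) curve <- ideal_curve(params)
  series <- compute_aaei(log, params)
  weeks <- nrow(series) / 7
  avg_weekly_pa <- sum(series$mt) / weeks
  avg_days <- sum(series$mt > 0) / weeks
  avg_aaei <- mean(series$aaei)
  if (avg_weekly_pa == 0) {
    warning("log contains no physical activity; AAEI/PA ratio undefined",
            call. = FALSE)
    ratio <- ideal_ratio <- deviation <- NA_real_
  } else {
    ratio <- avg_aaei / avg_weekly_pa
    ideal_ratio <- interpolate_ratio(curve, min(7, max(1, avg_days)))
    deviation <- abs(ratio - ideal_ratio) / ideal_ratio * 100
  }
  structure(list(avg_weekly_pa = avg_weekly_pa,
                 avg_days_per_week = avg_days,
                 avg_aaei = avg_aaei,
                 aaei_pa_ratio = ratio,
                 ideal_ratio_at_realized_days = ideal_ratio,
                 deviation_pct = deviation),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("Activity summary: %.0f MET-min/week, %.2f exercise days/week\n",
              x$avg_weekly_pa, x$avg_days_per_week))
  cat(sprintf("  average AAEI %.1f, AAEI/PA %.3f (ideal %.3f, deviation %.2f%%)\n",
              x$avg_aaei, x$aaei_pa_ratio, x$ideal_ratio_at_realized_days,
              x$deviation_pct))
  invisible(x)
}

#' Replicate-averaged scenario summary
#'
#' Runs `scenario$replicates` independent year-long simulations from the
#' scenario seed, summarises each, and averages the statistics. The ideal
#' reference ratio and the percent deviation are evaluated on the averaged
#' quantities (realised ratio vs ideal ratio at the replicate-mean realised
#' days/week).
#'
#' @param scenario A [sim_scenario()].
#' @param params An [aaei_params()] object.
#' @param curve An [ideal_curve()] for the same parameters (computed if
#'   omitted).
#' @return A list of class `sim_summary` (replicate means), with the
#'   per-replicate summaries in attribute `"replicates"`.
#' @examples
#' \donttest{
#' run_scenario(sim_scenario(5, 30, 5, seed = 1, replicates = 5))
#' }
#' @export
run_scenario <- function(scenario, params = aaei_params(), curve = NULL) {
  if (!inherits(scenario, "sim_scenario"))
    stop("'scenario' must come from sim_scenario()", call. = FALSE)
  params <- as_aaei_params(params)
  if (is.null(curve)) curve <- ideal_curve(params)
  set.seed(scenario$seed)
  reps <- vector("list", scenario$replicates)
  for (r in seq_len(scenario$replicates)) {
    log <- simulate_log_draw(scenario)
    reps[[r]] <- summarize_sim(log, params, curve)
  }
  get <- function(field) vapply(reps, `[[`, numeric(1), field)
  avg_days <- mean(get("avg_days_per_week"))
  ratio <- mean(get("aaei_pa_ratio"))
  ideal_ratio <- interpolate_ratio(curve, min(7, max(1, avg_days)))
  out <- structure(list(avg_weekly_pa = mean(get("avg_weekly_pa")),
                        avg_days_per_week = avg_days,
                        avg_aaei = mean(get("avg_aaei")),
                        aaei_pa_ratio = ratio,
                        ideal_ratio_at_realized_days = ideal_ratio,
                        deviation_pct = abs(ratio - ideal_ratio) /
                          ideal_ratio * 100),
                   class = "sim_summary")
  attr(out, "replicates") <- reps
  out
}
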