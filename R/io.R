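#' Read a daily activity log from CSV
#'
#' Two dialects are supported. Dialect A carries MET-minutes directly
#' (header `date,met_minutes`); dialect B carries sessions as activity level
#' and duration (header `date,activity_level,duration_min`) and the
#' MET-minutes are computed as their product. Lines starting with `#` are
#' comments. Rows sharing a date (multiple sessions or records on one day)
#' are summed; the result is date-sorted with one row per recorded day.
#'
#' @param path Path to a CSV file.
#' @param dialect `"auto"` (detect from the header), `"A"` or `"B"`.
#' @return A data frame with columns `date` (`Date`) and `met_minutes`,
#'   ready for [compute_aaei()].
#' @export
read_activity_log <- function(path, dialect = c("auto", "A", "B")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("activity log is empty: ", path, call. = FALSE)
  have <- names(raw)
  detected <-
    if (all(c("date", "met_minutes") %in% have)) "A"
    else if (all(c("date", "activity_level", "duration_min") %in% have)) "B"
    else stop("unknown activity-log header (", paste(have, collapse = ","),
              "); expected date,met_minutes or ",
              "date,activity_level,duration_min", call. = FALSE)
  if (dialect != "auto" && dialect != detected)
    stop("file header is dialect ", detected, ", not ", dialect,
         call. = FALSE)
  dates <- parse_log_dates(raw$date)
  if (detected == "A") {
    mt <- as.numeric(raw$met_minutes)
    if (anyNA(mt) || any(mt < 0)) {
      bad <- which(is.na(mt) | mt < 0)[1]
      stop("invalid met_minutes at data row ", bad, ": '",
           raw$met_minutes[bad], "'", call. = FALSE)
    }
  } else {
    lev <- as.numeric(raw$activity_level)
    dur <- as.numeric(raw$duration_min)
    bad <- which(is.na(lev) | is.na(dur) | lev <= 0 | dur <= 0)
    if (length(bad) > 0L)
      stop("invalid session at data row ", bad[1],
           ": activity_level and duration_min must be positive numbers",
           call. = FALSE)
    mt <- lev * dur
  }
  agg <- tapply(mt, dates, sum)
  out <- data.frame(date = as.Date(names(agg)), met_minutes = as.numeric(agg))
  out[order(out$date), , drop = FALSE]
}

#' Write an AAEI series to CSV
#'
#' Writes the per-day trace with header `date,mt,a,alpha,e,aaei`. A null
#' history coefficient is serialised as an empty field. The file starts with
#' comment lines recording the package version and the model parameters, so
#' a written series is self-describing; numbers carry 12 significant digits
#' and round-trip through [utils::read.csv()].
#'
#' @param series An `aaei_series` from [compute_aaei()].
#' @param path Output path. On any error nothing partial is left behind (the
#'   file is written to a temporary sibling and renamed).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  series <- as_aaei_series(series)
  p <- attr(series, "params")
  num <- function(v) sprintf("%.12g", v)
  alpha_chr <- ifelse(is.na(series$alpha), "", num(series$alpha))
  lines <- c(
    sprintf("# aaei %s", as.character(utils::packageVersion("aaei"))),
    sprintf("# k=%s W=%s C=%s tail_epsilon=%s",
            num(p$k), num(p$w), num(p$c), num(p$tail_epsilon)),
    "date,mt,a,alpha,e,aaei",
    paste(format(series$date), num(series$mt), num(series$a), alpha_chr,
          num(series$e), num(series$aaei), sep = ","))
  tmp <- paste0(path, ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path))
    stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognised keys: `k`, `w`, `c`, `tail_epsilon` (model parameters),
#' `goal` (goal index value, default 600) and `ma_windows` (moving-average
#' window lengths in days, default `c(7, 30)`). Missing keys fall back to the
#' defaults; unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `params` (an [aaei_params()]), `goal` and
#'   `ma_windows`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("k", "w", "c", "tail_epsilon", "goal", "ma_windows")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L)
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  pick <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  params <- aaei_params(k = pick("k", 1), w = pick("w", 0.5),
                        c = pick("c", 2),
                        tail_epsilon = pick("tail_epsilon", 1e-9))
  windows <- pick("ma_windows", c(7, 30))
  if (!is.numeric(windows) || any(windows < 1) ||
      any(windows != round(windows)) || anyDuplicated(windows))
    stop("'ma_windows' must be distinct positive integers", call. = FALSE)
  goal <- pick("goal", 600)
  if (!is.numeric(goal) || length(goal) != 1L || goal < 0)
    stop("'goal' must be a single non-negative number", call. = FALSE)
  list(params = params, goal = goal, ma_windows = as.integer(windows))
}

#' Generate a deterministic activity-log fixture
#'
#' Writes small, reproducible CSV logs used in tests and documentation:
#' \describe{
#'   \item{`ideal`}{the 5-days/week even periodic pattern (100 MET-minutes
#'     per week) repeated for 4 weeks.}
#'   \item{`who`}{a seeded year of the WHO recommendation scenario
#'     (5 days/week, 30 min, 5 MET).}
#'   \item{`vigorous`}{a seeded year of short vigorous sessions
#'     (2 days/week, 20 min, 10 MET).}
#'   \item{`inactive`}{a seeded year of low activity
#'     (2 days/week, 15 min, 5 MET).}
#'   \item{`rest-decay`}{14 everyday-exercise days at 100 MET-minutes
#'     followed by 7 rest days.}
#' }
#'
#' @param kind One of `"ideal"`, `"who"`, `"vigorous"`, `"inactive"`,
#'   `"rest-decay"`.
#' @param path Output CSV path (dialect A).
#' @param seed Seed for the stochastic kinds.
#' @return `path`, invisibly.
#' @export
make_fixture <- function(kind, path, seed = 42L) {
  kind <- match.arg(kind,
                    c("ideal", "who", "vigorous", "inactive", "rest-decay"))
  start <- as.Date("2024-01-01")
  log <- switch(kind,
    "ideal" = data.frame(
      date = start + 0:27,
      met_minutes = rep(ideal_pattern(5, 100)$daily_mt, 4)),
    "who" = simulate_log(sim_scenario(5, 30, 5, seed = seed), start),
    "vigorous" = simulate_log(sim_scenario(2, 20, 10, seed = seed), start),
    "inactive" = simulate_log(sim_scenario(2, 15, 5, seed = seed), start),
    "rest-decay" = data.frame(
      date = start + 0:20,
      met_minutes = c(rep(100, 14), rep(0, 7))))
  tmp <- paste0(path, ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c("date,met_minutes",
               paste(format(log$date),
                     sprintf("%.12g", log$met_minutes),
                     sep = ",")),
             tmp)
  if (!file.rename(tmp, path))
    stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}
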