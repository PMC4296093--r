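Package: aaei
Title: Accumulated Activity Effective Index for Physical-Activity Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the Accumulated Activity Effective Index (AAEI), a
    non-negative daily score of physical-activity status driven by MET-minute
    logs. The index accumulates daily MET-minutes and subtracts an "exercise
    expectance" penalty that grows with consecutive rest days, so that roughly
    one week of activity is tracked: everyday exercise at m MET-minutes/day
    stabilises the index at 7m, while seven rest days bring it near zero.
    Includes steady-state analysis of ideal periodic weekly schedules (the
    AAEI-to-physical-activity ratio as a function of exercise days per week),
    a seeded Poisson exercise-behaviour simulator for year-long adherence
    scenarios, moving-average and crossover analytics, goal checking, CSV
    readers/writers for activity logs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
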