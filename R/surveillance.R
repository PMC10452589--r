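# Surveillance schedules and visit-level test-panel arithmetic. A scheduled
# visit comprises a clinic visit, a CEA blood test, and a CT scan; colonoscopy
# is added at months 12 and 48. Visits sit at the end of each interval and
# active surveillance runs for 5 years of the 10-year horizon.

#' Build a surveillance schedule
#'
#' @param strategy One of [strategy_codes()].
#' @param horizon Model horizon in monthly cycles (default 120). Visit cycles
#'   beyond the horizon are dropped.
#' @return A `metasurv_schedule` with `visit_cycles`, `colonoscopy_cycles`,
#'   and a per-cycle integer flag vector used by the simulation engine
#'   (0 = none, 1 = visit, 2 = visit + colonoscopy).
#' @export
#' @examples
#' build_schedule("q3/q12")$visit_cycles
build_schedule <- function(strategy, horizon = 120) {
  strategy <- normalize_strategy(strategy)
  stopifnot(length(strategy) == 1, horizon >= 1)
  visits <- switch(strategy,
    none   = integer(0),
    q12    = seq(12L, 60L, by = 12L),
    q6     = seq(6L, 60L, by = 6L),
    q6_q12 = c(seq(6L, 24L, by = 6L), 36L, 48L, 60L),
    q3_q12 = c(seq(3L, 24L, by = 3L), 36L, 48L, 60L)
  )
  visits <- visits[visits <= horizon]
  colono <- if (strategy == "none") integer(0) else
    intersect(c(12L, 48L), visits)
  flags <- integer(horizon)
  flags[visits] <- 1L
  flags[colono] <- 2L
  structure(list(strategy = strategy, visit_cycles = visits,
                 colonoscopy_cycles = colono, horizon = as.integer(horizon),
                 visit_flags = flags),
            class = "metasurv_schedule")
}

#' @export
print.metasurv_schedule <- function(x, ...) {
  cat(sprintf("<metasurv_schedule> %s: %d visits (%s), colonoscopy at {%s}\n",
              x$strategy, length(x$visit_cycles),
              paste(x$visit_cycles, collapse = ","),
              paste(x$colonoscopy_cycles, collapse = ",")))
  invisible(x)
}

#' Per-visit detection probability of the test panel
#'
#' Probability that at least one test at a surveillance visit detects an
#' existing recurrence, treating tests as conditionally independent given
#' disease status: `1 - prod(1 - sensitivity_i)`.
#'
#' @param tests `tests` block of a `metasurv_config`.
#' @param with_colonoscopy Include the colonoscopy performed at months 12/48?
#' @return Probability in `[0, 1]`.
#' @export
panel_sensitivity <- function(tests, with_colonoscopy = FALSE) {
  s <- c(tests$clinic_visit$sensitivity, tests$cea_test$sensitivity,
         tests$ct$sensitivity,
         if (with_colonoscopy) tests$colonoscopy$sensitivity)
  1 - prod(1 - s)
}

#' Per-visit false-positive probability of the test panel
#'
#' Probability that a disease-free visit produces at least one positive test:
#' `1 - prod(specificity_i)`.
#'
#' @inheritParams panel_sensitivity
#' @return Probability in `[0, 1]`.
#' @export
panel_false_positive <- function(tests, with_colonoscopy = FALSE) {
  sp <- c(tests$clinic_visit$specificity, tests$cea_test$specificity,
          tests$ct$specificity,
          if (with_colonoscopy) tests$colonoscopy$specificity)
  1 - prod(sp)
}

#' Cost of one surveillance visit
#'
#' Clinic visit plus CEA test plus CT scan, with optional scheduled
#' colonoscopy, and optionally one confirmatory CT following a false-positive
#' panel result.
#'
#' @param costs `costs` block of a `metasurv_config`.
#' @param with_colonoscopy Scheduled colonoscopy at this visit?
#' @param confirmatory_workup Add one confirmatory CT (false-positive workup)?
#' @return Cost in CAD.
#' @export
#' @examples
#' visit_cost(default_config()$costs)
visit_cost <- function(costs, with_colonoscopy = FALSE,
                       confirmatory_workup = FALSE) {
  costs$clinic_visit + costs$cea_test + costs$ct_scan +
    (if (with_colonoscopy) costs$colonoscopy else 0) +
    (if (confirmatory_workup) costs$ct_scan else 0)
}
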