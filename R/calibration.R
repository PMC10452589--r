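# Calibration: convert the cohort's printed survival summaries into the
# constant monthly transition probabilities the simulation engine consumes.
# Constant (exponential) hazards are the minimal assumption available when
# only point survival summaries, not curves, are published.

#' Monthly transition probability from a survival fraction
#'
#' Constant-hazard conversion: a fraction `surviving_fraction` still event-free
#' after `elapsed_months` implies the per-month event probability
#' `1 - surviving_fraction^(1 / elapsed_months)`.
#'
#' @param surviving_fraction Event-free proportion at `elapsed_months`, in
#'   `(0, 1]`. Zero is rejected (it implies an infinite hazard).
#' @param elapsed_months Positive elapsed time in months.
#' @return Monthly event probability in `[0, 1)`. Vectorized.
#' @export
#' @examples
#' monthly_prob_from_survival(0.815, 120) # background death hazard
monthly_prob_from_survival <- function(surviving_fraction, elapsed_months) {
  if (any(!is.finite(surviving_fraction)) || any(surviving_fraction <= 0)) {
    abort(paste("surviving_fraction must be in (0, 1]; a zero survivor",
                "fraction implies an infinite hazard."))
  }
  if (any(surviving_fraction > 1)) abort("surviving_fraction must be <= 1.")
  if (any(!is.finite(elapsed_months)) || any(elapsed_months <= 0)) {
    abort("elapsed_months must be > 0.")
  }
  1 - surviving_fraction^(1 / elapsed_months)
}

#' Calibrate monthly transition probabilities
#'
#' Anchors the recurrence hazard at the cohort's cumulative recurrence by its
#' median follow-up, the background death hazard at 10-year survival of
#' non-recurred patients, and the post-recurrence death hazard at 5-year
#' survival of recurred patients; the undetected-to-symptomatic transition is
#' geometric with the stated mean sojourn (probability `1/mean` per cycle).
#' Operative mortality and resection probabilities pass through unchanged.
#'
#' @param cohort Cohort summary block of a config (or a full
#'   `metasurv_config`, from which both blocks are taken).
#' @param clinical Clinical-inputs block of a config; ignored when `cohort`
#'   is a full config.
#' @return A `metasurv_transitions` list of monthly probabilities.
#' @export
#' @examples
#' tp <- calibrate(default_config())
#' tp$p_recur_month
calibrate <- function(cohort, clinical = NULL) {
  if (inherits(cohort, "metasurv_config") ||
      (is.null(clinical) && all(c("cohort", "clinical") %in% names(cohort)))) {
    clinical <- cohort$clinical
    cohort <- cohort$cohort
  }
  if (is.null(clinical)) abort("calibrate() needs both cohort and clinical inputs.")
  tp <- list(
    p_recur_month = monthly_prob_from_survival(
      1 - cohort$recurrence_fraction, cohort$median_followup_months),
    p_symptomatic_month = 1 / clinical$mean_months_undetected_to_symptomatic,
    p_die_background_month = monthly_prob_from_survival(
      cohort$os10_nonrecurred, 120),
    p_die_postrecurrence_month = monthly_prob_from_survival(
      cohort$os5_recurred, 60),
    p_operative_death = clinical$metastasectomy_mortality,
    p_resect_asymptomatic = clinical$asymptomatic_metastasectomy_rate,
    p_resect_symptomatic = clinical$symptomatic_metastasectomy_rate
  )
  bad <- names(tp)[vapply(tp, function(p) !is.finite(p) || p < 0 || p > 1,
                          logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("Calibrated probabilities outside [0, 1]: %s.",
                  paste(bad, collapse = ", ")))
  }
  structure(tp, class = "metasurv_transitions")
}

#' @export
print.metasurv_transitions <- function(x, ...) {
  cat("<metasurv_transitions> (per monthly cycle)\n")
  for (k in names(x)) cat(sprintf("  %-28s %.6f\n", k, x[[k]]))
  invisible(x)
}
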