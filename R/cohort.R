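# Synthetic-cohort generator: patient-level recurrence, detection, resection
# and survival data with the statistical structure of the population cohort
# behind the model inputs, so that calibration and engine can be exercised
# end-to-end without any external data. Event times are drawn as continuous
# exponentials with the same monthly hazards the engine uses (the engine's
# per-cycle geometric process is exactly the ceiling of these times), which
# makes fixed-time summaries recover the calibration inputs exactly in
# expectation.

exp_time <- function(u, p_month) {
  lambda <- -log(1 - p_month)
  if (lambda <= 0) return(rep(Inf, length(u)))
  -log(u) / lambda
}

#' Generate a synthetic patient cohort
#'
#' Draws, per patient: a continuous time to recurrence and a background death
#' time (both exponential with the calibrated monthly hazards), a
#' post-recurrence survival time for patients who recur within follow-up, a
#' geometric undetected-to-symptomatic sojourn, per-visit asymptomatic
#' detection under a surveillance schedule, and repeat-resection indicators at
#' the asymptomatic/symptomatic rates. Death clocks are independent of
#' detection by design: the generator emulates the observed cohort from which
#' the hazards were calibrated, it does not model treatment effect (the
#' engine does that).
#'
#' @param tp Calibrated `metasurv_transitions`.
#' @param n Number of patients.
#' @param followup_months Common follow-up used to classify recurrence
#'   (default: the cohort's median follow-up, 76.4 months).
#' @param seed Integer seed.
#' @param schedule Surveillance schedule under which asymptomatic detection
#'   can occur (default `q6_q12`).
#' @param tests Test panel used for per-visit detection probabilities.
#' @return Tibble with one row per patient: `id`, `recurred`,
#'   `time_to_recurrence` (months, `NA` when censored at follow-up),
#'   `time_to_death` (months from baseline, latent event time),
#'   `detected_asymptomatically`, `presented_symptomatic`,
#'   `repeat_resection`, `followup`.
#' @export
#' @examples
#' tp <- calibrate(default_config())
#' cohort <- generate_cohort(tp, n = 257, seed = 42)
#' mean(cohort$recurred)
generate_cohort <- function(tp, n, followup_months = 76.4, seed,
                            schedule = build_schedule("q6_q12"),
                            tests = default_config()$tests) {
  stopifnot(n >= 1, followup_months > 0)
  set.seed(seed)
  t_recur <- exp_time(runif(n), tp$p_recur_month)
  t_bg <- exp_time(runif(n), tp$p_die_background_month)
  t_post <- exp_time(runif(n), tp$p_die_postrecurrence_month)
  sojourn <- rgeom(n, tp$p_symptomatic_month) + 1L # cycles undetected
  u_resect <- runif(n)
  recurred <- t_recur <= followup_months
  time_to_death <- ifelse(recurred, t_recur + t_post, t_bg)

  visits <- schedule$visit_cycles
  sens_v <- vapply(visits, function(v) {
    panel_sensitivity(tests, v %in% schedule$colonoscopy_cycles)
  }, numeric(1))
  u_detect <- matrix(runif(n * length(visits)), nrow = n)

  death_cycle <- ceiling(time_to_death)
  sympt_cycle <- ceiling(t_recur) + sojourn
  detected <- rep(FALSE, n)
  if (length(visits) > 0) {
    for (k in seq_along(visits)) {
      v <- visits[k]
      eligible <- recurred & !detected & ceiling(t_recur) < v & v < sympt_cycle &
        v < death_cycle
      detected <- detected | (eligible & u_detect[, k] < sens_v[k])
    }
  }
  presented <- recurred & !detected & sympt_cycle < death_cycle
  resected <- (detected & u_resect < tp$p_resect_asymptomatic) |
    (presented & u_resect < tp$p_resect_symptomatic)

  tibble::tibble(
    id = seq_len(n),
    recurred = recurred,
    time_to_recurrence = ifelse(recurred, t_recur, NA_real_),
    time_to_death = time_to_death,
    detected_asymptomatically = detected,
    presented_symptomatic = presented,
    repeat_resection = resected,
    followup = followup_months
  )
}

#' Crude cohort summary statistics
#'
#' Fixed-time cumulative fractions matching the cohort-summary inputs of the
#' calibration: recurrence by follow-up, survival at 5 and 10 years after
#' recurrence for the recurred stratum, survival at 10 years for the
#' non-recurred stratum, and the asymptomatic/symptomatic repeat-resection
#' rates, each with a binomial Monte Carlo standard error.
#'
#' @param patients Output of [generate_cohort()].
#' @return Tibble: `parameter`, `estimate`, `se`, `n`.
#' @export
summarize_cohort <- function(patients) {
  if (is.null(patients) || nrow(patients) == 0) {
    abort("Cannot summarize an empty cohort.")
  }
  prop <- function(x) {
    n <- length(x)
    if (n == 0) return(c(NA_real_, NA_real_, 0))
    p <- mean(x)
    c(p, sqrt(p * (1 - p) / n), n)
  }
  rec <- patients$recurred
  post_surv <- patients$time_to_death[rec] - patients$time_to_recurrence[rec]
  rows <- list(
    recurrence_fraction = prop(rec),
    os5_recurred = prop(post_surv >= 60),
    os10_recurred = prop(post_surv >= 120),
    os10_nonrecurred = prop(patients$time_to_death[!rec] >= 120),
    asymptomatic_resection_rate =
      prop(patients$repeat_resection[patients$detected_asymptomatically]),
    symptomatic_resection_rate =
      prop(patients$repeat_resection[patients$presented_symptomatic])
  )
  tibble::tibble(
    parameter = names(rows),
    estimate = vapply(rows, `[`, numeric(1), 1),
    se = vapply(rows, `[`, numeric(1), 2),
    n = as.integer(vapply(rows, `[`, numeric(1), 3))
  )
}

#' Parameter-recovery report
#'
#' Compares cohort-summary estimates against the values implied by a known
#' set of transition probabilities (the generator's truth): per-parameter
#' z-scores, a pass flag at `|z| <= 3`, and a low-power note for strata too
#' small to be informative.
#'
#' @param truth A `metasurv_transitions` (the generating parameters).
#' @param estimate Output of [summarize_cohort()].
#' @param followup_months Follow-up used when generating the cohort.
#' @return List with `table` (parameter, estimate, se, predicted, z, pass),
#'   `pass` (all parameters within 3 SE), and `low_power` (any stratum with
#'   fewer than 30 patients or an undefined z-score).
#' @export
parameter_recovery <- function(truth, estimate, followup_months = 76.4) {
  predicted <- c(
    recurrence_fraction = 1 - (1 - truth$p_recur_month)^followup_months,
    os5_recurred = (1 - truth$p_die_postrecurrence_month)^60,
    os10_recurred = (1 - truth$p_die_postrecurrence_month)^120,
    os10_nonrecurred = (1 - truth$p_die_background_month)^120,
    asymptomatic_resection_rate = truth$p_resect_asymptomatic,
    symptomatic_resection_rate = truth$p_resect_symptomatic
  )
  tbl <- estimate
  tbl$predicted <- predicted[tbl$parameter]
  se_floor <- sqrt(tbl$predicted * (1 - tbl$predicted) / pmax(tbl$n, 1))
  se_eff <- pmax(tbl$se, se_floor, na.rm = TRUE)
  tbl$z <- (tbl$estimate - tbl$predicted) / se_eff
  tbl$z[tbl$n == 0] <- NA_real_
  tbl$pass <- is.na(tbl$z) | abs(tbl$z) <= 3
  list(table = tbl,
       pass = all(tbl$pass),
       low_power = any(tbl$n < 30 | is.na(tbl$z)))
}
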