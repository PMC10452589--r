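# The Markov micro-simulation engine surface. The per-cycle transition kernel
# exists twice on purpose: `step_patient()` is a plain-R reference
# implementation, and src/engine.cpp is the fast path used by
# `run_strategy()`; both consume identical counter-based uniform draws, so a
# trajectory simulated in R must match the C++ engine exactly (this is
# asserted in the test suite).

.STATE_NAMES <- c("NED", "UNDETECTED_RECURRENCE", "CURATIVE_TREATMENT",
                  "PALLIATIVE_SYMPTOMATIC", "PALLIATIVE_ASYMPTOMATIC", "DEAD")
.EVENT_BITS <- c(scheduled_visit = 1L, colonoscopy = 2L,
                 detection_asymptomatic = 4L, symptomatic_presentation = 8L,
                 metastasectomy = 16L, operative_death = 32L,
                 false_positive = 64L, death = 128L)
.PUR <- c(death = 1, recur = 2, convert = 3, detect = 4, resect = 5,
          opdeath = 6, fp = 7)

#' Health states of the Markov model
#'
#' Six states: alive with no evidence of disease; alive with undetected
#' recurrence; alive in curative-intent treatment (metastasectomy plus
#' perioperative chemotherapy); alive in palliative treatment with symptomatic
#' or with asymptomatic (surveillance-detected) disease; deceased. `DEAD` is
#' absorbing.
#'
#' @return Character vector of state names.
#' @export
health_states <- function() .STATE_NAMES

decode_events <- function(bits) {
  names(.EVENT_BITS)[bitwAnd(bits, .EVENT_BITS) > 0L]
}

#' Mid-cycle discount factor
#'
#' Discount factor applied to costs and outcomes accruing in a given monthly
#' cycle: `(1 + annual_rate)^(-(cycle - 0.5) / 12)`. Discounting to the middle
#' of the cycle is the individual-level analogue of half-cycle correction.
#'
#' @param annual_rate Annual discount rate (e.g. 0.015).
#' @param cycle Cycle index, 1-based. Vectorized.
#' @return Discount factor(s) in `(0, 1]`.
#' @export
#' @examples
#' monthly_discount_factor(0.015, c(1, 120))
monthly_discount_factor <- function(annual_rate, cycle) {
  stopifnot(annual_rate >= 0, all(cycle >= 1))
  (1 + annual_rate)^(-(cycle - 0.5) / 12)
}

# State-indexed utility vector in engine order.
state_utilities <- function(config) {
  u <- config$utilities
  c(u$ned, u$undetected_recurrence, u$curative_treatment,
    u$palliative_symptomatic, u$palliative_asymptomatic)
}

# Parameter block handed to the C++ engine.
engine_params <- function(config, tp, schedule) {
  list(
    p_recur = tp$p_recur_month, p_sympt = tp$p_symptomatic_month,
    p_bg = tp$p_die_background_month, p_postrec = tp$p_die_postrecurrence_month,
    p_opdeath = tp$p_operative_death,
    p_res_a = tp$p_resect_asymptomatic, p_res_s = tp$p_resect_symptomatic,
    utilities = state_utilities(config),
    c_visit = visit_cost(config$costs),
    c_colono = config$costs$colonoscopy,
    c_fp_workup = config$costs$ct_scan,
    c_surgery = config$costs$hepatic_metastasectomy +
      config$costs$post_anesthesia_recovery,
    c_cur_chemo = config$costs$curative_chemo_month,
    c_pall_chemo = config$costs$palliative_chemo_month,
    cur_dur = as.integer(config$clinical$curative_treatment_duration),
    pall_dur = as.integer(config$clinical$palliative_chemo_duration),
    sens = panel_sensitivity(config$tests, FALSE),
    sens_colono = panel_sensitivity(config$tests, TRUE),
    fp = panel_false_positive(config$tests, FALSE),
    fp_colono = panel_false_positive(config$tests, TRUE),
    annual_rate = config$settings$annual_discount_rate,
    horizon = as.integer(config$settings$horizon),
    charge_fp = isTRUE(config$clinical$charge_false_positive_workup),
    visit = schedule$visit_flags
  )
}

#' One monthly transition of a simulated patient (reference kernel)
#'
#' Advances a patient one cycle: a death draw for the current state
#' (background hazard while disease-free or under curative treatment,
#' post-recurrence hazard otherwise), then recurrence, symptomatic
#' conversion, scheduled-visit detection, resection and operative-death
#' draws, and false-positive draws at disease-free visits. Deaths truncate
#' the cycle: state utility, life-years and continuous treatment costs take
#' half weight in the death cycle, while one-off event costs keep full
#' weight.
#'
#' This is the plain-R reference implementation; [run_strategy()] uses the
#' compiled engine, which draws the same counter-based uniforms and is tested
#' to produce identical trajectories.
#'
#' @param state Current state name (see [health_states()]), not `"DEAD"`.
#' @param cycle Cycle index, 1-based.
#' @param tp Calibrated `metasurv_transitions`.
#' @param schedule A `metasurv_schedule`.
#' @param config A `metasurv_config`.
#' @param stream List with `seed` and `patient` identifying the draw stream.
#' @param counters List with `months_in_curative` and `months_in_palliative`
#'   (cycles already completed in the current treatment state).
#' @return List: `next_state`, `events` (character), `cycle_cost`,
#'   `cycle_utility`, `cycle_ly`, updated `counters`.
#' @export
step_patient <- function(state, cycle, tp, schedule, config, stream,
                         counters = list(months_in_curative = 0L,
                                         months_in_palliative = 0L)) {
  state_i <- match(state, .STATE_NAMES)
  if (is.na(state_i)) abort(sprintf("Unknown state '%s'.", state))
  if (state_i == 6L) abort("Cannot step a DEAD patient: DEAD is absorbing.")
  u <- function(purpose) .cpp_u01(stream$seed, stream$patient, cycle,
                                  .PUR[[purpose]])
  par <- engine_params(config, tp, schedule)
  vf <- par$visit[cycle]
  events <- integer(0)
  event_cost <- 0
  nxt <- state_i

  p_die <- if (state_i %in% c(1L, 3L)) par$p_bg else par$p_postrec
  if (u("death") < p_die) {
    events <- .EVENT_BITS[["death"]]
    nxt <- 6L
  } else if (state_i == 1L) { # NED
    recurred <- u("recur") < par$p_recur
    if (vf > 0L) {
      events <- c(events, .EVENT_BITS[["scheduled_visit"]])
      event_cost <- event_cost + par$c_visit
      if (vf == 2L) {
        events <- c(events, .EVENT_BITS[["colonoscopy"]])
        event_cost <- event_cost + par$c_colono
      }
      if (!recurred && u("fp") < (if (vf == 2L) par$fp_colono else par$fp)) {
        events <- c(events, .EVENT_BITS[["false_positive"]])
        if (par$charge_fp) event_cost <- event_cost + par$c_fp_workup
      }
    }
    nxt <- if (recurred) 2L else 1L
  } else if (state_i == 2L) { # undetected recurrence
    if (u("convert") < par$p_sympt) {
      events <- c(events, .EVENT_BITS[["symptomatic_presentation"]])
      if (u("resect") < par$p_res_s) {
        events <- c(events, .EVENT_BITS[["metastasectomy"]])
        event_cost <- event_cost + par$c_surgery
        if (u("opdeath") < par$p_opdeath) {
          events <- c(events, .EVENT_BITS[["operative_death"]],
                      .EVENT_BITS[["death"]])
          nxt <- 6L
        } else {
          nxt <- 3L
          counters$months_in_curative <- 0L
        }
      } else {
        nxt <- 4L
        counters$months_in_palliative <- 0L
      }
    } else if (vf > 0L) {
      events <- c(events, .EVENT_BITS[["scheduled_visit"]])
      event_cost <- event_cost + par$c_visit
      if (vf == 2L) {
        events <- c(events, .EVENT_BITS[["colonoscopy"]])
        event_cost <- event_cost + par$c_colono
      }
      if (u("detect") < (if (vf == 2L) par$sens_colono else par$sens)) {
        events <- c(events, .EVENT_BITS[["detection_asymptomatic"]])
        if (u("resect") < par$p_res_a) {
          events <- c(events, .EVENT_BITS[["metastasectomy"]])
          event_cost <- event_cost + par$c_surgery
          if (u("opdeath") < par$p_opdeath) {
            events <- c(events, .EVENT_BITS[["operative_death"]],
                        .EVENT_BITS[["death"]])
            nxt <- 6L
          } else {
            nxt <- 3L
            counters$months_in_curative <- 0L
          }
        } else {
          nxt <- 5L
          counters$months_in_palliative <- 0L
        }
      }
    }
  } else if (state_i == 3L) { # curative treatment
    counters$months_in_curative <- counters$months_in_curative + 1L
    if (counters$months_in_curative >= par$cur_dur) nxt <- 1L
  }
  # Palliative states: no transitions beyond the death draw above.

  w <- if (nxt == 6L) 0.5 else 1
  occupancy <- if (state_i == 3L) {
    par$c_cur_chemo
  } else if (state_i %in% c(4L, 5L)) {
    m_pall <- counters$months_in_palliative
    counters$months_in_palliative <- m_pall + 1L
    if (m_pall < par$pall_dur) par$c_pall_chemo else 0
  } else 0
  list(
    next_state = .STATE_NAMES[nxt],
    events = names(.EVENT_BITS)[match(events, .EVENT_BITS)],
    cycle_cost = event_cost + w * occupancy,
    cycle_utility = w * par$utilities[min(state_i, 5L)] *
      (state_i != 6L) / 12,
    cycle_ly = w / 12,
    counters = counters
  )
}

#' Simulate one patient trajectory
#'
#' Runs a patient from no evidence of disease through the monthly-cycle model
#' until death or the horizon, recording per-cycle state, events, cost,
#' utility and life-year increments (undiscounted; see [accrue()] for
#' discounted totals). The `engine` argument selects the compiled engine or
#' the R reference kernel; both produce identical trajectories for the same
#' `seed` and `patient`.
#'
#' @param config A `metasurv_config`.
#' @param schedule A `metasurv_schedule` (or strategy code).
#' @param tp Calibrated transitions; recalibrated from `config` when `NULL`.
#' @param seed Integer seed of the simulation run.
#' @param patient Patient index within the run (the draw substream).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return Tibble with one row per lived cycle: `cycle`, `state`, `events`
#'   (`;`-separated), `cost`, `utility`, `ly`.
#' @export
#' @examples
#' cfg <- default_config()
#' simulate_patient(cfg, "q12", seed = 1, patient = 7)
simulate_patient <- function(config, schedule, tp = NULL, seed, patient = 1,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.character(schedule)) {
    schedule <- build_schedule(schedule, config$settings$horizon)
  }
  if (is.null(tp)) tp <- calibrate(config)
  if (engine == "cpp") {
    m <- .cpp_trajectory(seed, patient, engine_params(config, tp, schedule))
    return(tibble::tibble(
      cycle = as.integer(m[, 1]),
      state = .STATE_NAMES[m[, 2]],
      events = vapply(m[, 3], function(b) {
        paste(decode_events(as.integer(b)), collapse = ";")
      }, character(1)),
      cost = m[, 4], utility = m[, 5], ly = m[, 6]
    ))
  }
  stream <- list(seed = seed, patient = patient)
  counters <- list(months_in_curative = 0L, months_in_palliative = 0L)
  state <- "NED"
  rows <- vector("list", config$settings$horizon)
  n <- 0L
  for (cycle in seq_len(config$settings$horizon)) {
    st <- step_patient(state, cycle, tp, schedule, config, stream, counters)
    counters <- st$counters
    n <- n + 1L
    rows[[n]] <- tibble::tibble(
      cycle = cycle, state = state,
      events = paste(st$events, collapse = ";"),
      cost = st$cycle_cost, utility = st$cycle_utility, ly = st$cycle_ly)
    if (st$next_state == "DEAD") break
    state <- st$next_state
  }
  dplyr::bind_rows(rows[seq_len(n)])
}

#' Discounted totals of a trajectory
#'
#' Applies the mid-cycle discount factor to the per-cycle cost, utility and
#' life-year increments of a simulated trajectory. Half-cycle correction is
#' already encoded in the trajectory (deaths carry half-weight increments in
#' their final cycle).
#'
#' @param trajectory Output of [simulate_patient()].
#' @param config A `metasurv_config` (supplies the discount rate).
#' @return List with discounted `cost`, `qaly`, `ly`.
#' @export
accrue <- function(trajectory, config) {
  df <- monthly_discount_factor(config$settings$annual_discount_rate,
                                trajectory$cycle)
  list(cost = sum(trajectory$cost * df),
       qaly = sum(trajectory$utility * df),
       ly = sum(trajectory$ly * df))
}

#' Run one surveillance strategy
#'
#' Simulates `n_patients` independent trajectories under one schedule and
#' returns mean discounted cost, QALYs and life-years with Monte Carlo
#' standard errors, plus event summaries. Patients are identified by a
#' counter-based draw stream keyed on `(seed, patient)` only, so running
#' different strategies with the same seed reuses the same patients (common
#' random numbers): identical seed and config give bit-identical results.
#'
#' @param config A `metasurv_config`.
#' @param strategy One of [strategy_codes()].
#' @param n_patients Number of simulated patients.
#' @param seed Integer run seed.
#' @param tp Optional pre-calibrated transitions.
#' @param keep_patients If `TRUE`, attach the per-patient result matrix as
#'   attribute `"patients"`.
#' @return One-row tibble (`metasurv` strategy result).
#' @export
#' @examples
#' run_strategy(default_config(), "q12", n_patients = 500, seed = 1)
run_strategy <- function(config, strategy, n_patients = config$settings$n_patients,
                         seed = config$settings$rng_seed, tp = NULL,
                         keep_patients = FALSE) {
  strategy <- normalize_strategy(strategy)
  stopifnot(n_patients >= 1)
  if (is.null(tp)) tp <- calibrate(config)
  schedule <- build_schedule(strategy, config$settings$horizon)
  m <- .cpp_run_patients(as.integer(n_patients), seed,
                         engine_params(config, tp, schedule))
  se <- function(x) sd(x) / sqrt(length(x))
  out <- tibble::tibble(
    strategy = strategy,
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    mean_cost = mean(m[, "cost"]), se_cost = se(m[, "cost"]),
    mean_qaly = mean(m[, "qaly"]), se_qaly = se(m[, "qaly"]),
    mean_ly = mean(m[, "ly"]), se_ly = se(m[, "ly"]),
    mean_colonoscopies = mean(m[, "n_colonoscopy"]),
    max_colonoscopies = max(m[, "n_colonoscopy"]),
    prop_recurred = mean(m[, "recurred"]),
    prop_detected_asymptomatic = mean(m[, "detected_asymptomatic"]),
    prop_dead = mean(m[, "death_cycle"] > 0)
  )
  if (keep_patients) attr(out, "patients") <- m
  out
}

#' Run several strategies on the same simulated patients
#'
#' @inheritParams run_strategy
#' @param strategies Strategy codes (default: the four active schedules).
#' @return Tibble with one row per strategy, sharing seed and patients.
#' @export
run_strategies <- function(config, strategies = strategy_codes(active_only = TRUE),
                           n_patients = config$settings$n_patients,
                           seed = config$settings$rng_seed, tp = NULL) {
  strategies <- normalize_strategy(strategies)
  if (anyDuplicated(strategies)) abort("Duplicate strategy codes.")
  if (is.null(tp)) tp <- calibrate(config)
  dplyr::bind_rows(lapply(strategies, function(s) {
    run_strategy(config, s, n_patients = n_patients, seed = seed, tp = tp)
  }))
}
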