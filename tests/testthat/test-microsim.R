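test_that("mid-cycle discount factors follow the stated formula", {
  expect_equal(monthly_discount_factor(0, 1), 1)
  expect_equal(monthly_discount_factor(0, 120), 1)
  expect_equal(monthly_discount_factor(0.015, 1), 1.015^(-0.5 / 12))
  expect_equal(monthly_discount_factor(0.015, 1), 0.99938, tolerance = 1e-5)
  expect_equal(monthly_discount_factor(0.015, 120), 0.862202, tolerance = 1e-6)
  expect_true(all(diff(monthly_discount_factor(0.015, 1:120)) < 0))
})

test_that("accrual applies half-cycle credit and discounting", {
  cfg <- default_config()
  cfg$settings$annual_discount_rate <- 0
  # death in cycle 1: half a month of NED utility
  tr1 <- tibble::tibble(cycle = 1L, state = "NED", events = "death",
                        cost = 0, utility = 0.5 * 0.78 / 12, ly = 0.5 / 12)
  expect_equal(accrue(tr1, cfg)$qaly, 0.0325)
  # full-horizon survivor
  tr2 <- tibble::tibble(cycle = 1:120, state = "NED", events = "",
                        cost = 0, utility = 0.78 / 12, ly = 1 / 12)
  expect_equal(accrue(tr2, cfg)$ly, 10)
  expect_equal(accrue(tr2, cfg)$qaly, 7.8)
  cfg$settings$annual_discount_rate <- 0.015
  # brute-force oracle for the discounted sum
  expect_equal(accrue(tr2, cfg)$ly,
               sum((1 / 12) * 1.015^(-(1:120 - 0.5) / 12)))
  expect_equal(accrue(tr2, cfg)$ly, 9.2912, tolerance = 1e-4)
})

test_that("zero hazards make NED absorbing and reproduce schedule costs", {
  cfg <- zero_hazard_config()
  cfg$settings$annual_discount_rate <- 0
  tp <- calibrate(cfg)
  tr <- simulate_patient(cfg, "none", tp, seed = 3, patient = 1)
  expect_equal(nrow(tr), 120)
  expect_true(all(tr$state == "NED"))
  expect_equal(sum(tr$cost), 0)
  expect_equal(accrue(tr, cfg)$qaly, 7.8)

  # with no disease, a q12 patient pays exactly the full surveillance
  # schedule (minus any false-positive workups, which we disable here)
  cfg$clinical$charge_false_positive_workup <- FALSE
  res <- run_strategy(cfg, "q12", n_patients = 50, seed = 3)
  expect_equal(res$mean_cost, 4052.25)
  expect_equal(res$mean_ly, 10)
})

test_that("R reference kernel and compiled engine agree trajectory-by-trajectory", {
  cfg <- default_config()
  tp <- calibrate(cfg)
  for (s in c("none", "q12", "q3_q12")) {
    for (p in c(1, 2, 17, 101)) {
      a <- simulate_patient(cfg, s, tp, seed = 11, patient = p, engine = "cpp")
      b <- simulate_patient(cfg, s, tp, seed = 11, patient = p, engine = "r")
      expect_equal(as.data.frame(a), as.data.frame(b),
                   label = sprintf("%s patient %d", s, p))
    }
  }
})

test_that("step_patient branch frequencies match the exact branch tree", {
  cfg <- zero_hazard_config()
  cfg$clinical$metastasectomy_mortality <- 0.010
  cfg$clinical$mean_months_undetected_to_symptomatic <- 1 # convert next cycle
  cfg <- validate_config(cfg)
  tp <- calibrate(cfg)
  sched <- build_schedule("q12")
  n <- 20000
  nxt <- vapply(seq_len(n), function(p) {
    step_patient("UNDETECTED_RECURRENCE", 5, tp, sched, cfg,
                 stream = list(seed = 91, patient = p))$next_state
  }, character(1))
  freq <- table(factor(nxt, levels = health_states())) / n
  # exact enumeration: symptomatic conversion is certain; resection 0.05;
  # operative death 0.01 of resections; no other death hazards
  expected <- c(PALLIATIVE_SYMPTOMATIC = 0.95,
                CURATIVE_TREATMENT = 0.05 * 0.99,
                DEAD = 0.05 * 0.01)
  for (s in names(expected)) {
    se <- sqrt(expected[[s]] * (1 - expected[[s]]) / n)
    expect_lt(abs(freq[[s]] - expected[[s]]), 3 * se + 1e-12, label = s)
  }
  expect_equal(sum(freq), 1)
})

test_that("palliative states only persist or die, and DEAD is absorbing", {
  cfg <- default_config()
  tp <- calibrate(cfg)
  sched <- build_schedule("q6")
  for (p in 1:200) {
    st <- step_patient("PALLIATIVE_ASYMPTOMATIC", 30, tp, sched, cfg,
                       stream = list(seed = 5, patient = p))
    expect_true(st$next_state %in% c("PALLIATIVE_ASYMPTOMATIC", "DEAD"))
    st <- step_patient("PALLIATIVE_SYMPTOMATIC", 30, tp, sched, cfg,
                       stream = list(seed = 6, patient = p))
    expect_true(st$next_state %in% c("PALLIATIVE_SYMPTOMATIC", "DEAD"))
  }
  expect_error(step_patient("DEAD", 10, tp, sched, cfg,
                            stream = list(seed = 1, patient = 1)), "absorbing")
})

test_that("state occupancy accounts for every patient every cycle", {
  cfg <- default_config()
  tp <- calibrate(cfg)
  n <- 200
  death_cycle <- rep(Inf, n)
  alive_rows <- integer(120)
  for (p in seq_len(n)) {
    tr <- simulate_patient(cfg, "q6_q12", tp, seed = 21, patient = p)
    alive_rows[tr$cycle] <- alive_rows[tr$cycle] + 1L
    if (grepl("death", tr$events[nrow(tr)])) death_cycle[p] <- tr$cycle[nrow(tr)]
  }
  for (c in 1:120) {
    expect_equal(alive_rows[c] + sum(death_cycle < c), n)
  }
})

test_that("strategy results respect basic outcome inequalities", {
  cfg <- default_config()
  res <- run_strategies(cfg, n_patients = 2000, seed = 8)
  expect_true(all(res$mean_qaly <= res$mean_ly))
  expect_true(all(res$mean_cost >= 0))
  expect_true(all(res$max_colonoscopies <= 2))
  # discounting can only shrink totals
  cfg0 <- cfg
  cfg0$settings$annual_discount_rate <- 0
  und <- run_strategy(cfg0, "q6", n_patients = 2000, seed = 8)
  dis <- run_strategy(cfg, "q6", n_patients = 2000, seed = 8)
  expect_lt(dis$mean_cost, und$mean_cost)
  expect_lt(dis$mean_qaly, und$mean_qaly)
})

test_that("with blind tests every strategy matches no surveillance except costs", {
  cfg <- blind_tests_config()
  none <- run_strategy(cfg, "none", n_patients = 3000, seed = 14,
                       keep_patients = TRUE)
  q3 <- run_strategy(cfg, "q3_q12", n_patients = 3000, seed = 14,
                     keep_patients = TRUE)
  mn <- attr(none, "patients")
  mq <- attr(q3, "patients")
  # identical patients (common random numbers): identical health outcomes
  expect_identical(mq[, "qaly"], mn[, "qaly"])
  expect_identical(mq[, "ly"], mn[, "ly"])
  expect_equal(sum(mq[, "detected_asymptomatic"]), 0)
  expect_true(all(mq[, "cost"] >= mn[, "cost"]))
})

test_that("more intensive surveillance detects more, paired patients", {
  cfg <- default_config()
  q12 <- run_strategy(cfg, "q12", n_patients = 5000, seed = 31)
  q3 <- run_strategy(cfg, "q3_q12", n_patients = 5000, seed = 31)
  expect_gt(q3$prop_detected_asymptomatic, q12$prop_detected_asymptomatic)
})

test_that("raising the asymptomatic resection rate does not lower QALYs", {
  cfg <- default_config()
  hi <- set_config_value(cfg, "clinical.asymptomatic_metastasectomy_rate", 0.30)
  for (s in c("q12", "q3_q12")) {
    a <- run_strategy(cfg, s, n_patients = 10000, seed = 12)
    b <- run_strategy(hi, s, n_patients = 10000, seed = 12)
    se_diff <- sqrt(a$se_qaly^2 + b$se_qaly^2)
    expect_gt(b$mean_qaly - a$mean_qaly, -2 * se_diff)
  }
})

test_that("with no recurrence, life expectancy matches the closed form", {
  cfg <- default_config()
  cfg$cohort$recurrence_fraction <- 0
  cfg <- validate_config(cfg)
  tp <- calibrate(cfg)
  p <- tp$p_die_background_month
  res <- run_strategy(cfg, "none", n_patients = 20000, seed = 19, tp = tp)
  df <- monthly_discount_factor(0.015, 1:120)
  # survive the cycle (full 1/12) or die in it (half credit)
  closed <- sum(df / 12 * ((1 - p)^(1:120) + 0.5 * (1 - p)^(0:119) * p))
  expect_lt(abs(res$mean_ly - closed), 3 * res$se_ly)
})

test_that("identical seed and config reproduce results exactly", {
  cfg <- default_config()
  r1 <- run_strategy(cfg, "q6_q12", n_patients = 1500, seed = 99)
  r2 <- run_strategy(cfg, "q6_q12", n_patients = 1500, seed = 99)
  expect_identical(r1, r2)
  t1 <- simulate_patient(cfg, "q6", seed = 99, patient = 3)
  t2 <- simulate_patient(cfg, "q6", seed = 99, patient = 3)
  expect_identical(t1, t2)
})
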