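# Shared fixtures, all built in code.

base_cfg <- default_config()

# Config whose calibrated hazards are all zero (immortal, recurrence-free
# cohort); operative mortality also zero.
zero_hazard_config <- function() {
  cfg <- default_config()
  cfg$cohort$recurrence_fraction <- 0
  cfg$cohort$os5_recurred <- 1
  cfg$cohort$os10_recurred <- 1
  cfg$cohort$os10_nonrecurred <- 1
  cfg$clinical$metastasectomy_mortality <- 0
  cfg$clinical$metastasectomy_mortality_range <- c(0, 0.015)
  validate_config(cfg)
}

# Config with every PSA family collapsed to fixed.
all_fixed_config <- function() {
  cfg <- default_config()
  cfg$psa <- lapply(cfg$psa, function(d) {
    list(family = "fixed")
  })
  validate_config(cfg)
}

# Config whose test panel never detects anything.
blind_tests_config <- function() {
  cfg <- default_config()
  for (m in names(cfg$tests)) {
    cfg$tests[[m]]$sensitivity <- 0
    cfg$tests[[m]]$sensitivity_range <- c(0, 1)
  }
  validate_config(cfg)
}

# Printed strategy-level results (cost, QALY, LY) used by the incremental
# arithmetic checks.
published_table2 <- function() {
  tibble::tibble(
    strategy = c("q12", "q6_q12", "q6", "q3_q12"),
    cost = c(7707, 14175, 14191, 19890),
    qaly = c(0.6797, 0.7453, 0.7449, 0.7692),
    ly = c(0.8952, 0.9769, 0.9763, 1.0125)
  )
}

# Random strategy instances for frontier property tests.
random_instance <- function(n) {
  tibble::tibble(
    strategy = paste0("s", seq_len(n)),
    cost = stats::runif(n, 0, 25000),
    qaly = stats::runif(n, 0, 1)
  )
}
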