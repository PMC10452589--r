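# Model configuration: every input the model consumes, as one validated,
# nested list. Costs are 2021 Canadian dollars from the public-payer
# perspective; utilities are 0-1 health-state weights; test operating
# characteristics are per-modality sensitivities/specificities with their
# published uncertainty ranges.

CONFIG_SCHEMA <- "metasurv-config/1"

#' Base-case model configuration
#'
#' Returns the complete base-case parameter set: surveillance test costs and
#' operating characteristics, health-state utilities, clinical probabilities
#' (operative mortality, repeat-resection rates, mean time from undetected to
#' symptomatic recurrence), the population cohort summary used for hazard
#' calibration, analysis settings (monthly cycles over a 10-year horizon,
#' 1.5% annual discounting, 10,000 simulated patients), and the per-parameter
#' distribution assignments used by the probabilistic sensitivity analysis.
#'
#' Two costing conventions are deliberate and user-overridable:
#' `curative_chemo_month` (6 months of perioperative oxaliplatin-based
#' chemotherapy) defaults to the monthly palliative systemic-therapy cost as a
#' proxy, and palliative systemic therapy is charged as a single course cost
#' at entry into a palliative state (`clinical$palliative_chemo_duration = 1`
#' cycle); set the duration to the horizon to charge it monthly for life.
#'
#' @return A `metasurv_config` object (nested named list).
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$costs$ct_scan
#' cfg$clinical$symptomatic_metastasectomy_rate
default_config <- function() {
  test_row <- function(sens, sens_lo, sens_hi, spec, spec_lo, spec_hi) {
    list(sensitivity = sens, sensitivity_range = c(sens_lo, sens_hi),
         specificity = spec, specificity_range = c(spec_lo, spec_hi))
  }
  cfg <- list(
    schema = CONFIG_SCHEMA,
    costs = list(
      cea_test = 60.62,
      clinic_visit = 25.94,
      colonoscopy = 1059.35,
      ct_scan = 300.15,
      hepatic_metastasectomy = 4086.72,
      post_anesthesia_recovery = 84.58,
      palliative_chemo_month = 6409.77,
      curative_chemo_month = 6409.77
    ),
    utilities = list(
      ned = 0.78,
      undetected_recurrence = 0.74,
      curative_treatment = 0.74,
      palliative_asymptomatic = 0.68,
      palliative_symptomatic = 0.50
    ),
    tests = list(
      clinic_visit = test_row(0.42, 0.27, 0.57, 0.95, 0.70, 1.00),
      cea_test     = test_row(0.64, 0.49, 0.79, 0.90, 0.75, 1.00),
      ct           = test_row(0.83, 0.68, 0.98, 0.93, 0.78, 1.00),
      colonoscopy  = test_row(0.95, 0.80, 1.00, 1.00, 0.85, 1.00)
    ),
    clinical = list(
      metastasectomy_mortality = 0.010,
      metastasectomy_mortality_range = c(0.003, 0.015),
      mean_months_undetected_to_symptomatic = 4,
      mean_months_undetected_to_symptomatic_range = c(1, 28),
      asymptomatic_metastasectomy_rate = 0.23,
      symptomatic_metastasectomy_rate = 0.05,
      curative_treatment_duration = 6,
      palliative_chemo_duration = 1,
      charge_false_positive_workup = TRUE
    ),
    cohort = list(
      recurrence_fraction = 0.751,
      median_followup_months = 76.4,
      os5_recurred = 0.254,
      os10_recurred = 0.031,
      os10_nonrecurred = 0.815
    ),
    settings = list(
      cycle_length = 1,
      horizon = 120,
      n_patients = 10000,
      n_psa_draws = 10000,
      n_patients_per_psa_draw = 1000,
      annual_discount_rate = 0.015,
      wtp_grid = c(seq(0, 200000, by = 25000), 300000, 425000, 500000, 750000),
      rng_seed = 17
    ),
    psa = default_psa_distributions()
  )
  structure(cfg, class = "metasurv_config")
}

# Distribution assignments for the probabilistic sensitivity analysis.
# Gamma for costs and the time-to-symptomatic interval, beta for probabilities;
# parameters without a usable published spread stay fixed. Printed ranges are
# read as 95% intervals (SD = width / 3.92); printed SDs are used directly.
default_psa_distributions <- function() {
  sd_from_range <- function(lo, hi) (hi - lo) / 3.92
  dist <- function(family, mean, sd) list(family = family, mean = mean, sd = sd)
  out <- list(
    "costs.clinic_visit" = dist("gamma", 25.94, sd_from_range(10.37, 41.60)),
    "costs.colonoscopy" = dist("gamma", 1059.35, sd_from_range(618.06, 14833.48)),
    "costs.hepatic_metastasectomy" = dist("gamma", 4086.72, 741.75),
    "costs.post_anesthesia_recovery" = dist("gamma", 84.58, 31.43),
    "clinical.metastasectomy_mortality" =
      dist("beta", 0.010, sd_from_range(0.003, 0.015)),
    "clinical.mean_months_undetected_to_symptomatic" =
      dist("gamma", 4, sd_from_range(1, 28))
  )
  sens <- list(clinic_visit = c(0.42, 0.27, 0.57), cea_test = c(0.64, 0.49, 0.79),
               ct = c(0.83, 0.68, 0.98), colonoscopy = c(0.95, 0.80, 1.00))
  spec <- list(clinic_visit = c(0.95, 0.70, 1.00), cea_test = c(0.90, 0.75, 1.00),
               ct = c(0.93, 0.78, 1.00), colonoscopy = c(1.00, 0.85, 1.00))
  for (m in names(sens)) {
    out[[paste0("tests.", m, ".sensitivity")]] <-
      dist("beta", sens[[m]][1], sd_from_range(sens[[m]][2], sens[[m]][3]))
    out[[paste0("tests.", m, ".specificity")]] <-
      dist("beta", spec[[m]][1], sd_from_range(spec[[m]][2], spec[[m]][3]))
  }
  # Everything else is held fixed in the PSA (no usable published spread,
  # or excluded by design: utilities, resection rates, CEA/CT/chemo costs).
  fixed <- c("costs.cea_test", "costs.ct_scan", "costs.palliative_chemo_month",
             "costs.curative_chemo_month", "utilities.ned",
             "utilities.undetected_recurrence", "utilities.curative_treatment",
             "utilities.palliative_asymptomatic",
             "utilities.palliative_symptomatic",
             "clinical.asymptomatic_metastasectomy_rate",
             "clinical.symptomatic_metastasectomy_rate")
  for (f in fixed) out[[f]] <- list(family = "fixed")
  out
}

#' Read a model configuration file
#'
#' Reads a YAML (or JSON) configuration and merges it over the packaged
#' base-case defaults, so a partial file only needs to state the values it
#' changes; an empty file yields the defaults exactly. Unknown fields and
#' out-of-range values raise errors naming the offending field.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated `metasurv_config`.
#' @seealso [default_config()], [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::yaml.load_file(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$schema) && !identical(raw$schema, CONFIG_SCHEMA)) {
    abort(sprintf("Unsupported config schema '%s' (expected '%s').",
                  raw$schema, CONFIG_SCHEMA))
  }
  cfg <- merge_config(default_config(), raw)
  validate_config(cfg)
}

#' Write a model configuration file
#'
#' @param config A `metasurv_config`.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(x, precision = 12L), path)
  }
  invisible(path)
}

# Recursive merge of a partial user config over the defaults; errors on
# fields that do not exist in the schema.
merge_config <- function(base, override, prefix = NULL) {
  if (length(override) == 0) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == "")) {
    abort(sprintf("Config section '%s' must be a named mapping.",
                  paste(prefix, collapse = ".")))
  }
  for (k in nm) {
    path <- paste(c(prefix, k), collapse = ".")
    if (identical(k, "psa")) { # PSA table keys are parameter paths, not schema
      base$psa <- modifyList(base$psa, override$psa)
      next
    }
    if (!k %in% names(base)) abort(sprintf("Unknown config field: '%s'.", path))
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(override[[k]])) {
        abort(sprintf("Config field '%s' must be a mapping.", path))
      }
      base[[k]] <- merge_config(base[[k]], override[[k]], c(prefix, k))
    } else {
      base[[k]] <- if (is.list(override[[k]])) unlist(override[[k]]) else override[[k]]
    }
  }
  base
}

#' Validate a model configuration
#'
#' Checks ranges and cross-field invariants (non-negative costs, utilities and
#' probabilities in `[0, 1]`, ordered uncertainty ranges, cohort survival
#' consistency, a willingness-to-pay grid containing the CAD 50,000 reference
#' threshold) and returns the config invisibly unchanged on success.
#'
#' @param config A `metasurv_config`.
#' @return The validated config (classed), invisibly usable in pipelines.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) abort("Config must be a list.")
  required <- c("costs", "utilities", "tests", "clinical", "cohort",
                "settings", "psa")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort(sprintf("Config is missing required section(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  fail <- function(field, msg) {
    abort(sprintf("Invalid config value for '%s': %s.", field, msg))
  }
  check_num <- function(x, field, lo = -Inf, hi = Inf) {
    if (is.null(x) || !is.numeric(x) || length(x) == 0 || anyNA(x)) {
      fail(field, "must be a number")
    }
    if (any(x < lo) || any(x > hi)) {
      fail(field, sprintf("must be in [%s, %s]", lo, hi))
    }
  }
  for (k in names(config$costs)) {
    check_num(config$costs[[k]], paste0("costs.", k), lo = 0)
  }
  for (k in names(config$utilities)) {
    check_num(config$utilities[[k]], paste0("utilities.", k), lo = 0, hi = 1)
  }
  for (m in names(config$tests)) {
    tr <- config$tests[[m]]
    for (what in c("sensitivity", "specificity")) {
      field <- paste0("tests.", m, ".", what)
      check_num(tr[[what]], field, 0, 1)
      rng <- tr[[paste0(what, "_range")]]
      check_num(rng, paste0(field, "_range"), 0, 1)
      if (length(rng) != 2 || rng[1] > tr[[what]] || tr[[what]] > rng[2]) {
        fail(paste0(field, "_range"), "must satisfy lo <= point <= hi")
      }
    }
  }
  cl <- config$clinical
  check_num(cl$metastasectomy_mortality, "clinical.metastasectomy_mortality", 0, 1)
  check_num(cl$asymptomatic_metastasectomy_rate,
            "clinical.asymptomatic_metastasectomy_rate", 0, 1)
  check_num(cl$symptomatic_metastasectomy_rate,
            "clinical.symptomatic_metastasectomy_rate", 0, 1)
  check_num(cl$mean_months_undetected_to_symptomatic,
            "clinical.mean_months_undetected_to_symptomatic", lo = 1)
  check_num(cl$curative_treatment_duration,
            "clinical.curative_treatment_duration", lo = 1)
  check_num(cl$palliative_chemo_duration,
            "clinical.palliative_chemo_duration", lo = 0)
  co <- config$cohort
  for (k in c("recurrence_fraction", "os5_recurred", "os10_recurred",
              "os10_nonrecurred")) {
    check_num(co[[k]], paste0("cohort.", k), 0, 1)
  }
  check_num(co$median_followup_months, "cohort.median_followup_months", lo = 1)
  if (co$os10_recurred > co$os5_recurred) {
    fail("cohort.os10_recurred", "10-year survival cannot exceed 5-year survival")
  }
  st <- config$settings
  check_num(st$horizon, "settings.horizon", lo = 1)
  check_num(st$cycle_length, "settings.cycle_length", lo = 1)
  check_num(st$n_patients, "settings.n_patients", lo = 1)
  check_num(st$annual_discount_rate, "settings.annual_discount_rate", lo = 0)
  check_num(st$wtp_grid, "settings.wtp_grid", lo = 0)
  if (!any(st$wtp_grid == 50000)) {
    fail("settings.wtp_grid", "must include the 50,000 CAD/QALY threshold")
  }
  for (k in names(config$psa)) {
    d <- config$psa[[k]]
    if (!is.list(d) || !d$family %in% c("gamma", "beta", "fixed")) {
      fail(paste0("psa.", k), "family must be one of gamma, beta, fixed")
    }
  }
  structure(config, class = "metasurv_config")
}

#' @export
print.metasurv_config <- function(x, ...) {
  cat("<metasurv_config>\n")
  cat(sprintf("  horizon: %d monthly cycles; discount %.1f%%/yr; %d patients\n",
              as.integer(x$settings$horizon),
              100 * x$settings$annual_discount_rate,
              as.integer(x$settings$n_patients)))
  n_sampled <- sum(vapply(x$psa, function(d) d$family != "fixed", logical(1)))
  cat(sprintf("  PSA: %d sampled parameters, %d fixed\n",
              n_sampled, length(x$psa) - n_sampled))
  invisible(x)
}

#' Leaf parameter paths of a configuration
#'
#' Dot-separated paths (e.g. `"clinical.mean_months_undetected_to_symptomatic"`)
#' addressing every scalar model input, as accepted by [set_config_value()]
#' and the deterministic sensitivity analyses.
#'
#' @param config A `metasurv_config`.
#' @return Character vector of parameter paths.
#' @export
config_parameter_paths <- function(config = default_config()) {
  out <- character(0)
  walk <- function(x, prefix) {
    for (k in names(x)) {
      if (is.list(x[[k]])) {
        walk(x[[k]], c(prefix, k))
      } else {
        out[[length(out) + 1]] <<- paste(c(prefix, k), collapse = ".")
      }
    }
  }
  walk(config[c("costs", "utilities", "tests", "clinical", "cohort", "settings")],
       character(0))
  out
}

#' Set one configuration value by path
#'
#' @param config A `metasurv_config`.
#' @param path Dot-separated parameter path, see [config_parameter_paths()].
#' @param value Replacement value.
#' @return The modified, re-validated config.
#' @export
set_config_value <- function(config, path, value) {
  if (!path %in% config_parameter_paths(config)) {
    abort(sprintf(
      "Unknown parameter path '%s'. Known paths include: %s, ...",
      path, paste(utils::head(config_parameter_paths(config), 8), collapse = ", ")))
  }
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  config[[keys]] <- value
  validate_config(config)
}

get_config_value <- function(config, path) {
  config[[strsplit(path, ".", fixed = TRUE)[[1]]]]
}

#' Stable digest of a configuration
#'
#' Hash over the validated configuration contents; identical configurations
#' hash identically, so run manifests can assert reproducibility.
#'
#' @param config A `metasurv_config`.
#' @return A character hash.
#' @export
config_digest <- function(config) {
  rlang::hash(unclass(validate_config(config)))
}
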