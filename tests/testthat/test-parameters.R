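test_that("base-case defaults hold the published input values", {
  cfg <- default_config()
  expect_equal(cfg$costs$cea_test, 60.62)
  expect_equal(cfg$costs$ct_scan, 300.15)
  expect_equal(cfg$costs$colonoscopy, 1059.35)
  expect_equal(cfg$costs$palliative_chemo_month, 6409.77)
  expect_equal(cfg$utilities$ned, 0.78)
  expect_equal(cfg$utilities$palliative_symptomatic, 0.50)
  expect_equal(cfg$tests$ct$sensitivity, 0.83)
  expect_equal(cfg$tests$colonoscopy$specificity, 1.00)
  expect_equal(cfg$tests$colonoscopy$specificity_range, c(0.85, 1.00))
  expect_equal(cfg$clinical$metastasectomy_mortality, 0.010)
  expect_equal(cfg$clinical$mean_months_undetected_to_symptomatic, 4)
  expect_equal(cfg$clinical$asymptomatic_metastasectomy_rate, 0.23)
  expect_equal(cfg$clinical$symptomatic_metastasectomy_rate, 0.05)
  expect_equal(cfg$settings$annual_discount_rate, 0.015)
  expect_equal(cfg$settings$horizon, 120)
  expect_true(50000 %in% cfg$settings$wtp_grid)
})

test_that("parameters without a usable published spread stay fixed in the PSA", {
  psa <- default_config()$psa
  for (p in c("costs.cea_test", "costs.ct_scan", "costs.palliative_chemo_month",
              "utilities.ned", "clinical.asymptomatic_metastasectomy_rate",
              "clinical.symptomatic_metastasectomy_rate")) {
    expect_identical(psa[[p]]$family, "fixed", label = p)
  }
  expect_identical(psa[["costs.colonoscopy"]]$family, "gamma")
  expect_identical(psa[["tests.ct.sensitivity"]]$family, "beta")
  expect_equal(psa[["tests.ct.sensitivity"]]$sd, (0.98 - 0.68) / 3.92)
})

test_that("the packaged base-case file reproduces the defaults", {
  p <- system.file("extdata", "base_case.yaml", package = "metasurv")
  expect_true(nzchar(p))
  expect_equal(unclass(load_config(p)), unclass(default_config()),
               tolerance = 1e-9)
})

test_that("an empty override file yields the packaged defaults", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", p)
  expect_identical(config_digest(load_config(p)), config_digest(default_config()))
  expect_equal(load_config(p)$costs$ct_scan, 300.15)
})

test_that("overrides merge onto defaults and are range-checked", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines("utilities:\n  ned: 1.0\n", p)
  cfg <- load_config(p)
  expect_equal(cfg$utilities$ned, 1.0)
  expect_equal(cfg$utilities$palliative_symptomatic, 0.50) # untouched default

  writeLines("utilities:\n  ned: 1.2\n", p)
  expect_error(load_config(p), "utilities.ned")
  writeLines("costs:\n  ct_scan: -5\n", p)
  expect_error(load_config(p), "costs.ct_scan")
  writeLines("costs:\n  laser_surgery: 10\n", p)
  expect_error(load_config(p), "laser_surgery")
})

test_that("configs round-trip through YAML and JSON", {
  cfg <- default_config()
  cfg$settings$n_patients <- 1234
  for (ext in c(".yaml", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_config(cfg, p)
    expect_equal(unclass(load_config(p)), unclass(cfg), tolerance = 1e-9)
  }
})

test_that("missing sections and bad paths raise named errors", {
  expect_error(validate_config(list(costs = list())), "missing required")
  expect_error(set_config_value(default_config(), "clinical.nonexistent", 1),
               "Unknown parameter path")
  cfg <- set_config_value(default_config(), "utilities.ned", 0.8)
  expect_equal(cfg$utilities$ned, 0.8)
  expect_error(set_config_value(default_config(), "utilities.ned", 2),
               "utilities.ned")
})
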