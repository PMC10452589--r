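test_that("dominance annotation handles simple and degenerate instances", {
  # plainly dominated pair
  two <- tibble::tibble(strategy = c("a", "b"), cost = c(100, 50),
                        qaly = c(1.0, 2.0))
  tab <- incremental_table(two)
  expect_equal(tab$dominance[tab$strategy == "a"], "absolutely_dominated")
  expect_equal(tab$dominance[tab$strategy == "b"], "reference")

  # three collinear strategies: none dominated, equal ICERs retained
  lin <- tibble::tibble(strategy = c("a", "b", "c"),
                        cost = c(0, 100, 200), qaly = c(0, 0.01, 0.02))
  tab <- incremental_table(lin)
  expect_false(any(grepl("dominated", tab$dominance)))
  expect_equal(tab$frontier_icer[-1], c(10000, 10000))

  # single strategy: reference only, no ICER
  one <- incremental_table(tibble::tibble(strategy = "a", cost = 1, qaly = 1))
  expect_equal(one$dominance, "reference")
  expect_true(all(is.na(one$icer)))

  expect_error(incremental_table(
    tibble::tibble(strategy = c("a", "a"), cost = 1:2, qaly = 1:2)),
    "Duplicate")
})

test_that("frontier ICERs increase along surviving strategies", {
  set.seed(501)
  for (i in 1:50) {
    tab <- incremental_table(random_instance(sample(2:8, 1)))
    f <- tab$frontier_icer[tab$dominance %in% c("frontier")]
    if (length(f) > 1) expect_true(all(diff(f) >= -1e-9))
  }
})

test_that("elimination loop agrees with the brute-force frontier oracle", {
  set.seed(502)
  for (i in 1:200) {
    inst <- random_instance(sample(2:8, 1))
    tab <- incremental_table(inst)
    surv <- tab$strategy[tab$dominance %in% c("reference", "frontier")]
    expect_identical(surv, frontier_oracle(inst), label = paste("instance", i))
  }
  expect_identical(frontier_oracle(tibble::tibble(strategy = "x", cost = 5,
                                                  qaly = 0.2)), "x")
})

test_that("PSA sampling is moment-faithful and respects supports", {
  cfg <- default_config()
  # fixed-only config passes through identically
  fx <- all_fixed_config()
  expect_identical(config_digest(suppressWarnings(sample_psa_config(fx, 5))),
                   config_digest(fx))

  draws <- vapply(1:2000, function(i) {
    suppressWarnings(sample_psa_config(cfg, i))$tests$ct$sensitivity
  }, numeric(1))
  expect_lt(abs(mean(draws) - 0.83), 0.015)
  inside <- mean(draws >= 0.68 & draws <= 0.98)
  expect_gt(inside, 0.90) # range was read as a 95% interval
  expect_lt(inside, 0.99)
  expect_true(all(draws >= 0 & draws <= 1))

  more <- lapply(1:300, function(i) suppressWarnings(sample_psa_config(cfg, i)))
  expect_true(all(vapply(more, function(x) x$costs$colonoscopy, 1) > 0))
  expect_true(all(vapply(more, function(x) {
    x$clinical$mean_months_undetected_to_symptomatic
  }, 1) >= 1))
  # infeasible beta mean on the boundary stays fixed
  expect_true(all(vapply(more, function(x) x$tests$colonoscopy$specificity,
                         1) == 1))
  # utilities excluded from resampling
  expect_true(all(vapply(more, function(x) x$utilities$ned, 1) == 0.78))
})

test_that("a point-mass PSA reproduces the base case exactly", {
  fx <- all_fixed_config()
  draws <- suppressWarnings(
    run_psa(fx, n_draws = 2, n_patients = 400, seed = 77,
            strategies = c("q12", "q6")))
  base <- run_strategies(fx, c("q12", "q6"), n_patients = 400,
                         seed = metasurv:::derive_seed(77, 0, 2))
  expect_identical(draws$cost[draws$draw == 1],
                   base$mean_cost)
  expect_identical(draws$qaly[draws$draw == 1], base$mean_qaly)
  # point-mass parameters and shared patients: draws collapse completely
  expect_identical(draws$cost[draws$draw == 1],
                   draws$cost[draws$draw == 2])
})

test_that("acceptability curves are proper probabilities", {
  set.seed(600)
  draws <- tibble::tibble(
    draw = rep(1:40, each = 3),
    strategy = rep(c("a", "b", "c"), 40),
    cost = runif(120, 5000, 20000),
    qaly = runif(120, 3, 5))
  cc <- ceac(draws, c(0, 50000, 200000))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  # invariant to row order
  cc2 <- ceac(draws[sample(nrow(draws)), ], c(0, 50000, 200000))
  expect_equal(dplyr::arrange(cc, wtp, strategy),
               dplyr::arrange(cc2, wtp, strategy))
  # single strategy is always cost-effective
  solo <- ceac(draws[draws$strategy == "a", ], c(0, 50000))
  expect_equal(solo$probability, c(1, 1))
})

test_that("NMB choice matches the frontier segment bracketing the threshold", {
  res <- tibble::tibble(strategy = c("a", "b", "c"),
                        cost = c(0, 100, 300), qaly = c(0, 0.01, 0.015))
  tab <- incremental_table(res) # ICERs: b 10000, c 40000
  for (l in c(5000, 20000, 39999, 40001, 90000)) {
    nmb <- l * res$qaly - res$cost
    nmb_best <- res$strategy[which.max(nmb)]
    surv <- tab[tab$dominance %in% c("reference", "frontier"), ]
    icers <- c(-Inf, surv$frontier_icer[-1], Inf)
    seg <- max(which(icers[-length(icers)] <= l))
    expect_identical(nmb_best, surv$strategy[seg], label = paste("wtp", l))
  }
})

test_that("one-way DSA at the base value reproduces the base case", {
  cfg <- default_config()
  d <- one_way_dsa(cfg, "clinical.mean_months_undetected_to_symptomatic",
                   values = 4, n_patients = 800, seed = 55)
  base <- incremental_table(run_strategies(cfg, n_patients = 800, seed = 55))
  expect_equal(d$cost, base$cost)
  expect_equal(d$effect, base$effect)
  expect_equal(d$dominance, base$dominance)
  expect_error(one_way_dsa(cfg, "clinical.nope", 1, n_patients = 10, seed = 1),
               "Unknown parameter path")
})

test_that("two-way DSA grids are total and collapse to the base preference", {
  cfg <- default_config()
  g <- two_way_dsa(cfg,
                   "clinical.mean_months_undetected_to_symptomatic", 4,
                   "clinical.asymptomatic_metastasectomy_rate", 0.23,
                   n_patients = 800, seed = 55)
  expect_equal(nrow(g), 1)
  res <- run_strategies(cfg, n_patients = 800, seed = 55)
  expect_identical(g$preferred_strategy,
                   res$strategy[which.max(50000 * res$mean_qaly - res$mean_cost)])
  g2 <- two_way_dsa(cfg,
                    "clinical.mean_months_undetected_to_symptomatic", c(2, 6),
                    "clinical.asymptomatic_metastasectomy_rate", c(0.18, 0.28),
                    n_patients = 300, seed = 55)
  expect_equal(nrow(g2), 4)
  expect_true(all(g2$preferred_strategy %in% strategy_codes(TRUE)))
})
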