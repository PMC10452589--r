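# Incremental cost-effectiveness analysis: dominance-annotated ICER tables,
# the efficiency frontier, probabilistic sensitivity analysis with
# gamma/beta-resampled inputs, cost-effectiveness acceptability curves, and
# deterministic (one-way / two-way) sensitivity analyses.

resolve_effect_col <- function(results, effect) {
  cand <- c(effect, paste0("mean_", effect), "effect")
  hit <- cand[cand %in% names(results)][1]
  if (is.na(hit)) {
    abort(sprintf("No effect column for '%s' in results (have: %s).",
                  effect, paste(names(results), collapse = ", ")))
  }
  hit
}

resolve_cost_col <- function(results) {
  hit <- c("cost", "mean_cost")[c("cost", "mean_cost") %in% names(results)][1]
  if (is.na(hit)) abort("Results need a 'cost' or 'mean_cost' column.")
  hit
}

#' Incremental cost-effectiveness table
#'
#' Ranks strategies by ascending cost and annotates dominance: a strategy is
#' *absolutely dominated* when another costs no more and yields at least as
#' much effect (one inequality strict); among the remainder, ICERs against the
#' previous surviving row are computed and any strategy whose ICER exceeds
#' that of the next surviving strategy is removed as *extended dominated*,
#' iterating until the frontier ICERs increase. Equal consecutive ICERs
#' (collinear strategies) are retained.
#'
#' Two ICER conventions are reported: `icer` is computed against the adjacent
#' table row regardless of dominance (the convention of published strategy
#' tables), and `frontier_icer` against the previous surviving strategy (the
#' decision-relevant convention; `NA` off the frontier).
#'
#' @param results Tibble with a strategy column plus `cost`/`mean_cost` and an
#'   effect column (`qaly`, `ly`, `mean_qaly`, `mean_ly`, or `effect`), e.g.
#'   the output of [run_strategies()].
#' @param effect Which effect measure to rank on: `"qaly"` (default) or
#'   `"ly"`.
#' @return Tibble sorted by cost with `delta_cost`, `delta_effect`, `icer`,
#'   `frontier_icer` and a `dominance` tag (`reference`, `frontier`,
#'   `absolutely_dominated`, `extended_dominated`).
#' @export
#' @examples
#' res <- tibble::tibble(
#'   strategy = c("a", "b", "c"),
#'   cost = c(1000, 2000, 4000), qaly = c(1.0, 1.2, 1.5))
#' incremental_table(res)
incremental_table <- function(results, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  if (anyDuplicated(results$strategy)) {
    abort("Duplicate strategy codes in results.")
  }
  tbl <- tibble::tibble(
    strategy = results$strategy,
    cost = results[[resolve_cost_col(results)]],
    effect = results[[resolve_effect_col(results, effect)]]
  )
  tbl <- tbl[order(tbl$cost, tbl$effect, tbl$strategy), ]
  n <- nrow(tbl)
  dominance <- rep("frontier", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    if (any(tbl$cost[others] <= tbl$cost[i] & tbl$effect[others] >= tbl$effect[i] &
            (tbl$cost[others] < tbl$cost[i] | tbl$effect[others] > tbl$effect[i]))) {
      dominance[i] <- "absolutely_dominated"
    }
  }
  # Extended dominance: drop survivors whose ICER strictly exceeds the next
  # survivor's, until the frontier ICERs are non-decreasing.
  surv <- which(dominance != "absolutely_dominated")
  repeat {
    if (length(surv) < 3) break
    icer <- diff(tbl$cost[surv]) / diff(tbl$effect[surv])
    drop_at <- which(utils::head(icer, -1) > utils::tail(icer, -1))
    if (length(drop_at) == 0) break
    dominance[surv[drop_at[1] + 1]] <- "extended_dominated"
    surv <- surv[-(drop_at[1] + 1)]
  }
  if (length(surv) > 0) dominance[surv[1]] <- "reference"
  delta_cost <- c(NA_real_, diff(tbl$cost))
  delta_effect <- c(NA_real_, diff(tbl$effect))
  icer_adj <- ifelse(!is.na(delta_effect) & delta_effect > 0,
                     delta_cost / delta_effect, NA_real_)
  frontier_icer <- rep(NA_real_, n)
  if (length(surv) > 1) {
    frontier_icer[surv[-1]] <- diff(tbl$cost[surv]) / diff(tbl$effect[surv])
  }
  out <- tibble::tibble(
    strategy = tbl$strategy, cost = tbl$cost, effect = tbl$effect,
    delta_cost = delta_cost, delta_effect = delta_effect, icer = icer_adj,
    frontier_icer = frontier_icer, dominance = dominance
  )
  attr(out, "effect") <- effect
  out
}

#' Frontier survivors (independent oracle)
#'
#' Brute-force computation of the efficiency frontier: a strategy survives if
#' some non-negative willingness-to-pay makes its net monetary benefit
#' maximal. Candidate thresholds are all pairwise indifference slopes, so the
#' search is exhaustive. Used as an independent check of
#' [incremental_table()]'s elimination loop.
#'
#' @inheritParams incremental_table
#' @return Character vector of surviving strategy codes, by ascending cost.
#' @export
frontier_oracle <- function(results, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  cost <- results[[resolve_cost_col(results)]]
  eff <- results[[resolve_effect_col(results, effect)]]
  strategy <- results$strategy
  n <- length(cost)
  if (n == 1) return(strategy)
  lambdas <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (eff[i] != eff[j]) {
        l <- (cost[i] - cost[j]) / (eff[i] - eff[j])
        if (is.finite(l) && l >= 0) lambdas <- c(lambdas, l)
      }
    }
  }
  lo <- if (length(lambdas) > 0) min(lambdas[lambdas > 0], Inf) else Inf
  lambdas <- c(if (is.finite(lo)) lo / 2 else 1, lambdas,
               if (length(lambdas) > 0) 2 * max(lambdas) + 1 else 1)
  surv <- rep(FALSE, n)
  for (l in unique(lambdas)) {
    nmb <- l * eff - cost
    surv <- surv | (nmb >= max(nmb) - 1e-9 * (1 + abs(max(nmb))))
  }
  strategy[surv][order(cost[surv])]
}

#' Draw one parameter set for the probabilistic sensitivity analysis
#'
#' Resamples every non-fixed parameter from its assigned family:
#' gamma-distributed parameters by moment matching (`shape = (mean/sd)^2`),
#' beta-distributed probabilities by matching mean and variance. Published
#' ranges were converted to standard deviations as 95% intervals when the
#' configuration was built. Infeasible beta moments (mean on the boundary, or
#' variance exceeding `mean(1-mean)`) are clamped or held fixed with a
#' once-per-session warning. The sampled time-to-symptomatic interval is
#' floored at 1 month. Uncertainty ranges in the returned config are widened
#' to cover the draws, so the sampled config revalidates.
#'
#' @param config A `metasurv_config` whose `psa` block assigns families.
#' @param seed Integer seed for this draw.
#' @return A new validated `metasurv_config`.
#' @export
sample_psa_config <- function(config, seed) {
  set.seed(seed)
  out <- config
  for (path in sort(names(config$psa))) {
    d <- config$psa[[path]]
    if (d$family == "fixed") next
    value <- if (d$family == "gamma") {
      shape <- (d$mean / d$sd)^2
      rgamma(1, shape = shape, rate = d$mean / d$sd^2)
    } else { # beta
      if (d$mean <= 0 || d$mean >= 1) {
        warn(sprintf(paste("PSA: beta family for '%s' infeasible (mean %.3f",
                           "on the boundary); parameter held fixed."),
                     path, d$mean),
             .frequency = "once", .frequency_id = paste0("psa-fixed-", path))
        next
      }
      s <- d$sd
      smax <- sqrt(d$mean * (1 - d$mean))
      if (s >= smax) {
        warn(sprintf(paste("PSA: beta SD for '%s' (%.4f) exceeds the feasible",
                           "maximum %.4f; clamped."), path, s, smax),
             .frequency = "once", .frequency_id = paste0("psa-clamp-", path))
        s <- 0.95 * smax
      }
      v <- d$mean * (1 - d$mean) / s^2 - 1
      rbeta(1, shape1 = d$mean * v, shape2 = (1 - d$mean) * v)
    }
    if (path == "clinical.mean_months_undetected_to_symptomatic") {
      value <- max(1, value)
    }
    keys <- strsplit(path, ".", fixed = TRUE)[[1]]
    out[[keys]] <- value
    rng_key <- c(utils::head(keys, -1),
                 paste0(keys[length(keys)], "_range"))
    if (!is.null(out[[rng_key]])) {
      out[[rng_key]] <- range(c(out[[rng_key]], value))
    }
  }
  validate_config(out)
}

#' Probabilistic sensitivity analysis
#'
#' Jointly resamples all uncertain inputs per draw, recalibrates the
#' transition probabilities, and re-runs the micro-simulation for every
#' strategy. Within a draw all strategies share one simulation seed (common
#' random numbers), and each draw gets its own deterministic sub-seed, so the
#' whole analysis reproduces exactly from `seed`.
#'
#' @param config A `metasurv_config`.
#' @param n_draws Number of parameter draws.
#' @param n_patients Simulated patients per draw and strategy.
#' @param seed Master seed.
#' @param strategies Strategy codes to compare.
#' @param keep_configs If `TRUE`, attach the sampled configs as attribute
#'   `"configs"`.
#' @return Tibble with one row per draw and strategy: `draw`, `strategy`,
#'   `cost`, `qaly`, `ly` (discounted means over the draw's patients).
#' @export
run_psa <- function(config, n_draws = config$settings$n_psa_draws,
                    n_patients = config$settings$n_patients_per_psa_draw,
                    seed = config$settings$rng_seed,
                    strategies = strategy_codes(active_only = TRUE),
                    keep_configs = FALSE) {
  stopifnot(n_draws >= 1)
  strategies <- normalize_strategy(strategies)
  configs <- if (keep_configs) vector("list", n_draws) else NULL
  rows <- vector("list", n_draws)
  # One simulation seed for all draws: the same simulated patients are pushed
  # through every parameter draw (common random numbers across draws), so
  # draw-to-draw variation reflects parameter uncertainty, not Monte Carlo
  # noise, and a point-mass PSA reproduces the base case exactly.
  sim_seed <- derive_seed(seed, 0, 2)
  for (d in seq_len(n_draws)) {
    cfg_d <- sample_psa_config(config, derive_seed(seed, d, 1))
    tp_d <- calibrate(cfg_d)
    res <- dplyr::bind_rows(lapply(strategies, function(s) {
      r <- run_strategy(cfg_d, s, n_patients = n_patients, seed = sim_seed,
                        tp = tp_d)
      tibble::tibble(draw = d, strategy = s, cost = r$mean_cost,
                     qaly = r$mean_qaly, ly = r$mean_ly)
    }))
    rows[[d]] <- res
    if (keep_configs) configs[[d]] <- cfg_d
  }
  out <- dplyr::bind_rows(rows)
  if (keep_configs) attr(out, "configs") <- configs
  out
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the probability (fraction of PSA
#' draws) that each strategy has the maximal net monetary benefit
#' `wtp * QALY - cost`. Ties within a draw are split equally, so the
#' probabilities sum to one at every threshold.
#'
#' @param draws Output of [run_psa()].
#' @param wtp_grid Willingness-to-pay thresholds (CAD per QALY).
#' @return Tibble: `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(draws, wtp_grid) {
  stopifnot(nrow(draws) > 0, all(wtp_grid >= 0))
  purrr::map_dfr(wtp_grid, function(l) {
    draws |>
      dplyr::group_by(.data$draw) |>
      dplyr::mutate(nmb = l * .data$qaly - .data$cost,
                    win = .data$nmb >= max(.data$nmb) -
                      1e-9 * (1 + abs(max(.data$nmb))),
                    weight = .data$win / sum(.data$win)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$strategy) |>
      dplyr::summarise(probability = mean(.data$weight), .groups = "drop") |>
      dplyr::mutate(wtp = l, .before = 1)
  })
}

# Shared scenario runner for the deterministic sensitivity analyses: for each
# scenario config, recalibrate, simulate all strategies with the same seed,
# and report each strategy against the scenario's reference (the cheapest
# strategy on the frontier), Table-3 style, plus the full dominance tags.
run_dsa_scenarios <- function(configs, strategies, n_patients, seed) {
  purrr::imap_dfr(configs, function(cfg, scenario) {
    res <- run_strategies(cfg, strategies, n_patients = n_patients, seed = seed)
    inc <- incremental_table(res, effect = "qaly")
    ref <- inc$strategy[inc$dominance == "reference"][1]
    ref_cost <- inc$cost[inc$strategy == ref]
    ref_eff <- inc$effect[inc$strategy == ref]
    dplyr::mutate(
      inc,
      scenario = scenario, .before = 1,
      reference = ref,
      delta_cost_vs_ref = .data$cost - ref_cost,
      delta_qaly_vs_ref = .data$effect - ref_eff,
      icer_vs_ref = dplyr::if_else(
        .data$delta_qaly_vs_ref > 0,
        .data$delta_cost_vs_ref / .data$delta_qaly_vs_ref, NA_real_),
      comparison = dplyr::case_when(
        .data$strategy == ref ~ "reference",
        .data$delta_qaly_vs_ref <= 0 & .data$delta_cost_vs_ref >= 0 ~ "dominated",
        TRUE ~ "icer")
    )
  })
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the base-case comparison with one parameter set to each supplied
#' value (recalibrating where needed), under a fixed seed so scenarios differ
#' only through the parameter. Each scenario reports the dominance-annotated
#' incremental table plus every strategy's ICER against the scenario's
#' reference (cheapest frontier) strategy.
#'
#' @param config A `metasurv_config`.
#' @param parameter Dot-separated parameter path, see
#'   [config_parameter_paths()].
#' @param values Values to scan.
#' @param strategies Strategy codes to compare.
#' @param n_patients Simulated patients per scenario and strategy.
#' @param seed Simulation seed shared across scenarios.
#' @return Long tibble: one row per scenario and strategy.
#' @export
#' @examples
#' \donttest{
#' one_way_dsa(default_config(),
#'             "clinical.mean_months_undetected_to_symptomatic",
#'             values = c(1, 28), n_patients = 500, seed = 1)
#' }
one_way_dsa <- function(config, parameter, values,
                        strategies = strategy_codes(active_only = TRUE),
                        n_patients = 2000, seed = config$settings$rng_seed) {
  configs <- lapply(values, function(v) set_config_value(config, parameter, v))
  names(configs) <- sprintf("%s=%g", parameter, values)
  out <- run_dsa_scenarios(configs, strategies, n_patients, seed)
  out$parameter <- parameter
  out$value <- rep(values, each = length(strategies))
  out
}

#' Resection-rate sensitivity scenarios
#'
#' Varies the asymptomatic and symptomatic repeat-resection probabilities by
#' a relative amount in opposite directions, approximating the maximum and
#' minimum plausible difference between the two observed rates.
#'
#' @param config A `metasurv_config`.
#' @param rel_change Relative variation (default 0.25).
#' @inheritParams one_way_dsa
#' @return Long tibble as in [one_way_dsa()], with scenarios
#'   `difference_decreased` (asymptomatic down, symptomatic up) and
#'   `difference_increased` (the reverse).
#' @export
resection_rate_dsa <- function(config, rel_change = 0.25,
                               strategies = strategy_codes(active_only = TRUE),
                               n_patients = 2000,
                               seed = config$settings$rng_seed) {
  a <- config$clinical$asymptomatic_metastasectomy_rate
  s <- config$clinical$symptomatic_metastasectomy_rate
  mk <- function(fa, fs) {
    cfg <- set_config_value(config, "clinical.asymptomatic_metastasectomy_rate",
                            min(1, a * fa))
    set_config_value(cfg, "clinical.symptomatic_metastasectomy_rate",
                     min(1, s * fs))
  }
  configs <- list(difference_decreased = mk(1 - rel_change, 1 + rel_change),
                  difference_increased = mk(1 + rel_change, 1 - rel_change))
  run_dsa_scenarios(configs, strategies, n_patients, seed)
}

#' Two-way deterministic sensitivity analysis
#'
#' Evaluates every combination of two parameter value grids and reports the
#' strategy with maximal net monetary benefit at the given willingness-to-pay
#' threshold in each cell.
#'
#' @inheritParams one_way_dsa
#' @param parameter_a,parameter_b Parameter paths.
#' @param values_a,values_b Value grids.
#' @param wtp Willingness-to-pay threshold (CAD/QALY, default 50,000).
#' @return Tibble: `value_a`, `value_b`, `preferred_strategy`, `nmb`.
#' @export
two_way_dsa <- function(config, parameter_a, values_a, parameter_b, values_b,
                        wtp = 50000,
                        strategies = strategy_codes(active_only = TRUE),
                        n_patients = 2000, seed = config$settings$rng_seed) {
  grid <- expand.grid(value_a = values_a, value_b = values_b,
                      KEEP.OUT.ATTRS = FALSE)
  purrr::pmap_dfr(grid, function(value_a, value_b) {
    cfg <- set_config_value(config, parameter_a, value_a)
    cfg <- set_config_value(cfg, parameter_b, value_b)
    res <- run_strategies(cfg, strategies, n_patients = n_patients, seed = seed)
    nmb <- wtp * res$mean_qaly - res$mean_cost
    best <- which.max(nmb)
    tibble::tibble(value_a = value_a, value_b = value_b,
                   preferred_strategy = res$strategy[best], nmb = nmb[best])
  })
}
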