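# Convenience plots (ggplot2 is Suggests-only; these are not part of the
# analysis surface).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("Plotting requires the 'ggplot2' package.")
  }
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param curves Output of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curves) {
  need_ggplot()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(labels = function(x) x / 1000) +
    ggplot2::labs(x = "Willingness to pay (thousand CAD / QALY)",
                  y = "Probability cost-effective", colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot the incremental cost-effectiveness plane
#'
#' Draw-level incremental cost and effect of each strategy against a
#' reference strategy, with the willingness-to-pay threshold as a diagonal.
#'
#' @param draws Output of [run_psa()].
#' @param reference Reference strategy code.
#' @param wtp Threshold drawn as a diagonal (CAD/QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, reference = "q6_q12", wtp = 50000) {
  need_ggplot()
  reference <- normalize_strategy(reference)
  ref <- draws[draws$strategy == reference, c("draw", "cost", "qaly")]
  names(ref) <- c("draw", "ref_cost", "ref_qaly")
  d <- dplyr::inner_join(draws[draws$strategy != reference, ], ref, by = "draw")
  d$dcost <- d$cost - d$ref_cost
  d$dqaly <- d$qaly - d$ref_qaly
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dqaly, y = .data$dcost,
                                  colour = .data$strategy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = sprintf("Incremental QALYs vs %s", reference),
                  y = sprintf("Incremental cost (CAD) vs %s", reference),
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}
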