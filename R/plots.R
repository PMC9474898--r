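#' Plot the EMT score distribution
#'
#' Histogram of per-sample scores, filled by EMT class when present.
#'
#' @param scores An `emt_scores` tibble, optionally with `emt_class`.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, bins = 40) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$score))
  if ("emt_class" %in% names(scores)) {
    p <- p + ggplot2::geom_histogram(ggplot2::aes(fill = .data$emt_class),
                                     bins = bins)
  } else {
    p <- p + ggplot2::geom_histogram(bins = bins)
  }
  p + ggplot2::labs(x = "EMT score", y = "samples", fill = "EMT class") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step curves
#'
#' @param object An `emt_km` fit.
#' @param ... Unused.
#' @return A ggplot object with one step curve per group.
#' @export
autoplot.emt_km <- function(object, ...) {
  curves <- object$curves |>
    group_by(.data$label) |>
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L,
             n_censor = 0L, surv = 1),
      .x
    )) |>
    ungroup()
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$label)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of Cox hazard ratios
#'
#' @param object An `emt_cox` fit.
#' @param ... Unused.
#' @return A ggplot object (log-scaled hazard ratios with 95% CIs).
#' @export
autoplot.emt_cox <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$hazard_ratio, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a feature-correlation screen
#'
#' @param hits Result of [correlate_features()].
#' @param config An [emt_config()] supplying the rho cut to draw.
#' @return A ggplot object.
#' @export
plot_correlation_hits <- function(hits, config = emt_config()) {
  ggplot2::ggplot(hits,
                  ggplot2::aes(x = .data$rho,
                               y = -log10(pmax(.data$p.adjusted, 1e-300)),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * config$protein_rho_cut,
                        linetype = "dashed") +
    ggplot2::labs(x = "Spearman rho with EMT score",
                  y = "-log10 adjusted p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Bar chart of retained drug associations
#'
#' @param screen An `emt_drug_screen` result.
#' @return A ggplot object of rho per retained drug, coloured by sign group.
#' @export
plot_drug_screen <- function(screen) {
  kept <- screen$associations[screen$associations$retained, , drop = FALSE]
  ggplot2::ggplot(kept,
                  ggplot2::aes(x = stats::reorder(.data$drug, .data$rho),
                               y = .data$rho, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Spearman rho with EMT score", fill = NULL) +
    ggplot2::theme_minimal()
}
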