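#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot predicted versus observed inbred relative hatching
#'
#' One point per population: the inbred relative hatching predicted from
#' the estimated haploid load (`exp(-B/4)`, with the interval implied by
#' the bootstrap interval of B) against the observed value. Points on the
#' dashed identity line are populations whose inbred hatching is fully
#' explained by the load inferred from parthenogenesis; points well above
#' it indicate that parthenogenetic failure exceeds what inbreeding
#' depression alone predicts.
#'
#' @param object A `load_inference` object from [run_load_inference()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot load_inference
#' @export
autoplot.load_inference <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$b_hat) & !is.na(d$observed_inbred_rel), ]
  d$pred_low <- predict_inbred_relative_hatching(d$conf_high)
  d$pred_high <- predict_inbred_relative_hatching(d$conf_low)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted_inbred_rel,
                                  y = .data$observed_inbred_rel,
                                  colour = .data$population)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$pred_low,
                                         xmax = .data$pred_high),
                            height = 0.02) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1.05), ylim = c(0, 1.05)) +
    ggplot2::labs(
      x = "Predicted inbred relative hatching, exp(-B/4)",
      y = "Observed inbred relative hatching",
      colour = "Population",
      title = "Inbreeding depression predicted from parthenogenetic load"
    ) +
    ggplot2::theme_minimal()
}

#' Plot hatching rates by population and treatment
#'
#' Pooled hatching rate (total hatched / total eggs) per population and
#' treatment, with pods overplotted as jittered per-pod rates.
#'
#' @param pods Pod table (see [simulate_experiment()]).
#' @return A ggplot object.
#' @export
plot_hatching_rates <- function(pods) {
  check_pod_table(pods)
  pooled <- pods |>
    dplyr::group_by(.data$population, .data$treatment) |>
    dplyr::summarise(rate = sum(.data$n_hatched) / sum(.data$n_eggs),
                     .groups = "drop")
  per_pod <- dplyr::filter(pods, .data$n_eggs > 0) |>
    dplyr::mutate(rate = .data$n_hatched / .data$n_eggs)
  ggplot2::ggplot(pooled,
                  ggplot2::aes(x = factor(.data$treatment,
                                          levels = treatment_levels()),
                               y = .data$rate)) +
    ggplot2::geom_jitter(data = per_pod, width = 0.15, alpha = 0.3,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 3, shape = 18) +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "Reproduction treatment", y = "Hatching rate",
                  title = "Hatching by treatment (diamonds: pooled rate)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
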