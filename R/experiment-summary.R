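#' Per-treatment summaries of a breeding experiment
#'
#' Aggregates pod (and optionally offspring and female) tables into one row
#' per population x treatment: laying proportion, pooled egg and hatchling
#' counts, pooled hatching and 24-h survival rates, hatching relative to the
#' population's outbred pods, and the inbreeding-depression coefficient
#' `delta = 1 - w_treatment / w_outbred` for hatching. Pooled rates are
#' ratios of total counts (egg-weighted); `weighting = "per_female"`
#' averages per-female rates instead, for designs where females rather than
#' eggs are the unit of interest.
#'
#' @param pods Pod table (see [simulate_experiment()]).
#' @param offspring Optional offspring table; adds larval survival to adult
#'   molt, mean development time and mean femur length per group.
#' @param females Optional female table (one row per isolated female with a
#'   logical `laid`); required for `laying_proportion`, otherwise `NA`.
#' @param weighting `"pooled"` (egg-weighted ratios of summed counts,
#'   default) or `"per_female"` (unweighted mean of per-female rates).
#' @return A tibble with one row per population x treatment. Quantities
#'   that cannot be computed (e.g. relative hatching without outbred eggs)
#'   are `NA`, never `NaN`.
#' @examples
#' sim <- simulate_experiment(example_sim_configs(), seed = 1)
#' summarize_treatments(sim$pods, sim$offspring, sim$females)
#' @export
summarize_treatments <- function(pods, offspring = NULL, females = NULL,
                                 weighting = c("pooled", "per_female")) {
  weighting <- match.arg(weighting)
  check_pod_table(pods)
  if (nrow(pods) == 0) stop("pod table is empty", call. = FALSE)

  base <- pods |>
    dplyr::group_by(.data$population, .data$treatment) |>
    dplyr::summarise(
      n_females_laying = dplyr::n_distinct(.data$female_id),
      n_pods = dplyr::n(),
      total_eggs = sum(.data$n_eggs),
      total_hatched = sum(.data$n_hatched),
      total_survived_24h = sum(.data$n_survived_24h),
      hatch_rate = pooled_rate(.data$n_eggs, .data$n_hatched,
                               .data$female_id, weighting),
      survival_24h_rate = if (sum(.data$n_hatched) > 0)
        sum(.data$n_survived_24h) / sum(.data$n_hatched) else NA_real_,
      .groups = "drop"
    )

  if (!is.null(females)) {
    lay <- females |>
      dplyr::group_by(.data$population, .data$treatment) |>
      dplyr::summarise(n_females = dplyr::n(),
                       laying_proportion = mean(.data$laid),
                       .groups = "drop")
    base <- dplyr::left_join(base, lay, by = c("population", "treatment"))
  } else {
    base$n_females <- NA_integer_
    base$laying_proportion <- NA_real_
  }

  out_rate <- base |>
    dplyr::filter(.data$treatment == "outbred", .data$total_eggs > 0) |>
    dplyr::select("population", outbred_hatch = "hatch_rate")
  base <- base |>
    dplyr::left_join(out_rate, by = "population") |>
    dplyr::mutate(
      relative_hatching = dplyr::if_else(
        !is.na(.data$outbred_hatch) & .data$outbred_hatch > 0,
        .data$hatch_rate / .data$outbred_hatch, NA_real_),
      delta_hatch = 1 - .data$relative_hatching
    ) |>
    dplyr::select(-"outbred_hatch")

  if (!is.null(offspring) && nrow(offspring) > 0) {
    tr <- offspring |>
      dplyr::group_by(.data$population, .data$treatment) |>
      dplyr::summarise(
        n_offspring = dplyr::n(),
        larval_survival = mean(.data$event == "molted"),
        mean_development_time = mean(.data$development_time, na.rm = TRUE),
        mean_femur_length = mean(.data$femur_length, na.rm = TRUE),
        .groups = "drop"
      )
    base <- dplyr::left_join(base, tr, by = c("population", "treatment"))
  }
  dplyr::arrange(base, .data$population,
                 match(.data$treatment, treatment_levels()))
}

#' End-to-end lethal-equivalents inference per population
#'
#' For every population in the pod table: estimates the haploid load B from
#' the hatching of parthenogenetic pods relative to outbred pods (fully
#' homozygous offspring, F = 1), attaches a pod-resampling bootstrap
#' interval, predicts the relative hatching of full-sib inbred offspring
#' `exp(-B/4)`, and compares it with the observed inbred relative hatching
#' when inbred pods exist. The `discrepant` flag marks populations whose
#' observed inbred relative hatching falls outside the interval implied by
#' mapping the bootstrap interval of B through `exp(-B/4)` -- the pattern
#' expected when parthenogenetic failure is driven by more than inbreeding
#' depression (e.g. developmental constraints of automixis).
#'
#' Populations without parthenogenetic eggs are reported with `NA` estimates
#' and an explanatory `note`; populations whose parthenogenetic eggs all
#' failed get `b_hat = Inf` and a predicted inbred relative hatching of 0.
#'
#' @inheritParams summarize_treatments
#' @param n_boot Bootstrap replicates for the confidence interval.
#' @param seed Integer seed (bootstrap resampling).
#' @return A `load_inference` tibble, one row per population: `b_hat`,
#'   `conf_low`, `conf_high`, `rel_hatching_parthenogenetic`,
#'   `predicted_inbred_rel`, `observed_inbred_rel`, `discrepant`, `note`.
#'   [tidy()], [glance()] and [ggplot2::autoplot()] methods are available.
#' @examples
#' sim <- simulate_experiment(example_sim_configs(), seed = 1)
#' run_load_inference(sim$pods, n_boot = 200, seed = 1)
#' @export
run_load_inference <- function(pods, n_boot = 1000, seed = 1,
                               weighting = c("pooled", "per_female")) {
  weighting <- match.arg(weighting)
  check_pod_table(pods)
  res <- purrr::map_dfr(unique(pods$population), function(pop) {
    sub <- pods[pods$population == pop, ]
    out <- sub[sub$treatment == "outbred" & sub$n_eggs > 0, ]
    par <- sub[sub$treatment == "parthenogenetic" & sub$n_eggs > 0, ]
    inb <- sub[sub$treatment == "inbred_fullsib" & sub$n_eggs > 0, ]
    row <- tibble::tibble(
      population = pop, b_hat = NA_real_, conf_low = NA_real_,
      conf_high = NA_real_, rel_hatching_parthenogenetic = NA_real_,
      predicted_inbred_rel = NA_real_, observed_inbred_rel = NA_real_,
      discrepant = NA, note = NA_character_
    )
    out_rate <- if (nrow(out)) pooled_rate(out$n_eggs, out$n_hatched,
                                           out$female_id, weighting) else NA
    if (nrow(inb) && !is.na(out_rate) && out_rate > 0) {
      row$observed_inbred_rel <-
        pooled_rate(inb$n_eggs, inb$n_hatched, inb$female_id, weighting) /
        out_rate
    }
    if (nrow(out) == 0 || is.na(out_rate) || out_rate == 0) {
      row$note <- "no outbred hatching data; load not estimable"
      return(row)
    }
    if (nrow(par) == 0) {
      row$note <- "no parthenogenetic pods with eggs; load not estimable"
      return(row)
    }
    ci <- bootstrap_load_ci(sub, n_boot = n_boot, seed = seed, f = 1)
    row$b_hat <- ci$b_hat
    row$conf_low <- ci$conf_low
    row$conf_high <- ci$conf_high
    row$rel_hatching_parthenogenetic <- ci$rel_hatching
    row$predicted_inbred_rel <- predict_inbred_relative_hatching(ci$b_hat)
    if (ci$rel_hatching == 0) {
      row$note <- "no parthenogenetic egg hatched; load is unbounded"
    }
    if (!is.na(row$observed_inbred_rel)) {
      pred_low <- predict_inbred_relative_hatching(ci$conf_high)
      pred_high <- predict_inbred_relative_hatching(ci$conf_low)
      row$discrepant <- row$observed_inbred_rel < pred_low |
        row$observed_inbred_rel > pred_high
    }
    row
  })
  structure(res,
            class = c("load_inference", class(res)),
            n_boot = n_boot, seed = seed, weighting = weighting)
}

#' @rdname run_load_inference
#' @param x A `load_inference` object.
#' @param ... Unused.
#' @method tidy load_inference
#' @export
tidy.load_inference <- function(x, ...) {
  tibble::as_tibble(unclass_load_inference(x))
}

unclass_load_inference <- function(x) {
  attr(x, "n_boot") <- NULL; attr(x, "seed") <- NULL
  attr(x, "weighting") <- NULL
  class(x) <- setdiff(class(x), "load_inference")
  x
}

#' @rdname run_load_inference
#' @method glance load_inference
#' @export
glance.load_inference <- function(x, ...) {
  tibble::tibble(
    n_populations = nrow(x),
    n_estimated = sum(!is.na(x$b_hat)),
    n_boot = attr(x, "n_boot"),
    seed = attr(x, "seed"),
    weighting = attr(x, "weighting")
  )
}

#' Text report of a load inference
#'
#' Renders the per-population lethal-equivalents estimates and the
#' predicted-versus-observed comparison of inbred relative hatching as
#' lines of text, percentages rounded to the nearest integer (full
#' precision is retained in the underlying table). Unbounded loads are
#' written as `inf`.
#'
#' @param x A `load_inference` object from [run_load_inference()].
#' @return Character vector of report lines, invisibly printed.
#' @export
report_load_inference <- function(x) {
  stopifnot(inherits(x, "load_inference"))
  fmt_b <- function(b) ifelse(is.infinite(b), "inf", sprintf("%.1f", b))
  fmt_pct <- function(p) ifelse(is.na(p), "NA", sprintf("%d%%", round(100 * p)))
  lines <- c("Lethal-equivalents inference (haploid load B; F = 1 parthenogenetic, 1/4 full-sib)")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$b_hat[i])) {
      lines <- c(lines, sprintf("  %s: %s", x$population[i],
                                x$note[i] %||% "not estimable"))
    } else {
      lines <- c(lines, sprintf(
        "  %s: B = %s [%s, %s]; predicted inbred relative hatching %s; observed %s%s",
        x$population[i], fmt_b(x$b_hat[i]), fmt_b(x$conf_low[i]),
        fmt_b(x$conf_high[i]), fmt_pct(x$predicted_inbred_rel[i]),
        fmt_pct(x$observed_inbred_rel[i]),
        ifelse(isTRUE(x$discrepant[i]), " (outside predicted interval)", "")))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
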