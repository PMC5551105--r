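#' Reproduction treatments and offspring inbreeding coefficients
#'
#' The three reproduction treatments of the breeding design and the
#' inbreeding coefficient F of the offspring each produces: outbred matings
#' give F = 0, full-sib matings F = 1/4, and automictic parthenogenesis with
#' endomitotic ploidy restoration gives fully homozygous offspring, F = 1.
#'
#' @return A tibble with columns `treatment` and `f`.
#' @examples
#' treatment_inbreeding()
#' @export
treatment_inbreeding <- function() {
  tibble::tibble(
    treatment = c("outbred", "inbred_fullsib", "parthenogenetic"),
    f = c(0, 0.25, 1)
  )
}

#' @rdname treatment_inbreeding
#' @export
treatment_levels <- function() treatment_inbreeding()$treatment

treatment_f <- function(treatment) {
  map <- treatment_inbreeding()
  f <- map$f[match(treatment, map$treatment)]
  if (anyNA(f)) {
    bad <- unique(treatment[is.na(f)])
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         "; valid labels are: ", paste(map$treatment, collapse = ", "),
         call. = FALSE)
  }
  f
}

check_bf <- function(b, f) {
  if (any(is.na(b) & !is.nan(b)) || any(b < 0, na.rm = TRUE)) {
    stop("lethal-equivalents `b` must be >= 0 (Inf allowed)", call. = FALSE)
  }
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    stop("inbreeding coefficient `f` must lie in [0, 1]", call. = FALSE)
  }
  invisible(NULL)
}

#' Expected relative hatching under the Poisson lethal-equivalents model
#'
#' Assuming the number of recessive lethals per haploid genome is Poisson
#' with mean `b` (the number of lethal equivalents) and that each lethal is
#' exposed as a homozygote with probability equal to the offspring inbreeding
#' coefficient `f`, the probability that an egg expresses no lethal -- its
#' hatching rate relative to outbred eggs -- is `exp(-b * f)`.
#'
#' @param b Lethal equivalents per haploid genome (>= 0, `Inf` allowed).
#' @param f Offspring inbreeding coefficient in `[0, 1]`; see
#'   [treatment_inbreeding()].
#' @return Numeric vector of relative hatching rates in `[0, 1]`.
#' @examples
#' expected_relative_hatching(1.1, 0.25) # ~0.76
#' expected_relative_hatching(3.8, 1)
#' @seealso [estimate_lethal_equivalents()] for the inverse map.
#' @export
expected_relative_hatching <- function(b, f) {
  check_bf(b, f)
  out <- exp(-b * f)
  # exp(-Inf * 0) is NaN; F = 0 offspring express no load whatever b is
  out[f == 0] <- 1
  out[is.infinite(b) & f > 0] <- 0
  out
}

#' Estimate lethal equivalents from relative hatching
#'
#' Inverts the Poisson load model: given the hatching rate of offspring with
#' inbreeding coefficient `f` relative to outbred offspring, the haploid load
#' is `b = -log(rel) / f`. A relative rate of exactly 0 gives `b = Inf`
#' (at least one lethal in essentially every genome); sampling noise can push
#' observed ratios above 1, in which case `b` is clamped to 0 with a warning.
#'
#' @param rel Observed relative hatching (>= 0; values > 1 tolerated).
#' @param f Offspring inbreeding coefficient in `(0, 1]`. Load is not
#'   identifiable from non-inbred (`f = 0`) offspring.
#' @return Numeric vector of lethal-equivalents estimates, with attribute
#'   `clamped` marking entries where `rel >= 1` was clamped to `b = 0`.
#' @examples
#' estimate_lethal_equivalents(exp(-3.8), 1) # 3.8
#' estimate_lethal_equivalents(0.5, 0.25)
#' @export
estimate_lethal_equivalents <- function(rel, f) {
  if (any(rel < 0, na.rm = TRUE)) {
    stop("relative hatching `rel` must be >= 0", call. = FALSE)
  }
  if (any(f <= 0 | f > 1, na.rm = TRUE)) {
    stop("inbreeding coefficient `f` must lie in (0, 1]: ",
         "load is not identifiable from non-inbred offspring", call. = FALSE)
  }
  b <- -log(rel) / f
  clamped <- !is.na(rel) & rel >= 1 & rel != 1
  if (any(clamped)) {
    warning("observed relative hatching > 1 (sampling noise); ",
            "load estimate clamped to 0", call. = FALSE)
  }
  b[!is.na(rel) & rel >= 1] <- 0
  b[!is.na(rel) & rel == 0] <- Inf
  attr(b, "clamped") <- clamped
  b
}

#' Predicted relative hatching of full-sib inbred offspring
#'
#' Evaluates the load model at `f = 1/4`, the inbreeding coefficient of
#' full-sib offspring: `exp(-b / 4)`. This is the quantity compared against
#' the hatching of the inbred treatment measured relative to outbred pods.
#'
#' @inheritParams expected_relative_hatching
#' @return Numeric vector of predicted relative hatching rates.
#' @examples
#' predict_inbred_relative_hatching(c(1.1, 3.8, 3.9))
#' @export
predict_inbred_relative_hatching <- function(b) {
  expected_relative_hatching(b, f = 0.25)
}

# Pooled (egg-weighted) or per-female hatch rates for one treatment's pods.
pooled_rate <- function(n_eggs, n_hatched, female = NULL,
                        weighting = c("pooled", "per_female")) {
  weighting <- match.arg(weighting)
  if (weighting == "pooled" || is.null(female)) {
    total <- sum(n_eggs)
    if (total == 0) return(NA_real_)
    sum(n_hatched) / total
  } else {
    eggs <- tapply(n_eggs, female, sum)
    hatched <- tapply(n_hatched, female, sum)
    keep <- eggs > 0
    if (!any(keep)) return(NA_real_)
    mean(hatched[keep] / eggs[keep])
  }
}

check_pod_table <- function(pods) {
  required <- c("population", "family", "female_id", "treatment",
                "pod_rank", "n_eggs", "n_hatched", "n_survived_24h")
  missing <- setdiff(required, names(pods))
  if (length(missing) > 0) {
    stop("pod table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  treatment_f(unique(pods$treatment))
  bad <- with(pods, n_survived_24h > n_hatched | n_hatched > n_eggs |
                n_survived_24h < 0 | n_eggs < 0)
  if (any(bad, na.rm = TRUE)) {
    stop("pod table violates 0 <= n_survived_24h <= n_hatched <= n_eggs at row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  invisible(pods)
}

#' Bootstrap confidence interval for the lethal-equivalents estimate
#'
#' Estimates the haploid load of one population from the hatching of its
#' parthenogenetic pods relative to its outbred pods, and attaches a
#' percentile bootstrap interval obtained by resampling egg pods with
#' replacement within each treatment. Pods (not eggs) are the resampling
#' unit because they are the independent sampling units of the design.
#' Replicates in which no resampled outbred egg hatches leave the ratio
#' undefined; they are discarded and counted, and more than 50% discarded is
#' an error.
#'
#' @param pods Pod table for a single population (columns as in
#'   [simulate_experiment()]): at least `treatment`, `n_eggs`, `n_hatched`.
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the interval is reproducible for a fixed seed.
#' @param f Inbreeding coefficient of the non-outbred treatment being used
#'   for estimation (1 for parthenogenetic offspring, the default).
#' @param treatment Name of the inbred/parthenogenetic treatment whose
#'   relative hatching carries the load signal.
#' @return A one-row tibble: `b_hat`, `conf_low`, `conf_high` (2.5% and
#'   97.5% percentiles), `rel_hatching`, `n_boot`, `n_discarded`.
#' @examples
#' pods <- simulate_experiment(
#'   population_sim_config("demo", b = 2, n_families = 10),
#'   seed = 42
#' )$pods
#' bootstrap_load_ci(pods, n_boot = 200, seed = 1)
#' @export
bootstrap_load_ci <- function(pods, n_boot = 1000, seed = 1, f = 1,
                              treatment = "parthenogenetic") {
  check_pod_table(pods)
  if (length(unique(pods$population)) > 1) {
    stop("bootstrap_load_ci() expects pods from a single population; ",
         "use run_load_inference() for multi-population tables", call. = FALSE)
  }
  if (n_boot < 1) stop("`n_boot` must be >= 1", call. = FALSE)
  trt <- pods[pods$treatment == treatment & pods$n_eggs > 0, ]
  out <- pods[pods$treatment == "outbred" & pods$n_eggs > 0, ]
  if (nrow(trt) == 0 || nrow(out) == 0) {
    stop("need at least one pod with eggs in both the '", treatment,
         "' and 'outbred' treatments", call. = FALSE)
  }
  rel_obs <- (sum(trt$n_hatched) / sum(trt$n_eggs)) /
    (sum(out$n_hatched) / sum(out$n_eggs))
  b_hat <- suppressWarnings(estimate_lethal_equivalents(rel_obs, f))
  b_hat <- as.numeric(b_hat)

  boot <- withr::with_seed(seed, {
    idx_t <- matrix(sample.int(nrow(trt), nrow(trt) * n_boot, replace = TRUE),
                    ncol = n_boot)
    idx_o <- matrix(sample.int(nrow(out), nrow(out) * n_boot, replace = TRUE),
                    ncol = n_boot)
    eggs_t <- colSums(matrix(trt$n_eggs[idx_t], ncol = n_boot))
    hat_t <- colSums(matrix(trt$n_hatched[idx_t], ncol = n_boot))
    eggs_o <- colSums(matrix(out$n_eggs[idx_o], ncol = n_boot))
    hat_o <- colSums(matrix(out$n_hatched[idx_o], ncol = n_boot))
    list(rel = (hat_t / eggs_t) / (hat_o / eggs_o), bad = hat_o == 0)
  })
  n_discarded <- sum(boot$bad)
  if (n_discarded > n_boot / 2) {
    stop("more than 50% of bootstrap replicates had zero outbred hatchlings (",
         n_discarded, "/", n_boot, ")", call. = FALSE)
  }
  rel_b <- boot$rel[!boot$bad]
  b_b <- suppressWarnings(estimate_lethal_equivalents(rel_b, f))
  qs <- stats::quantile(as.numeric(b_b), c(0.025, 0.975), names = FALSE,
                        type = 7)
  tibble::tibble(
    b_hat = b_hat, conf_low = qs[1], conf_high = qs[2],
    rel_hatching = rel_obs, n_boot = n_boot, n_discarded = n_discarded
  )
}
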