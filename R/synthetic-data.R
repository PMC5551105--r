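#' Configure one simulated population for the breeding experiment
#'
#' Bundles the parameters of the generative model for a single population of
#' the three-treatment breeding design: females are isolated per family and
#' assigned to outbred, full-sib inbred or parthenogenetic reproduction; a
#' female lays with a treatment-specific probability; laying females produce
#' `pods_per_female` egg pods whose egg numbers decline with pod rank; each
#' egg hatches if a baseline viability Bernoulli succeeds and no recessive
#' lethal is expressed (lethals drawn per egg as Poisson(`b`), each exposed
#' with probability equal to the treatment's inbreeding coefficient); each
#' hatchling survives its first 24 h with a treatment-specific probability.
#' Surviving hatchlings (up to `offspring_cap` per pod) from the outbred and
#' inbred treatments are followed individually for larval survival,
#' development time and adult femur length.
#'
#' @param name Population label.
#' @param b Lethal equivalents per haploid genome (>= 0, `Inf` allowed).
#' @param baseline_hatch Outbred hatching probability in `[0, 1]`.
#' @param laying_prob Named vector of laying probabilities per treatment
#'   (names `outbred`, `inbred_fullsib`, `parthenogenetic`).
#' @param n_families Number of full-sib families.
#' @param females_per_family Females assigned per family to each treatment.
#' @param pods_per_female Egg pods kept per laying female (default 2).
#' @param egg_mean_rank1,egg_mean_rank2 Mean eggs per pod for first and
#'   second pods; first pods hold more eggs (`egg_mean_rank1 >=
#'   egg_mean_rank2 > 0`). Pods beyond rank 2 reuse the rank-2 mean.
#' @param egg_dist Distribution of eggs per pod: `"poisson"` (default) or
#'   `"nbinom"` with dispersion `egg_size`.
#' @param egg_size Negative-binomial size parameter when `egg_dist =
#'   "nbinom"`.
#' @param survival24h_prob Named vector, per-treatment probability a
#'   hatchling is alive 24 h after emergence.
#' @param larval_survival_prob Named vector, per-treatment probability a
#'   followed offspring survives to the adult molt.
#' @param trait_effects List with elements `development_time` and
#'   `femur_length`, each a named per-treatment additive shift (days, mm).
#' @param dev_time_mean Baseline days from hatching to adult molt.
#' @param femur_mean Baseline adult femur length (mm).
#' @param offspring_cap Maximum 24-h survivors per pod reared individually.
#' @param offspring_treatments Treatments whose survivors are followed
#'   individually; parthenogenetic survivors are excluded by default,
#'   mirroring the rearing design, but can be added.
#' @return A `population_sim_config` list, validated.
#' @seealso [simulate_experiment()], [example_sim_configs()]
#' @export
population_sim_config <- function(name,
                                  b,
                                  baseline_hatch = 0.75,
                                  laying_prob = c(outbred = 0.85,
                                                  inbred_fullsib = 0.85,
                                                  parthenogenetic = 0.45),
                                  n_families = 8,
                                  females_per_family = 4,
                                  pods_per_female = 2,
                                  egg_mean_rank1 = 70,
                                  egg_mean_rank2 = 55,
                                  egg_dist = c("poisson", "nbinom"),
                                  egg_size = 20,
                                  survival24h_prob = c(outbred = 0.90,
                                                       inbred_fullsib = 0.90,
                                                       parthenogenetic = 0.55),
                                  larval_survival_prob = c(outbred = 0.85,
                                                           inbred_fullsib = 0.85,
                                                           parthenogenetic = 0.05),
                                  trait_effects = list(
                                    development_time = c(outbred = 0,
                                                         inbred_fullsib = 0.5,
                                                         parthenogenetic = 4),
                                    femur_length = c(outbred = 0,
                                                     inbred_fullsib = -0.2,
                                                     parthenogenetic = 0.5)
                                  ),
                                  dev_time_mean = 30,
                                  femur_mean = 20,
                                  offspring_cap = 15,
                                  offspring_treatments = c("outbred",
                                                           "inbred_fullsib")) {
  egg_dist <- match.arg(egg_dist)
  cfg <- list(
    name = as.character(name), b = b, baseline_hatch = baseline_hatch,
    laying_prob = laying_prob, n_families = n_families,
    females_per_family = females_per_family,
    pods_per_female = pods_per_female,
    egg_mean_rank1 = egg_mean_rank1, egg_mean_rank2 = egg_mean_rank2,
    egg_dist = egg_dist, egg_size = egg_size,
    survival24h_prob = survival24h_prob,
    larval_survival_prob = larval_survival_prob,
    trait_effects = trait_effects,
    dev_time_mean = dev_time_mean, femur_mean = femur_mean,
    offspring_cap = offspring_cap,
    offspring_treatments = offspring_treatments
  )
  class(cfg) <- "population_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop("invalid simulation config", if (!is.null(cfg$name)) paste0(" '", cfg$name, "'"),
         ": field `", field, "` ", msg, call. = FALSE)
  }
  if (!length(cfg$name) || is.na(cfg$name)) stop_cfg("name", "must be a label")
  if (!is.numeric(cfg$b) || length(cfg$b) != 1 || is.na(cfg$b) || cfg$b < 0) {
    stop_cfg("b", "must be a single number >= 0 (Inf allowed)")
  }
  for (field in c("baseline_hatch")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(v < 0 | v > 1)) stop_cfg(field, "must lie in [0, 1]")
  }
  for (field in c("laying_prob", "survival24h_prob", "larval_survival_prob")) {
    v <- cfg[[field]]
    if (!all(treatment_levels() %in% names(v))) {
      stop_cfg(field, paste0("must be named for all treatments: ",
                             paste(treatment_levels(), collapse = ", ")))
    }
    if (any(v < 0 | v > 1)) stop_cfg(field, "must lie in [0, 1]")
  }
  if (!(cfg$egg_mean_rank1 >= cfg$egg_mean_rank2) || cfg$egg_mean_rank2 <= 0) {
    stop_cfg("egg_mean_rank1/egg_mean_rank2",
             "must satisfy egg_mean_rank1 >= egg_mean_rank2 > 0")
  }
  for (field in c("n_families", "females_per_family", "pods_per_female",
                  "offspring_cap")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || v < 1 || v != round(v)) {
      stop_cfg(field, "must be a positive integer")
    }
  }
  if (!all(cfg$offspring_treatments %in% treatment_levels())) {
    stop_cfg("offspring_treatments", "contains unknown treatment labels")
  }
  cfg
}

#' Example four-population simulation design
#'
#' A ready-made design emulating a study of four desert-locust populations
#' with contrasting rearing histories: two old laboratory colonies with low
#' genetic diversity, one recent colony, and one field-derived population.
#' Haploid loads default to 1.1, 3.8 and 3.9 lethal equivalents for the old
#' and recent colonies; the field population (whose parthenogenetic pods
#' yield no hatching data, emulated by a zero parthenogenetic laying
#' probability) is given a field-like load of 4. Family counts follow the
#' study design (8, 8, 7, 6 families).
#'
#' @param b Named numeric vector of lethal equivalents per population.
#' @return A named list of [population_sim_config()] objects.
#' @examples
#' sim <- simulate_experiment(example_sim_configs(), seed = 1)
#' dplyr::count(sim$pods, population, treatment)
#' @export
example_sim_configs <- function(b = c(England = 1.1, Belgium = 3.8,
                                      France = 3.9, Mauritania = 4)) {
  n_fam <- c(England = 8, Belgium = 8, France = 7, Mauritania = 6)
  purrr::imap(as.list(b), function(load, pop) {
    laying <- c(outbred = 0.85, inbred_fullsib = 0.85, parthenogenetic = 0.45)
    if (pop == "Mauritania") {
      laying["parthenogenetic"] <- 0
      laying[c("outbred", "inbred_fullsib")] <- 0.6
    }
    population_sim_config(
      name = pop, b = load, laying_prob = laying,
      n_families = unname(n_fam[pop] %||% 8)
    )
  })
}

# Deterministic per-population RNG seed, derived from the master seed and the
# population name so that adding or reordering populations leaves the other
# populations' draws untouched.
population_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 100003L
  as.integer((abs(as.numeric(seed)) %% 20011 + 1) * 100003 + h) %% 2147483647L
}

#' Simulate per-egg hatching under the mechanistic lethal model
#'
#' Draws hatching outcomes egg by egg: each egg carries `k ~ Poisson(b)`
#' recessive lethals, each lethal is expressed (made homozygous) with
#' probability `f`, and the egg hatches iff an independent baseline-viability
#' Bernoulli succeeds and no lethal is expressed. The hatch probability is
#' therefore `baseline_hatch * exp(-b * f)`, but the draw is mechanistic so
#' that the simulator can serve as an independent check of the closed form.
#'
#' @param n_eggs Number of eggs.
#' @inheritParams expected_relative_hatching
#' @param baseline_hatch Baseline viability in `[0, 1]`.
#' @return Logical vector of length `n_eggs`: did each egg hatch?
#' @examples
#' set.seed(1)
#' mean(simulate_egg_hatching(1e5, b = 1.1, f = 1))  # ~ 0.75 * exp(-1.1)
#' @export
simulate_egg_hatching <- function(n_eggs, b, f, baseline_hatch = 1) {
  check_bf(b, f)
  if (n_eggs == 0) return(logical(0))
  viable <- stats::runif(n_eggs) < baseline_hatch
  if (is.infinite(b)) {
    if (f > 0) return(rep(FALSE, n_eggs)) else return(viable)
  }
  k <- stats::rpois(n_eggs, b)
  expressed <- stats::rbinom(n_eggs, size = k, prob = f)
  viable & expressed == 0L
}

draw_eggs <- function(n, mean, dist, size) {
  if (dist == "poisson") stats::rpois(n, mean)
  else stats::rnbinom(n, size = size, mu = mean)
}

simulate_population <- function(cfg, seed) {
  trts <- treatment_inbreeding()
  pods <- list(); offspring <- list(); females <- list()
  withr::with_seed(population_seed(seed, cfg$name), {
    female_no <- 0L
    for (fam in seq_len(cfg$n_families)) {
      for (ti in seq_len(nrow(trts))) {
        trt <- trts$treatment[ti]
        f_coef <- trts$f[ti]
        for (j in seq_len(cfg$females_per_family)) {
          female_no <- female_no + 1L
          fid <- sprintf("%s_F%03d", cfg$name, female_no)
          laid <- stats::runif(1) < cfg$laying_prob[[trt]]
          females[[length(females) + 1L]] <- tibble::tibble(
            population = cfg$name, family = fam, female_id = fid,
            treatment = trt, laid = laid
          )
          if (!laid) next
          for (rank in seq_len(cfg$pods_per_female)) {
            mu <- if (rank == 1) cfg$egg_mean_rank1 else cfg$egg_mean_rank2
            n_eggs <- draw_eggs(1, mu, cfg$egg_dist, cfg$egg_size)
            hatched <- simulate_egg_hatching(n_eggs, cfg$b, f_coef,
                                             cfg$baseline_hatch)
            n_hatched <- sum(hatched)
            n_surv <- stats::rbinom(1, n_hatched, cfg$survival24h_prob[[trt]])
            pods[[length(pods) + 1L]] <- tibble::tibble(
              population = cfg$name, family = fam, female_id = fid,
              treatment = trt, pod_rank = rank, n_eggs = n_eggs,
              n_hatched = n_hatched, n_survived_24h = n_surv
            )
            if (trt %in% cfg$offspring_treatments && n_surv > 0) {
              n_off <- min(n_surv, cfg$offspring_cap)
              sex <- ifelse(stats::runif(n_off) < 0.5, "F", "M")
              extra <- stats::runif(n_off) < 0.15
              molted <- stats::runif(n_off) < cfg$larval_survival_prob[[trt]]
              dev <- cfg$dev_time_mean +
                cfg$trait_effects$development_time[[trt]] +
                4 * extra + 2 * (sex == "F") + stats::rnorm(n_off, 0, 2)
              dev <- pmax(round(dev, 1), 10)
              femur <- cfg$femur_mean + cfg$trait_effects$femur_length[[trt]] +
                2 * (sex == "F") + 0.6 * extra + stats::rnorm(n_off, 0, 0.5)
              death_day <- round(pmax(2, dev * stats::runif(n_off)^0.5), 1)
              offspring[[length(offspring) + 1L]] <- tibble::tibble(
                population = cfg$name, family = fam, treatment = trt,
                offspring_id = sprintf("%s_P%d_%02d", fid, rank, seq_len(n_off)),
                sex = sex, extra_molt = extra,
                development_time = ifelse(molted, dev, NA_real_),
                femur_length = ifelse(molted, round(femur, 2), NA_real_),
                survival_days = ifelse(molted, dev, death_day),
                event = ifelse(molted, "molted", "died")
              )
            }
          }
        }
      }
    }
  })
  list(
    pods = dplyr::bind_rows(pods),
    offspring = dplyr::bind_rows(offspring),
    females = dplyr::bind_rows(females)
  )
}

#' Simulate a three-treatment locust breeding experiment
#'
#' Generates tidy pod, offspring and female tables for one or more
#' populations under the generative model described in
#' [population_sim_config()]. Each population consumes its own RNG stream,
#' derived deterministically from `seed` and the population name, so results
#' for a population do not change when other populations are added or
#' removed. Output is byte-identical across runs for a fixed seed.
#'
#' @param configs A [population_sim_config()] or a list of them.
#' @param seed Integer master seed (mandatory).
#' @return A list of three tibbles:
#'   * `pods` -- one row per egg pod (`population`, `family`, `female_id`,
#'     `treatment`, `pod_rank`, `n_eggs`, `n_hatched`, `n_survived_24h`);
#'   * `offspring` -- one row per individually reared hatchling (traits,
#'     survival, `event` = `"died"` or `"molted"`; `development_time` and
#'     `femur_length` are `NA` for larvae that died);
#'   * `females` -- one row per isolated female (`laid` logical), needed to
#'     compute laying proportions.
#' @examples
#' sim <- simulate_experiment(population_sim_config("demo", b = 3.8), seed = 1)
#' head(sim$pods)
#' @export
simulate_experiment <- function(configs, seed) {
  if (missing(seed)) stop("`seed` is mandatory for simulation", call. = FALSE)
  if (inherits(configs, "population_sim_config")) configs <- list(configs)
  configs <- lapply(configs, validate_sim_config)
  nm <- vapply(configs, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicated population names in configs: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  parts <- lapply(configs, simulate_population, seed = seed)
  list(
    pods = dplyr::bind_rows(lapply(parts, `[[`, "pods")),
    offspring = dplyr::bind_rows(lapply(parts, `[[`, "offspring")),
    females = dplyr::bind_rows(lapply(parts, `[[`, "females"))
  )
}

#' Configure a simulated microsatellite sample
#'
#' Parameters for drawing diploid multilocus genotypes for one population
#' with a target within-population inbreeding coefficient. For
#' `f_is >= 0` each genotype is drawn mechanistically: with probability
#' `f_is` the two alleles are identical by descent (a single draw from the
#' allele-frequency vector, duplicated), otherwise two independent draws.
#' For `f_is < 0` (heterozygote excess) genotypes are sampled exactly from
#' the genotype distribution `P(ii) = p_i^2 + F p_i (1 - p_i)`,
#' `P(ij) = 2 p_i p_j (1 - F)`; configurations in which some homozygote
#' probability would be negative are rejected at validation.
#'
#' @param population Population label.
#' @param n_individuals Number of diploid individuals.
#' @param n_loci Number of loci (default 6, a typical microsatellite panel).
#' @param alleles_per_locus Number of alleles per locus when `allele_freqs`
#'   is not supplied (equifrequent alleles are then used).
#' @param allele_freqs Optional list of per-locus frequency vectors, each
#'   summing to 1 (within 1e-9); allele codes are the vector indices.
#' @param f_is Target inbreeding coefficient, `-1 < f_is < 1`.
#' @param missing_rate Probability a genotype is missing, per individual and
#'   locus.
#' @return A `genotype_sim_config` list.
#' @seealso [simulate_genotypes()]
#' @export
genotype_sim_config <- function(population = "pop1",
                                n_individuals = 30,
                                n_loci = 6,
                                alleles_per_locus = 8,
                                allele_freqs = NULL,
                                f_is = 0,
                                missing_rate = 0) {
  if (is.null(allele_freqs)) {
    allele_freqs <- replicate(n_loci,
                              rep(1 / alleles_per_locus, alleles_per_locus),
                              simplify = FALSE)
  }
  cfg <- list(population = as.character(population),
              n_individuals = n_individuals,
              allele_freqs = allele_freqs, f_is = f_is,
              missing_rate = missing_rate)
  class(cfg) <- "genotype_sim_config"
  validate_genotype_config(cfg)
}

validate_genotype_config <- function(cfg) {
  if (abs(cfg$f_is) >= 1) {
    stop("invalid genotype config: |f_is| must be < 1", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1) {
    stop("invalid genotype config: missing_rate must lie in [0, 1]",
         call. = FALSE)
  }
  for (l in seq_along(cfg$allele_freqs)) {
    p <- cfg$allele_freqs[[l]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      stop("invalid genotype config: allele frequencies at locus ", l,
           " must be non-negative and sum to 1", call. = FALSE)
    }
    if (cfg$f_is < 0) {
      hom <- p^2 + cfg$f_is * p * (1 - p)
      if (any(hom < -1e-12)) {
        stop("invalid genotype config: f_is = ", cfg$f_is,
             " implies a negative homozygote probability at locus ", l,
             call. = FALSE)
      }
    }
  }
  if (cfg$n_individuals < 1) {
    stop("invalid genotype config: n_individuals must be >= 1", call. = FALSE)
  }
  cfg
}

draw_locus_genotypes <- function(n, p, f_is) {
  k <- length(p)
  if (f_is >= 0) {
    ibd <- stats::runif(n) < f_is
    a1 <- sample.int(k, n, replace = TRUE, prob = p)
    a2 <- sample.int(k, n, replace = TRUE, prob = p)
    a2[ibd] <- a1[ibd]
  } else {
    # exact draw from P(ii) = p_i^2 + F p_i (1-p_i), P(ij) = 2 p_i p_j (1-F)
    gp <- outer(p, p) * (1 - f_is)
    diag(gp) <- p^2 + f_is * p * (1 - p)
    gp[lower.tri(gp)] <- 2 * gp[lower.tri(gp)]
    gp[upper.tri(gp)] <- 0
    idx <- which(gp > 0, arr.ind = TRUE)
    g <- sample.int(nrow(idx), n, replace = TRUE, prob = gp[idx])
    a1 <- idx[g, 2]; a2 <- idx[g, 1]
  }
  cbind(pmin(a1, a2), pmax(a1, a2))
}

#' Simulate multilocus microsatellite genotypes
#'
#' Draws a tidy genotype table for one or more populations from
#' [genotype_sim_config()] settings. The expected observed heterozygosity is
#' `(1 - f_is)` times the expected heterozygosity of the frequency vector,
#' so large samples recover the configured `f_is`.
#'
#' @param configs A `genotype_sim_config` or list of them (one per
#'   population; all must share the same number of loci).
#' @param seed Integer master seed; per-population streams as in
#'   [simulate_experiment()].
#' @return A tibble with one row per individual x locus: `population`,
#'   `individual`, `locus`, `allele_1`, `allele_2` (ordered so `allele_1 <=
#'   allele_2`; both `NA` when missing).
#' @examples
#' geno <- simulate_genotypes(genotype_sim_config(f_is = 0.3), seed = 1)
#' popgen_summary(geno)
#' @export
simulate_genotypes <- function(configs, seed) {
  if (missing(seed)) stop("`seed` is mandatory for simulation", call. = FALSE)
  if (inherits(configs, "genotype_sim_config")) configs <- list(configs)
  configs <- lapply(configs, validate_genotype_config)
  n_loci <- unique(vapply(configs, function(c) length(c$allele_freqs), 0L))
  if (length(n_loci) != 1) {
    stop("all genotype configs must have the same number of loci",
         call. = FALSE)
  }
  tabs <- lapply(configs, function(cfg) {
    withr::with_seed(population_seed(seed, paste0("geno:", cfg$population)), {
      rows <- lapply(seq_along(cfg$allele_freqs), function(l) {
        g <- draw_locus_genotypes(cfg$n_individuals, cfg$allele_freqs[[l]],
                                  cfg$f_is)
        miss <- stats::runif(cfg$n_individuals) < cfg$missing_rate
        tibble::tibble(
          population = cfg$population,
          individual = sprintf("%s_%03d", cfg$population,
                               seq_len(cfg$n_individuals)),
          locus = sprintf("L%02d", l),
          allele_1 = ifelse(miss, NA_integer_, g[, 1]),
          allele_2 = ifelse(miss, NA_integer_, g[, 2])
        )
      })
      dplyr::bind_rows(rows)
    })
  })
  dplyr::arrange(dplyr::bind_rows(tabs), .data$population, .data$individual,
                 .data$locus)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
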