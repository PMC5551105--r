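#' Default pipeline configuration
#'
#' A complete configuration for the simulate-and-analyse pipeline: the
#' four-population breeding design of [example_sim_configs()], a matching
#' set of genotype configurations (high-diversity field-like populations,
#' low-diversity old colonies), bootstrap settings and reporting options.
#' The configuration round-trips losslessly through
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed Master seed used by every simulation stage.
#' @param n_boot Bootstrap replicates for load confidence intervals.
#' @param weighting Hatch-rate weighting, `"pooled"` or `"per_female"`.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1, n_boot = 1000,
                                    weighting = "pooled") {
  diversity <- list(
    England = list(alleles = 4, f_is = 0.02),
    Belgium = list(alleles = 4, f_is = 0.00),
    France = list(alleles = 10, f_is = 0.07),
    Mauritania = list(alleles = 12, f_is = -0.04)
  )
  cfg <- list(
    seed = as.integer(seed),
    n_boot = as.integer(n_boot),
    weighting = weighting,
    report_digits = 0L,
    populations = lapply(example_sim_configs(), unclass),
    genotypes = purrr::imap(diversity, function(d, pop) {
      unclass(genotype_sim_config(
        population = pop, n_individuals = 30, n_loci = 6,
        alleles_per_locus = d$alleles, f_is = d$f_is
      ))
    })
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read and write pipeline configurations
#'
#' Configurations are stored as YAML. Reading validates every population
#' and genotype block and restores the classed config objects.
#'
#' @param config A `pipeline_config` object.
#' @param path File path.
#' @return `read_pipeline_config()` returns a validated `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_config(config), path, precision = 15)
  invisible(path)
}

unclass_config <- function(config) {
  x <- unclass(config)
  x$populations <- lapply(x$populations, function(p) {
    p$trait_effects <- lapply(p$trait_effects, as.list)
    p$laying_prob <- as.list(p$laying_prob)
    p$survival24h_prob <- as.list(p$survival24h_prob)
    p$larval_survival_prob <- as.list(p$larval_survival_prob)
    p
  })
  x
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (field in c("seed", "populations")) {
    if (is.null(raw[[field]])) {
      stop("pipeline config is missing field `", field, "`", call. = FALSE)
    }
  }
  raw$populations <- lapply(raw$populations, function(p) {
    p$laying_prob <- unlist(p$laying_prob)
    p$survival24h_prob <- unlist(p$survival24h_prob)
    p$larval_survival_prob <- unlist(p$larval_survival_prob)
    p$trait_effects <- lapply(p$trait_effects, unlist)
    validate_sim_config(structure(p, class = "population_sim_config"))
  })
  raw$genotypes <- lapply(raw$genotypes, function(g) {
    validate_genotype_config(structure(g, class = "genotype_sim_config"))
  })
  raw$n_boot <- as.integer(raw$n_boot %||% 1000L)
  raw$weighting <- raw$weighting %||% "pooled"
  raw$report_digits <- as.integer(raw$report_digits %||% 0L)
  structure(raw, class = "pipeline_config")
}

format_inf <- function(x, digits = 6) {
  ifelse(is.na(x), NA_character_,
         ifelse(is.infinite(x), "inf", formatC(x, digits = digits,
                                               format = "g")))
}

#' Simulate a full dataset to disk
#'
#' Runs [simulate_experiment()] and [simulate_genotypes()] under the
#' configuration's master seed and writes `pods.csv`, `offspring.csv`,
#' `females.csv`, `genotypes.gen` (GENEPOP) and `provenance.json` (config
#' hash, seed, package version) into `out_dir`. Identical configuration and
#' seed give byte-identical files.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]) or a
#'   path to a YAML config.
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_experiment(config$populations, seed = config$seed)
  files <- c(
    pods = file.path(out_dir, "pods.csv"),
    offspring = file.path(out_dir, "offspring.csv"),
    females = file.path(out_dir, "females.csv")
  )
  readr::write_csv(sim$pods, files["pods"], na = "")
  readr::write_csv(sim$offspring, files["offspring"], na = "")
  readr::write_csv(sim$females, files["females"], na = "")
  if (!is.null(config$genotypes) && length(config$genotypes) > 0) {
    geno <- simulate_genotypes(config$genotypes, seed = config$seed)
    files["genotypes"] <- file.path(out_dir, "genotypes.gen")
    write_genepop(geno, files["genotypes"])
  }
  files["provenance"] <- file.path(out_dir, "provenance.json")
  prov <- list(
    config_hash = rlang::hash(unclass_config(config)),
    seed = config$seed,
    package = "locustload",
    version = as.character(utils::packageVersion("locustload"))
  )
  writeLines(paste0(
    '{"config_hash": "', prov$config_hash, '", "seed": ', prov$seed,
    ', "package": "', prov$package, '", "version": "', prov$version, '"}'
  ), files["provenance"])
  invisible(files)
}

#' Read a pod or offspring CSV with schema validation
#'
#' @param path CSV path with the column schema written by
#'   [pipeline_simulate()].
#' @return A validated tibble.
#' @export
read_pods_csv <- function(path) {
  pods <- readr::read_csv(path, show_col_types = FALSE)
  check_pod_table(pods)
  pods
}

#' Analyse a dataset from disk
#'
#' Reads the pod table (plus optional offspring, female and GENEPOP
#' genotype files), runs [summarize_treatments()], [run_load_inference()]
#' and, when genotypes are given, [popgen_summary()], and writes
#' `treatment_summary.csv`, `load_estimates.csv`, `report.txt` and (with
#' genotypes) `popgen_per_locus.csv`, `popgen_per_population.csv`,
#' `popgen_fst.csv` into `out_dir`. In `load_estimates.csv`, unbounded load
#' estimates are serialised as the string `inf`.
#'
#' @param pods_path Pod CSV path.
#' @param offspring_path,females_path,genotypes_path Optional companion
#'   files.
#' @param out_dir Output directory.
#' @param n_boot,seed,weighting Passed to [run_load_inference()].
#' @return Named character vector of the files written, invisibly.
#' @export
pipeline_analyze <- function(pods_path, offspring_path = NULL,
                             females_path = NULL, genotypes_path = NULL,
                             out_dir, n_boot = 1000, seed = 1,
                             weighting = "pooled") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pods <- read_pods_csv(pods_path)
  offspring <- if (!is.null(offspring_path))
    readr::read_csv(offspring_path, show_col_types = FALSE) else NULL
  females <- if (!is.null(females_path))
    readr::read_csv(females_path, show_col_types = FALSE) else NULL

  summ <- summarize_treatments(pods, offspring, females,
                               weighting = weighting)
  files <- c(summary = file.path(out_dir, "treatment_summary.csv"))
  readr::write_csv(summ, files["summary"], na = "")

  have_parth <- any(pods$treatment == "parthenogenetic" & pods$n_eggs > 0)
  report_lines <- character()
  if (have_parth) {
    inf <- run_load_inference(pods, n_boot = n_boot, seed = seed,
                              weighting = weighting)
    est <- tidy(inf)
    est$b_hat <- format_inf(est$b_hat)
    est$conf_low <- format_inf(est$conf_low)
    est$conf_high <- format_inf(est$conf_high)
    files["estimates"] <- file.path(out_dir, "load_estimates.csv")
    readr::write_csv(est, files["estimates"], na = "")
    report_lines <- utils::capture.output(report_load_inference(inf))
  } else {
    warning("no parthenogenetic pods with eggs; load inference skipped",
            call. = FALSE)
    report_lines <- "Load inference skipped: no parthenogenetic pods with eggs."
  }

  if (!is.null(genotypes_path)) {
    geno <- read_genepop(genotypes_path)
    pg <- popgen_summary(geno)
    files["popgen_per_locus"] <- file.path(out_dir, "popgen_per_locus.csv")
    files["popgen_per_population"] <-
      file.path(out_dir, "popgen_per_population.csv")
    files["popgen_fst"] <- file.path(out_dir, "popgen_fst.csv")
    readr::write_csv(pg$per_locus, files["popgen_per_locus"], na = "")
    readr::write_csv(pg$per_population, files["popgen_per_population"],
                     na = "")
    readr::write_csv(pg$fst, files["popgen_fst"], na = "")
    report_lines <- c(report_lines, "",
                      utils::capture.output(print(pg)))
  }
  files["report"] <- file.path(out_dir, "report.txt")
  writeLines(report_lines, files["report"])
  invisible(files)
}
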