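test_that("treatment summaries compute pooled rates and relative hatching", {
  pods <- make_pods(c("outbred", "outbred", "inbred_fullsib"),
                    n_eggs = c(60, 40, 100),
                    n_hatched = c(45, 30, 75),
                    n_survived = c(40, 28, 70))
  s <- summarize_treatments(pods)
  expect_identical(nrow(s), 2L)
  out <- s[s$treatment == "outbred", ]
  inb <- s[s$treatment == "inbred_fullsib", ]
  expect_equal(out$hatch_rate, 75 / 100)
  expect_equal(out$relative_hatching, 1)
  # equal hatch rates: relative hatching 1, no inbreeding depression
  expect_equal(inb$relative_hatching, 1)
  expect_equal(inb$delta_hatch, 0)
  expect_equal(inb$survival_24h_rate, 70 / 75)

  # outbred pods only: a single summary row with relative hatching 1
  only_out <- summarize_treatments(make_pods("outbred", 80, 60))
  expect_identical(nrow(only_out), 1L)
  expect_equal(only_out$relative_hatching, 1)

  expect_error(
    summarize_treatments(make_pods("selfed", 10, 5)),
    "outbred, inbred_fullsib, parthenogenetic")
})

test_that("per-female weighting averages female rates instead of pooling eggs", {
  pods <- tibble::tibble(
    population = "p", family = 1L,
    female_id = c("f1", "f1", "f2"), treatment = "outbred",
    pod_rank = c(1L, 2L, 1L), n_eggs = c(10, 10, 100),
    n_hatched = c(10, 10, 50), n_survived_24h = c(10, 10, 50)
  )
  pooled <- summarize_treatments(pods)$hatch_rate
  per_female <- summarize_treatments(pods, weighting = "per_female")$hatch_rate
  expect_equal(pooled, 70 / 120)
  expect_equal(per_female, mean(c(1, 0.5)))
})

test_that("laying proportion and trait summaries appear when tables are given", {
  sim <- simulate_experiment(
    population_sim_config("demo", b = 1, n_families = 10), seed = 19)
  s <- summarize_treatments(sim$pods, sim$offspring, sim$females)
  expect_true(all(!is.na(s$laying_proportion)))
  expect_true(all(s$laying_proportion >= 0 & s$laying_proportion <= 1))
  expect_true(all(c("larval_survival", "mean_development_time",
                    "mean_femur_length") %in% names(s)))
  # laying proportion = layers / isolated females, per treatment
  for (i in seq_len(nrow(s))) {
    fem <- sim$females[sim$females$treatment == s$treatment[i], ]
    expect_equal(s$laying_proportion[i], mean(fem$laid))
  }
})

test_that("summaries calibrate to the configured probabilities", {
  cfg <- population_sim_config(
    "calib", b = 1.5, baseline_hatch = 0.8, n_families = 60,
    females_per_family = 4,
    laying_prob = c(outbred = 0.7, inbred_fullsib = 0.7,
                    parthenogenetic = 0.3),
    survival24h_prob = c(outbred = 0.9, inbred_fullsib = 0.9,
                         parthenogenetic = 0.5),
    offspring_treatments = character(0)
  )
  sim <- simulate_experiment(cfg, seed = 23)
  s <- summarize_treatments(sim$pods, females = sim$females)
  n_fem <- 60 * 4
  for (trt in c("outbred", "parthenogenetic")) {
    row <- s[s$treatment == trt, ]
    p_lay <- cfg$laying_prob[[trt]]
    expect_lt(abs(row$laying_proportion - p_lay),
              4 * sqrt(p_lay * (1 - p_lay) / n_fem))
    p_hatch <- 0.8 * expected_relative_hatching(1.5, treatment_inbreeding()$f[
      treatment_inbreeding()$treatment == trt])
    expect_lt(abs(row$hatch_rate - p_hatch),
              4 * sqrt(p_hatch * (1 - p_hatch) / row$total_eggs))
    p_s <- cfg$survival24h_prob[[trt]]
    expect_lt(abs(row$survival_24h_rate - p_s),
              4 * sqrt(p_s * (1 - p_s) / row$total_hatched))
  }
})

test_that("load inference reproduces the forward model per population", {
  pods <- dplyr::bind_rows(
    make_pods(c("outbred", "parthenogenetic", "inbred_fullsib"),
              n_eggs = c(10000, 10000, 10000),
              n_hatched = c(10000, 3329, 7596), population = "E"),
    make_pods(c("outbred", "parthenogenetic"),
              n_eggs = c(5000, 5000), n_hatched = c(5000, 0),
              population = "Z"),
    make_pods(c("outbred", "inbred_fullsib"),
              n_eggs = c(500, 500), n_hatched = c(400, 350),
              population = "M")
  )
  inf <- run_load_inference(pods, n_boot = 100, seed = 2)
  e <- inf[inf$population == "E", ]
  expect_equal(round(e$b_hat, 1), 1.1)
  expect_identical(round(100 * e$predicted_inbred_rel), 76)
  expect_equal(e$observed_inbred_rel, 0.7596)
  # predicted = exp(-b/4) exactly
  expect_identical(e$predicted_inbred_rel,
                   predict_inbred_relative_hatching(e$b_hat))

  z <- inf[inf$population == "Z", ]
  expect_identical(z$b_hat, Inf)
  expect_identical(z$predicted_inbred_rel, 0)
  expect_match(z$note, "unbounded")

  m <- inf[inf$population == "M", ]
  expect_true(is.na(m$b_hat))
  expect_match(m$note, "no parthenogenetic pods")
  expect_equal(m$observed_inbred_rel, (350 / 500) / (400 / 500))

  # pure function of inputs and seed
  expect_identical(tidy(inf),
                   tidy(run_load_inference(pods, n_boot = 100, seed = 2)))

  g <- glance(inf)
  expect_identical(g$n_populations, 3L)
  expect_identical(g$n_estimated, 2L)

  rep_lines <- capture.output(txt <- report_load_inference(inf))
  expect_true(any(grepl("B = inf", rep_lines)))
  expect_true(any(grepl("76%", rep_lines)))
})

test_that("pipeline recovers simulated load, independent of baseline hatch", {
  for (base in c(0.9, 0.6)) {
    cfg <- population_sim_config(
      "rec", b = 2, baseline_hatch = base, n_families = 120,
      females_per_family = 3,
      laying_prob = c(outbred = 1, inbred_fullsib = 1, parthenogenetic = 1),
      offspring_treatments = character(0)
    )
    pods <- simulate_experiment(cfg, seed = round(100 * base))$pods
    inf <- run_load_inference(pods, n_boot = 100, seed = 1)
    # ~45k parthenogenetic eggs; exp(-2) ~ 0.135
    expect_lt(abs(inf$b_hat - 2), 0.15)
    expect_lt(abs(inf$observed_inbred_rel - exp(-2 / 4)), 0.05)
  }
})

test_that("autoplot and hatching plots build without error", {
  sim <- simulate_experiment(example_sim_configs(), seed = 1)
  inf <- run_load_inference(sim$pods, n_boot = 50, seed = 1)
  expect_s3_class(autoplot(inf), "ggplot")
  expect_s3_class(plot_hatching_rates(sim$pods), "ggplot")
})
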