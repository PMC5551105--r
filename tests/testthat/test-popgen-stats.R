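test_that("heterozygosity and richness match hand-computed values", {
  # monomorphic locus
  expect_identical(expected_heterozygosity(10), 0)
  # 5 diploid individuals, two alleles at 5/5 copies: (10/9) * 0.5
  expect_equal(expected_heterozygosity(c(5, 5)), 10 / 9 * 0.5)
  # large-sample limit with k equifrequent alleles -> 1 - 1/k
  expect_equal(expected_heterozygosity(rep(1e6, 4)), 0.75, tolerance = 1e-5)

  expect_identical(observed_heterozygosity(c(1, 1), c(1, 1)), 0)
  expect_equal(observed_heterozygosity(c(1, 1, 2, 1), c(2, 1, 2, 2)), 0.5)
  expect_identical(observed_heterozygosity(c(1, 2), c(2, 3)), 1)

  expect_identical(inbreeding_coefficient(c(0.4, 0.2), c(0.4, 0.2)), 0)
  expect_identical(inbreeding_coefficient(c(0, 0), c(0.5, 0.3)), 1)
  expect_identical(inbreeding_coefficient(c(0, 0), c(0, 0)), NA_real_)

  expect_identical(allelic_richness(12, g = 4), 1)
  expect_equal(allelic_richness(c(9, 1), g = 2),
               1 + (1 - choose(9, 2) / choose(10, 2)))
  # g = N: no rarefaction, observed allele count
  expect_equal(allelic_richness(c(4, 3, 3), g = 10), 3)
  expect_error(allelic_richness(c(4, 4), g = 9), "must lie in")
})

test_that("all statistics match naive enumeration on small tables", {
  for (s in 1:4) {
    geno <- simulate_genotypes(list(
      genotype_sim_config("A", n_individuals = 6, n_loci = 2,
                          alleles_per_locus = 3, f_is = 0.2,
                          missing_rate = 0.1),
      genotype_sim_config("B", n_individuals = 5, n_loci = 2,
                          alleles_per_locus = 3, f_is = 0,
                          missing_rate = 0.1)
    ), seed = s)
    het <- heterozygosity_table(geno)
    for (i in seq_len(nrow(het))) {
      d <- geno[geno$population == het$population[i] &
                  geno$locus == het$locus[i], ]
      expect_equal(het$ho[i], enum_ho(d$allele_1, d$allele_2),
                   tolerance = 1e-12)
      expect_equal(het$he[i], enum_he(d$allele_1, d$allele_2),
                   tolerance = 1e-12)
    }
    # rarefied richness against subset enumeration at the default g
    pg <- popgen_summary(geno)
    for (i in seq_len(nrow(pg$per_locus))) {
      row <- pg$per_locus[i, ]
      d <- geno[geno$population == row$population & geno$locus == row$locus, ]
      g_used <- pg$rarefaction_g[[row$locus]]
      expect_equal(row$a_r, enum_ar(d$allele_1, d$allele_2, g_used),
                   tolerance = 1e-12)
    }
    # multilocus F_IS is the ratio-of-sums aggregation
    for (p in c("A", "B")) {
      hp <- het[het$population == p, ]
      keep <- hp$he > 0
      expect_equal(
        pg$per_population$f_is[pg$per_population$population == p],
        1 - sum(hp$ho[keep]) / sum(hp$he[keep]), tolerance = 1e-12)
    }
    # Weir-Cockerham theta against the indicator-variable ANOVA
    expect_equal(pairwise_fst(geno)$fst, enum_theta(geno, c("A", "B")),
                 tolerance = 1e-12)
  }
})

test_that("theta behaves at the differentiation extremes", {
  # two populations fixed for different alleles: theta = 1
  fixed <- dplyr::bind_rows(
    tibble::tibble(population = "A", individual = sprintf("A%d", 1:10),
                   locus = "L1", allele_1 = 1L, allele_2 = 1L),
    tibble::tibble(population = "B", individual = sprintf("B%d", 1:10),
                   locus = "L1", allele_1 = 2L, allele_2 = 2L)
  )
  expect_equal(pairwise_fst(fixed)$fst, 1)

  # same allele frequencies: theta near 0 (can be slightly negative)
  same <- simulate_genotypes(list(
    genotype_sim_config("A", n_individuals = 2000, n_loci = 4,
                        alleles_per_locus = 6),
    genotype_sim_config("B", n_individuals = 2000, n_loci = 4,
                        alleles_per_locus = 6)
  ), seed = 13)
  expect_lt(abs(pairwise_fst(same)$fst), 0.01)

  # shared monomorphic locus: undefined differentiation
  mono <- dplyr::mutate(fixed, allele_2 = 1L, allele_1 = 1L)
  expect_true(is.na(pairwise_fst(mono)$fst))
})

test_that("statistics are invariant to permutation, predictable under duplication", {
  geno <- simulate_genotypes(
    genotype_sim_config("A", n_individuals = 12, n_loci = 3,
                        alleles_per_locus = 4, f_is = 0.1), seed = 21)
  shuffled <- withr::with_seed(1, geno[sample(nrow(geno)), ])
  h1 <- heterozygosity_table(geno)
  h2 <- heterozygosity_table(shuffled)
  expect_equal(h1, h2)

  # duplicating every individual preserves allele frequencies; H_E changes
  # only through the finite-sample factor N/(N-1)
  dup <- dplyr::mutate(geno, individual = paste0(individual, "_copy"))
  both <- dplyr::bind_rows(geno, dup)
  h3 <- heterozygosity_table(both)
  n1 <- 2 * h1$n
  n2 <- 2 * h3$n
  expect_equal(h3$he * (n2 - 1) / n2, h1$he * (n1 - 1) / n1,
               tolerance = 1e-12)
  expect_equal(h3$ho, h1$ho)
})

test_that("rarefied richness is non-decreasing in subsample size", {
  counts <- c(11, 6, 2, 1)
  ar <- vapply(2:sum(counts), function(g) allelic_richness(counts, g), 0)
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("simulated inbreeding is recovered by the multilocus F_IS", {
  n <- 3000
  geno <- simulate_genotypes(
    genotype_sim_config("fis", n_individuals = n, n_loci = 6,
                        alleles_per_locus = 8, f_is = 0.3), seed = 31)
  het <- heterozygosity_table(geno)
  f_hat <- inbreeding_coefficient(het$ho, het$he)
  he0 <- 1 - 1 / 8
  se <- sqrt(0.7 * he0 * (1 - 0.7 * he0) / (6 * n)) / he0
  expect_lt(abs(f_hat - 0.3), 4 * se)
})

test_that("popgen_summary aggregates, tidies and prints", {
  geno <- simulate_genotypes(list(
    genotype_sim_config("A", n_individuals = 15, n_loci = 3,
                        alleles_per_locus = 5, f_is = 0.1),
    genotype_sim_config("B", n_individuals = 10, n_loci = 3,
                        alleles_per_locus = 5)
  ), seed = 17)
  pg <- popgen_summary(geno)
  expect_s3_class(tidy(pg), "tbl_df")
  expect_identical(nrow(tidy(pg)), 2L)
  expect_identical(glance(pg)$n_pairs, 1L)
  # default rarefaction size: smallest gene-copy count (here pop B, 20)
  expect_true(all(pg$rarefaction_g == 20))
  expect_output(print(pg), "Pairwise F_ST")
  expect_error(popgen_summary(geno, g = 25), "exceeds the sample")
  expect_error(popgen_summary(dplyr::select(geno, -locus)),
               "missing column")
})
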