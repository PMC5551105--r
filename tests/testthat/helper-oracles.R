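# Independent from-first-principles oracles for the population-genetic
# statistics, and small fixture builders. These deliberately use naive
# enumeration/loops so they share no code path with the package.

# P(two gene copies drawn without replacement carry different alleles),
# by enumerating every ordered pair of copies.
enum_he <- function(allele_1, allele_2) {
  copies <- c(allele_1, allele_2)
  copies <- copies[!is.na(copies)]
  n <- length(copies)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && copies[i] != copies[j]) diff <- diff + 1
    }
  }
  diff / (n * (n - 1))
}

# Mean number of distinct alleles over every size-g subset of gene copies.
enum_ar <- function(allele_1, allele_2, g) {
  copies <- c(allele_1, allele_2)
  copies <- copies[!is.na(copies)]
  subsets <- utils::combn(length(copies), g)
  mean(apply(subsets, 2, function(ix) length(unique(copies[ix]))))
}

enum_ho <- function(allele_1, allele_2) {
  ok <- !is.na(allele_1)
  if (!any(ok)) return(NA_real_)
  sum(allele_1[ok] != allele_2[ok]) / sum(ok)
}

# Weir-Cockerham theta via the raw indicator-variable nested ANOVA
# (allele-presence indicators per gene copy; variance components from the
# observed mean squares), aggregated ratio-of-sums over alleles and loci.
enum_theta <- function(geno, pops) {
  num <- 0; den <- 0
  for (loc in unique(geno$locus)) {
    d <- geno[geno$locus == loc & geno$population %in% pops, ]
    d <- d[!is.na(d$allele_1), ]
    n_i <- sapply(pops, function(p) sum(d$population == p))
    if (any(n_i < 2)) next
    r <- length(pops)
    n_c <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    for (al in sort(unique(c(d$allele_1, d$allele_2)))) {
      x1 <- as.numeric(d$allele_1 == al)
      x2 <- as.numeric(d$allele_2 == al)
      xbar <- (x1 + x2) / 2
      p_i <- sapply(pops, function(p) mean(xbar[d$population == p]))
      p_w <- sum(n_i * p_i) / sum(n_i)
      ssp <- sum(2 * n_i * (p_i - p_w)^2)
      ssi <- 0; ssg <- 0
      for (j in seq_len(nrow(d))) {
        pij <- p_i[match(d$population[j], pops)]
        ssi <- ssi + 2 * (xbar[j] - pij)^2
        ssg <- ssg + (x1[j] - xbar[j])^2 + (x2[j] - xbar[j])^2
      }
      msp <- ssp / (r - 1)
      msi <- ssi / sum(n_i - 1)
      msg <- ssg / sum(n_i)
      s2c <- msg
      s2b <- (msi - msg) / 2
      s2a <- (msp - msi) / (2 * n_c)
      num <- num + s2a
      den <- den + s2a + s2b + s2c
    }
  }
  unname(num / den)
}

# Minimal pod table builder.
make_pods <- function(treatment, n_eggs, n_hatched,
                      n_survived = n_hatched, population = "pop") {
  tibble::tibble(
    population = population, family = 1L,
    female_id = sprintf("%s_f%03d", population, seq_along(treatment)),
    treatment = treatment, pod_rank = 1L,
    n_eggs = n_eggs, n_hatched = n_hatched, n_survived_24h = n_survived
  )
}

# A replicate of the two-treatment design used for parameter-recovery
# checks: n_pods pods per treatment, fixed eggs per pod, hatching drawn
# through the mechanistic per-egg simulator.
sim_recovery_pods <- function(b_true, n_pods = 200, eggs = 50,
                              baseline = 0.75) {
  trts <- rep(c("parthenogenetic", "outbred"), each = n_pods)
  f <- ifelse(trts == "parthenogenetic", 1, 0)
  hatched <- vapply(seq_along(trts), function(i) {
    sum(simulate_egg_hatching(eggs, b_true, f[i], baseline))
  }, integer(1))
  make_pods(trts, rep(eggs, length(trts)), hatched)
}
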