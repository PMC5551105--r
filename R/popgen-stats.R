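#' Unbiased expected heterozygosity from allele counts
#'
#' Nei's gene diversity with small-sample correction:
#' `(N / (N - 1)) * (1 - sum(p_i^2))`, where `N` is the number of non-missing
#' gene copies and `p_i` the sample allele frequencies. For diploid data
#' `N = 2n` with `n` genotyped individuals, giving the familiar
#' `2n/(2n - 1)` factor.
#'
#' @param counts Vector of allele counts (gene copies per allele) at one
#'   locus in one population.
#' @return Expected heterozygosity in `[0, 1]`; `NA` with fewer than two
#'   gene copies.
#' @examples
#' expected_heterozygosity(c(5, 5)) # (10/9) * 0.5
#' @export
expected_heterozygosity <- function(counts) {
  counts <- counts[!is.na(counts) & counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Observed heterozygosity of a genotype table
#'
#' Fraction of non-missing genotypes carrying two distinct alleles.
#'
#' @param allele_1,allele_2 Integer allele codes of each individual's two
#'   alleles at one locus (both `NA` when missing).
#' @return Proportion heterozygous, or `NA` if everything is missing.
#' @examples
#' observed_heterozygosity(c(1, 1, 2, 1), c(2, 1, 2, 2))
#' @export
observed_heterozygosity <- function(allele_1, allele_2) {
  ok <- !is.na(allele_1) & !is.na(allele_2)
  if (!any(ok)) return(NA_real_)
  mean(allele_1[ok] != allele_2[ok])
}

#' Multilocus inbreeding coefficient
#'
#' `F_IS = 1 - sum(H_O) / sum(H_E)` over loci (ratio of sums rather than
#' mean of ratios, which stabilises loci with tiny diversity); loci with
#' `H_E = 0` or missing values are excluded.
#'
#' @param ho,he Per-locus observed and expected heterozygosities.
#' @return Multilocus `F_IS`, or `NA` if every locus is monomorphic.
#' @examples
#' inbreeding_coefficient(c(0.2, 0.3), c(0.4, 0.5))
#' @export
inbreeding_coefficient <- function(ho, he) {
  keep <- !is.na(ho) & !is.na(he) & he > 0
  if (!any(keep)) return(NA_real_)
  1 - sum(ho[keep]) / sum(he[keep])
}

#' Rarefied allelic richness from allele counts
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by hypergeometric rarefaction:
#' `A_R(g) = sum_i [1 - choose(N - N_i, g) / choose(N, g)]` with `N` total
#' copies and `N_i` copies of allele `i`. `g = N` returns the observed
#' allele count.
#'
#' @inheritParams expected_heterozygosity
#' @param g Rarefaction size in gene copies, `2 <= g <= N`.
#' @return Rarefied allelic richness (>= 1 whenever data exist).
#' @examples
#' allelic_richness(c(9, 1), g = 2) # 1.2
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[!is.na(counts) & counts > 0]
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  if (g < 2 || g > n) {
    stop("rarefaction size g = ", g, " must lie in [2, ", n,
         "] for this locus", call. = FALSE)
  }
  # lchoose for numerical stability at microsatellite sample sizes
  sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
}

check_genotype_table <- function(geno) {
  required <- c("population", "individual", "locus", "allele_1", "allele_2")
  missing <- setdiff(required, names(geno))
  if (length(missing) > 0) {
    stop("genotype table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  half <- xor(is.na(geno$allele_1), is.na(geno$allele_2))
  if (any(half)) {
    stop("genotype table has half-missing genotypes at row(s) ",
         paste(utils::head(which(half), 5), collapse = ", "), call. = FALSE)
  }
  if (any(geno$allele_1 <= 0 | geno$allele_2 <= 0, na.rm = TRUE)) {
    stop("allele codes must be positive integers", call. = FALSE)
  }
  invisible(geno)
}

allele_count_vector <- function(allele_1, allele_2) {
  a <- c(allele_1, allele_2)
  table(a[!is.na(a)])
}

#' Per-locus heterozygosity table
#'
#' Computes, for every population x locus, the number of genotyped
#' individuals, the number of distinct alleles, observed and unbiased
#' expected heterozygosity, and the per-locus inbreeding coefficient
#' `1 - H_O / H_E`.
#'
#' @param geno Tidy genotype table as produced by [simulate_genotypes()] or
#'   [read_genepop()].
#' @return A tibble with one row per population x locus.
#' @export
heterozygosity_table <- function(geno) {
  check_genotype_table(geno)
  geno |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      n = sum(!is.na(.data$allele_1)),
      n_alleles = length(unique(stats::na.omit(c(.data$allele_1,
                                                 .data$allele_2)))),
      ho = observed_heterozygosity(.data$allele_1, .data$allele_2),
      he = expected_heterozygosity(
        as.numeric(allele_count_vector(.data$allele_1, .data$allele_2))),
      .groups = "drop"
    ) |>
    dplyr::mutate(f_is_locus = ifelse(!is.na(.data$he) & .data$he > 0,
                                      1 - .data$ho / .data$he, NA_real_))
}

# Per-locus allele count matrices: list (by locus) of allele x population
# count matrices over the shared allele set.
locus_count_matrices <- function(geno) {
  pops <- unique(geno$population)
  split(geno, geno$locus) |>
    lapply(function(d) {
      a <- c(d$allele_1, d$allele_2)
      p <- c(d$population, d$population)
      keep <- !is.na(a)
      if (!any(keep)) return(NULL)
      tab <- table(factor(a[keep]), factor(p[keep], levels = pops))
      unclass(tab)
    })
}

# Weir & Cockerham (1984) variance components for one locus and a set of
# populations. Returns per-allele a, b, c vectors.
wc_components <- function(sub) {
  pops <- unique(sub$population)
  r <- length(pops)
  ok <- !is.na(sub$allele_1)
  sub <- sub[ok, ]
  n_i <- vapply(pops, function(p) sum(sub$population == p), 0)
  if (any(n_i == 0) || r < 2) return(NULL)
  alleles <- sort(unique(c(sub$allele_1, sub$allele_2)))
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  a <- b <- cc <- numeric(length(alleles))
  for (k in seq_along(alleles)) {
    al <- alleles[k]
    p_i <- vapply(pops, function(p) {
      d <- sub[sub$population == p, ]
      (sum(d$allele_1 == al) + sum(d$allele_2 == al)) / (2 * nrow(d))
    }, 0)
    h_i <- vapply(pops, function(p) {
      d <- sub[sub$population == p, ]
      mean(d$allele_1 != d$allele_2 & (d$allele_1 == al | d$allele_2 == al))
    }, 0)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a[k] <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
    b[k] <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc[k] <- h_bar / 2
  }
  list(a = a, b = b, c = cc)
}

#' Pairwise population differentiation (Weir & Cockerham's theta)
#'
#' Multilocus F_ST between each pair of populations, estimated as Weir &
#' Cockerham's (1984) theta with the usual ratio-of-sums aggregation of the
#' per-allele, per-locus variance components. Negative estimates are
#' reported as computed, not clamped to zero.
#'
#' @inheritParams heterozygosity_table
#' @return A tibble with columns `pop_a`, `pop_b`, `fst` (one row per
#'   unordered pair); `fst` is `NA` when a pair shares no polymorphic locus
#'   with data in both populations.
#' @examples
#' geno <- simulate_genotypes(list(
#'   genotype_sim_config("A", allele_freqs = list(c(0.9, 0.1))),
#'   genotype_sim_config("B", allele_freqs = list(c(0.1, 0.9)))
#' ), seed = 1)
#' pairwise_fst(geno)
#' @export
pairwise_fst <- function(geno) {
  check_genotype_table(geno)
  pops <- unique(geno$population)
  if (length(pops) < 2) {
    stop("pairwise_fst() needs at least two populations", call. = FALSE)
  }
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    sub <- geno[geno$population %in% pr, ]
    comp <- lapply(split(sub, sub$locus), wc_components)
    comp <- comp[!vapply(comp, is.null, TRUE)]
    num <- sum(unlist(lapply(comp, `[[`, "a")))
    den <- sum(unlist(lapply(comp, function(x) x$a + x$b + x$c)))
    tibble::tibble(pop_a = pr[1], pop_b = pr[2],
                   fst = if (length(comp) == 0 || den == 0) NA_real_
                         else num / den)
  })
}

#' Population-genetic summary of a genotype table
#'
#' Computes the standard microsatellite characterisation of a set of
#' populations: per-locus and mean observed/expected heterozygosity,
#' multilocus F_IS (ratio of sums over loci), rarefied allelic richness and,
#' when more than one population is present, pairwise Weir-Cockerham F_ST.
#'
#' @inheritParams heterozygosity_table
#' @param g Rarefaction size in gene copies for allelic richness; defaults
#'   per locus to the smallest non-missing gene-copy count across
#'   populations.
#' @return A `popgen_summary` object: a list with tibbles `per_locus`,
#'   `per_population` and `fst`, plus the rarefaction sizes used. Use
#'   [tidy()] / [glance()] to extract tibbles, `print()` for a report-style
#'   table.
#' @examples
#' geno <- simulate_genotypes(genotype_sim_config(f_is = 0.2), seed = 7)
#' popgen_summary(geno)
#' @export
popgen_summary <- function(geno, g = NULL) {
  check_genotype_table(geno)
  per_locus <- heterozygosity_table(geno)
  counts <- locus_count_matrices(geno)

  loci <- names(counts)
  g_locus <- vapply(loci, function(l) {
    m <- counts[[l]]
    if (is.null(m)) return(NA_real_)
    copies <- colSums(m)
    copies <- copies[copies > 0]
    if (is.null(g)) min(copies) else as.numeric(g)
  }, 0)

  ar <- purrr::map_dfr(loci, function(l) {
    m <- counts[[l]]
    if (is.null(m) || is.na(g_locus[[l]])) return(NULL)
    purrr::map_dfr(colnames(m), function(p) {
      cnt <- m[, p]
      if (sum(cnt) == 0) {
        return(tibble::tibble(population = p, locus = l, a_r = NA_real_))
      }
      if (g_locus[[l]] > sum(cnt)) {
        stop("rarefaction size g = ", g_locus[[l]],
             " exceeds the sample at locus ", l, " in population ", p,
             call. = FALSE)
      }
      tibble::tibble(population = p, locus = l,
                     a_r = allelic_richness(as.numeric(cnt), g_locus[[l]]))
    })
  })
  per_locus <- dplyr::left_join(per_locus, ar, by = c("population", "locus"))

  per_population <- per_locus |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n = max(.data$n),
      mean_a_r = mean(.data$a_r, na.rm = TRUE),
      mean_h_o = mean(.data$ho, na.rm = TRUE),
      mean_h_e = mean(.data$he, na.rm = TRUE),
      f_is = inbreeding_coefficient(.data$ho, .data$he),
      .groups = "drop"
    )

  fst <- if (length(unique(geno$population)) > 1) pairwise_fst(geno) else
    tibble::tibble(pop_a = character(), pop_b = character(), fst = numeric())

  structure(
    list(per_locus = per_locus, per_population = per_population, fst = fst,
         rarefaction_g = g_locus),
    class = "popgen_summary"
  )
}

#' @export
print.popgen_summary <- function(x, digits = 3, ...) {
  cat("Population summary (per-locus means over",
      length(unique(x$per_locus$locus)), "loci)\n")
  tab <- x$per_population
  cat(sprintf("%-14s %4s %6s %6s %6s %7s\n",
              "Population", "N", "A_R", "H_O", "H_E", "F_IS"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%-14s %4d %6.*f %6.*f %6.*f %+7.*f\n",
                tab$population[i], tab$n[i],
                digits, tab$mean_a_r[i], digits, tab$mean_h_o[i],
                digits, tab$mean_h_e[i], digits, tab$f_is[i]))
  }
  if (nrow(x$fst) > 0) {
    cat("\nPairwise F_ST (Weir & Cockerham theta)\n")
    for (i in seq_len(nrow(x$fst))) {
      cat(sprintf("  %s - %s: %.*f\n", x$fst$pop_a[i], x$fst$pop_b[i],
                  digits, x$fst$fst[i]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname popgen_summary
#' @param x A `popgen_summary` object.
#' @param ... Unused.
#' @method tidy popgen_summary
#' @export
tidy.popgen_summary <- function(x, ...) x$per_population

#' @rdname popgen_summary
#' @method glance popgen_summary
#' @export
glance.popgen_summary <- function(x, ...) {
  tibble::tibble(
    n_populations = nrow(x$per_population),
    n_loci = length(unique(x$per_locus$locus)),
    n_pairs = nrow(x$fst),
    mean_fst = if (nrow(x$fst)) mean(x$fst$fst, na.rm = TRUE) else NA_real_
  )
}
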