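Package: locustload
Title: Lethal Equivalents, Tychoparthenogenesis and Inbreeding Depression in Locust Breeding Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify recessive genetic load from locust breeding
    experiments that compare outbred, full-sib inbred and parthenogenetic
    reproduction. Implements the Poisson lethal-equivalents model relating
    hatching success to offspring inbreeding (relative hatching exp(-B*F)),
    inverse estimation of the haploid load B from parthenogenetic hatching
    with pod-level bootstrap confidence intervals, a seeded simulator of the
    three-treatment breeding design (egg pods, hatching, early survival,
    offspring traits) and of multilocus microsatellite genotypes, and the
    population-genetic summary statistics used to characterise study
    populations (expected and observed heterozygosity, F_IS, rarefied
    allelic richness, pairwise Weir-Cockerham F_ST) with GENEPOP input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
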