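---
title: "The Poisson lethal-equivalents model and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Poisson lethal-equivalents model and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locustload)
```

## The model

Locust tychoparthenogenesis is automictic: meiosis proceeds and diploidy is
restored by endomitosis in the embryo, so parthenogenetic offspring are
fully homozygous — their inbreeding coefficient is F = 1, against F = 1/4
for full-sib offspring and F = 0 for outbred offspring
(`treatment_inbreeding()`). If each haploid genome carries a
Poisson-distributed number of recessive lethals with mean B (the number of
*lethal equivalents*), and inbreeding exposes each lethal as a homozygote
independently with probability F, the number of *expressed* lethals is
Poisson with mean B·F and the probability an egg expresses none is

$$ w(F) = e^{-BF}. $$

This is the hatching rate relative to outbred eggs: any load-independent
viability (fertility, incubation conditions) multiplies the hatching rate
of every treatment equally and cancels in the ratio. The model makes three
substantive assumptions:

* lethals act fully recessively and independently (no epistasis, no
  partial dominance — so B captures *lethal* equivalents, not the milder
  detrimental load);
* load is an egg-level property: each egg draws its lethals
  independently, ignoring the correlation between siblings that shared
  maternal genotype induces;
* selection acts at hatching; later-life effects are not part of B.

Inverting the map gives the estimator used throughout,
$\hat B = -\log(w)/F$, applied at F = 1 to the parthenogenetic/outbred
hatching ratio. The same $\hat B$ then *predicts* the full-sib inbred
relative hatching as $e^{-\hat B/4}$; disagreement between that prediction
and the measured inbred hatching is the model's diagnostic for
parthenogenetic failure beyond inbreeding depression. For loads of 1.1,
3.8 and 3.9 lethal equivalents the predictions are:

```{r}
round(100 * predict_inbred_relative_hatching(c(1.1, 3.8, 3.9)))
```

### Edge cases and numerical conventions

* F = 0 carries no information about load: `estimate_lethal_equivalents()`
  refuses it rather than returning 0/0.
* An observed ratio of exactly 0 gives $\hat B = \infty$; reports
  serialise it as the string `inf`.
* Sampling noise can push observed ratios above 1 (outbred hatching is
  itself an estimate); these are clamped to $\hat B = 0$ with a warning
  and a `clamped` attribute, not treated as errors.
* Percentages in text reports are rounded to the nearest integer; full
  precision is kept in the returned tibbles.

### Pooling and the bootstrap

Hatching rates per treatment are computed by *pooling*: total hatched over
total eggs, so every egg carries the same weight regardless of how pods
differ in size. An alternative weighting (`weighting = "per_female"`,
an unweighted mean of per-female rates) is exposed because either choice
is defensible when females contribute unequal egg numbers; pooling is the
default. Both pod ranks enter the pooled rates.

Uncertainty in $\hat B$ comes from a percentile bootstrap
(`bootstrap_load_ci()`) that resamples *pods* with replacement within each
treatment — pods, not eggs, are the independent sampling units of the
design. A resample with zero outbred hatchlings leaves the ratio
undefined; such replicates are discarded and counted, and more than 50%
discarded aborts with an error rather than returning an interval built
from a biased remnant. The test suite checks, over 200 replicate
experiments of 200 pods × 50 eggs per treatment at B = 3.8, that the
estimator is unbiased to well within 0.15 lethal equivalents and that the
nominal 95% interval covers the truth at close to nominal rate; those
problem sizes give roughly 220 expected parthenogenetic hatchlings per
replicate, enough for the log-ratio to be approximately unbiased.

## What the simulator emulates

`simulate_experiment()` generates the three-treatment breeding design:
full-sib families; females isolated per family and assigned to a
treatment; Bernoulli laying with treatment-specific probability; two pods
per laying female with rank-dependent mean egg numbers (first pods larger,
as observed in gregarious locust lines); hatching; Bernoulli 24-h
survival; and individually reared offspring (up to 15 per pod, outbred and
inbred treatments only by default, mirroring rearing practice) with sex,
extra-molt, larval survival, development time and adult femur length.

Hatching is *mechanistic*, not a draw from the closed form: each egg draws
k ~ Poisson(B) lethals, expresses each with probability F, and hatches iff
an independent baseline-viability Bernoulli succeeds and no lethal is
expressed. The simulator is therefore an independent oracle for the model
— the acceptance tests compare its empirical hatch fractions at 10^6 eggs
against $e^{-BF}$ within four binomial standard errors — rather than a
restatement of it.

Default parameters are chosen to resemble a gregarious *S. gregaria*
rearing: baseline outbred hatching 0.75, pod means of 70 (rank 1) and 55
(rank 2) eggs, laying probability 0.85 for mated females and 0.45 for
virgin (parthenogenetic-treatment) females, 24-h survival 0.90 (sexual)
and 0.55 (parthenogenetic), development ~30 days with small treatment,
sex and extra-molt shifts, femur ~20 mm. Eggs per pod are Poisson by
default; the count's true distribution is not established, so a
negative-binomial switch (`egg_dist = "nbinom"`) is available for
overdispersed designs. `example_sim_configs()` instantiates four
populations (8, 8, 7 and 6 families) with loads 1.1, 3.8, 3.9 and 4; the
field-derived population gets a zero parthenogenetic laying probability,
reproducing the situation where a population contributes no
parthenogenetic hatching data and the load is reported as not estimable.

Reproducibility: every population consumes its own RNG stream derived
deterministically from the master seed and the population name, so adding
or removing a population never perturbs the others, and identical
configurations give byte-identical tables.

What the simulator does **not** capture — and hence what passing tests do
not establish about real data: shared maternal load among siblings (eggs
are exchangeable), purging across generations, linkage, maternal effects
on pod quality, phase polyphenism, and any inbred/outbred hatching
difference *not* mediated by the Poisson lethal model. In particular,
because simulated hatching follows $e^{-BF}$ by construction, simulated
inbred hatching always matches the model's prediction; the
predicted-versus-observed comparison only becomes informative on real
data.

## Genotype simulation and the population-genetic statistics

`simulate_genotypes()` draws diploid multilocus genotypes with a target
within-population inbreeding coefficient. For `f_is >= 0` the draw is
mechanistic identity-by-descent: with probability `f_is` one allele is
drawn and duplicated, otherwise two independent draws. For `f_is < 0`
(heterozygote excess) genotypes are sampled exactly from the genotype
distribution $P(ii) = p_i^2 + F p_i(1-p_i)$,
$P(ij) = 2 p_i p_j (1 - F)$; configurations implying a negative
homozygote probability are rejected at validation. Either way the expected
observed heterozygosity is $(1 - F)$ times the gene diversity, so large
samples recover the configured `f_is`.

The summary statistics follow standard estimators:

* **Expected heterozygosity**: unbiased gene diversity
  $\frac{N}{N-1}(1 - \sum_i p_i^2)$ with N non-missing gene copies —
  equivalently, the probability that two copies drawn *without
  replacement* differ, which is how the test-suite oracle computes it by
  enumeration.
* **F_IS**: multilocus $1 - \sum_\ell H_{O,\ell} / \sum_\ell H_{E,\ell}$
  (ratio of sums; a mean of per-locus ratios lets near-monomorphic loci
  dominate). Monomorphic loci are excluded; per-locus values are also
  reported.
* **Allelic richness**: hypergeometric rarefaction
  $\sum_i [1 - \binom{N-N_i}{g} / \binom{N}{g}]$, computed via `lchoose`
  to avoid overflow. The rarefaction size g defaults per locus to the
  smallest non-missing gene-copy count across populations — the standard
  reporting convention; with unequal samples any other g changes the
  values, which is why published richness values cannot be matched
  without knowing the g used.
* **F_ST**: Weir & Cockerham's (1984) θ, the default of the common
  microsatellite packages and the field standard, aggregated ratio-of-sums
  over alleles and loci; negative estimates are reported as computed. The
  tests cross-check it against an independent indicator-variable nested
  ANOVA on the raw gene copies.

Missing genotypes are excluded locus-wise (an individual missing at one
locus still contributes elsewhere), never list-wise. GENEPOP input
auto-detects the 2- and 3-digit dialects; output writes 3-digit codes with
`Pop` separators and zero-coded missing data.

## Design choices that were genuinely open

* **The model's F-generalisation.** The Poisson argument is usually stated
  for fully homozygous offspring (F = 1); extending it to arbitrary F via
  independent per-lethal exposure yields the Morton–Crow–Muller form
  $e^{-BF}$, the only form consistent with using one B for both the
  parthenogenetic (F = 1) estimate and the full-sib (F = 1/4) prediction.
* **Pod-level bootstrap** rather than an egg-level binomial interval:
  pods are the natural resampling unit and the bootstrap is agnostic to
  overdispersion between pods.
* **Laying proportions need a females table.** Pod records alone cannot
  distinguish a female that laid nothing from one that was never
  isolated, so the simulator emits (and `summarize_treatments()` accepts)
  a one-row-per-female table; without it laying proportions are `NA`.
* **Discrepancy flag.** `run_load_inference()` flags a population when its
  observed inbred relative hatching falls outside
  $[e^{-B_{hi}/4}, e^{-B_{lo}/4}]$, the bootstrap interval mapped through
  the prediction — a pragmatic operationalisation of "observed differs
  from predicted" that inherits the bootstrap's coverage.

## Validation problem sizes

The test suite uses: a B × F grid of 861 points for the round-trip
identity (tolerance 1e-12); 10^6 mechanistic egg draws per (B, F) case for
oracle agreement; 200 replicate experiments of 200 pods × 50 eggs with
1000 bootstrap replicates each for parameter recovery and interval
coverage; toy genotype tables of ≤ 6 individuals × 2 loci for exact
(1e-12) agreement with enumeration oracles; and 10^4 individuals × 6 loci
for F_IS recovery. These sizes were chosen so each check's Monte-Carlo
error is far below its assertion tolerance.

## Limitations

B is identified only relative to outbred hatching, confounds lethal and
severe-detrimental load, and is a population-level scalar: family
variation in load, purging history and maternal effects all end up in the
bootstrap interval rather than the model. A population whose
parthenogenetic eggs all fail yields $\hat B = \infty$ — an honest
statement that hatching data alone cannot bound the load from above, and
often a hint that development, not load, is the barrier.
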