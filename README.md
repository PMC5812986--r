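# dmrscan

Statistical machinery for two-group RRBS + RNA-seq studies of inherited
dietary effects — for example, comparing liver methylomes and
transcriptomes of offspring whose parents received a control diet versus
one deficient in one-carbon nutrients (folate, B12, B6, methionine,
choline). The package is aimed at analysts who have per-CpG
methylated/total read counts for a handful of replicates per group and
want region-level discovery with honest, permutation-based error control.

## What it computes

**Per-CpG differential methylation.** A beta-binomial Wald test: group
proportions are pooled count ratios, and the variance follows
`t·μ(1−μ)(1+(t−1)φ)/t²` summed over samples, with the per-site dispersion
φ estimated by moments and shrunk toward the genome-wide trimmed mean with
a coverage-dependent weight. Two-sided normal p-values, BH q-values.

**Running-sum DMR calling.** Coverage-filtered CpGs (≥10 reads in every
sample) get a one-way ANOVA f-statistic of methylation proportions
(between- over within-group variance). The genome is traversed and scored
as

    s_i = max(0, s_{i−1} + log2(f_i / mean f) − p·(d_i − d_{i−1}))

with separation penalty `p = 0.02` per bp. A region is emitted whenever
the score returns to zero after being positive, spanning its first CpG
through the maximal-score CpG.

**Permutation empirical FDR.** The full per-feature analysis is re-run
under exhaustive (`C(12,6) = 924` labelled assignments for 6 vs 6) or
random group-label permutations; the empirical FDR is the mean null
discovery count over the observed count. The per-feature test is injected
as a function, so the same engine calibrates both the methylation test and
the expression test (a Welch t-test on `log2(FPKM + 1)`).

**Genomic context.** Strand-aware promoters, islands, shores, introns and
intergenic space; Fisher-exact feature enrichment of DMLs; hypergeometric
enrichment in 1 kb windows around TSSs with Holm adjustment; nested
TSS-window methylation matrices with centred, unscaled PCA and exact
Mann–Whitney / Welch segregation tests; nearest-gene assignment within
40 kb; directional (down-regulated) hypergeometric gene-set enrichment
with expression-matched backgrounds.

**Synthetic data with ground truth.** `simulate_annotation()`,
`simulate_methylome()` and `simulate_expression()` generate a bimodal
methylome (~80% of sites >80% methylated, ~6% <10%), a TSS methylation
dip with island-boosted RRBS-like coverage, planted differentially
methylated CpGs near promoters and a predominantly down-regulated planted
gene module — so every pipeline stage can be validated against known
truth.

## Worked example

```r
library(dmrscan)

cfg <- sim_config(seed = 1)             # 6 vs 6 design, 100 planted DMLs
mod <- simulate_annotation(cfg)
sim <- simulate_methylome(mod, cfg)

res <- dml_test(sim$table)              # beta-binomial Wald test
sum(res$q < 0.05, na.rm = TRUE)
#> [1] 97

dmr <- find_dmrs(sim$table)             # f-track + running-sum caller
nrow(dmr$dmrs)
#> [1] 415

asg <- random_assignments(sim$table$samples$group, n = 100, seed = 2)
meth_fun <- function(data, labels) {
  d <- data; d$samples$group <- labels; dml_test(d)$p
}
permutation_discovery_counts(sim$table, meth_fun, asg,
                             threshold_kind = "q", threshold = 0.05)
#> permutation_summary: observed = 97 ( q < 0.05 )
#>   mean null = 0.46  empirical FDR = 0.004742

h <- methylation_histogram(filter_by_coverage(sim$table))
round(c(high = h$fraction_high, low = h$fraction_low), 3)
#>  high   low
#> 0.795 0.061
```

Reading: the test finds 97 sites at q < 0.05 of which 91 are planted truth;
random label permutations of the same data yield on average 0.46
discoveries, so the empirical FDR of the observed discovery set is ~0.005.
The pooled methylation histogram reproduces the bimodal landscape the
generator was configured for.

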