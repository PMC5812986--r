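---
title: "Differential methylation with running-sum DMR calling and permutation FDR"
author: "dmrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation with running-sum DMR calling and permutation FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrscan)
```

## The problem this package addresses

Parental nutrition can leave molecular marks in offspring. A typical study
design compares two groups of sibling animals whose parents received either
a sufficient or a deficient diet in one-carbon (1-C) nutrients — folate,
vitamin B12, vitamin B6, methionine and choline — the dietary inputs of the
methyl-donor cycle that supplies S-adenosylmethionine for DNA methylation.
The molecular readouts are reduced representation bisulfite sequencing
(RRBS) of offspring livers (six animals per feed group, per-CpG methylated
and total read counts) and RNA-seq (four animals per group, FPKM-like
abundances).

Both assays pose the same inference problem: with six (or four) biological
replicates per group, per-feature p-values from any parametric model rest on
assumptions that are hard to verify, and a group difference could in
principle reflect any unknown factor that co-segregates with the groups.
The machinery in this package addresses that by (i) modelling per-CpG
counts with a beta-binomial law whose dispersion is stabilised by shrinkage,
(ii) aggregating evidence along the genome with a running-sum region score,
and (iii) calibrating every discovery count against an empirical null
obtained by re-running the *entire* analysis under permuted group labels.

## The models and procedures

### Per-CpG beta-binomial Wald test

At one CpG, sample $j$ in group $g$ contributes $m_{gj}$ methylated reads of
$t_{gj}$ total. Counts are modelled as beta-binomial: binomial with success
probability varying between replicates around the group mean $\mu_g$ with
dispersion $\varphi$, so that
$\mathrm{Var}(m_{gj}) = t_{gj}\,\mu(1-\mu)\,[1 + (t_{gj}-1)\varphi]$.
The group proportion estimate is the pooled ratio
$\hat\mu_g = \sum_j m_{gj} / \sum_j t_{gj}$, and the Wald statistic is

$$ z = \frac{\hat\mu_2 - \hat\mu_1}{\sqrt{\widehat{\mathrm{Var}}(\hat\mu_1)
      + \widehat{\mathrm{Var}}(\hat\mu_2)}}, \qquad
   \widehat{\mathrm{Var}}(\hat\mu_g) = \mu_0(1-\mu_0)\,
   \frac{T_g + \hat\varphi \sum_j t_{gj}(t_{gj}-1)}{T_g^2}, $$

with $T_g = \sum_j t_{gj}$ and two-sided normal p-values, followed by
Benjamini–Hochberg adjustment. Two numerical choices matter here:

* **Pooled mean in the variance.** $\mu_0(1-\mu_0)$ uses the *two-group*
  pooled mean rather than per-group means. With per-group means, a site
  monomorphic in one group (all zero or all full methylation) would get a
  zero variance contribution and an infinite statistic from a single stray
  read in the other group. The pooled form keeps the statistic total and,
  because $\mu_0$ lies between the group means, costs essentially nothing
  in power. Identical counts in both groups still give $z = 0$, $p = 1$.
* **Dispersion shrinkage.** The per-site method-of-moments estimate
  $\hat\varphi$ (from the spread of per-sample proportions, corrected for
  binomial sampling noise) is noisy at 12 samples. It is shrunk linearly
  toward the trimmed mean $\bar\varphi$ of all finite per-site estimates,
  with weight $w = T/(T + T_0)$ growing in the site's total coverage $T$;
  $T_0 = 1000$ reads by default, i.e. a site needs on the order of a
  thousand reads before its own estimate dominates. Negative moment
  estimates are clamped to zero; inestimable sites receive $\bar\varphi$.
  Sites with zero total coverage in either group are flagged and skipped,
  not guessed at.

The test is deliberately *not* a port of any published package: it is a
re-specified Wald test without spatial smoothing, because the region-level
aggregation below and the permutation layer are the calibration devices of
this workflow.

### The f-statistic track and running-sum DMR score

For region detection each coverage-filtered CpG (total reads $\ge 10$ in
*every* sample, the same filter used for the methylation PCAs) receives a
one-way ANOVA f-statistic of the per-sample methylation *proportions*:
between-group mean square over within-group mean square. Proportions, not
counts, are used so that a deeply covered sample does not dominate the
variance decomposition. When the within-group variance is exactly zero the
statistic is capped at $1/\varepsilon$ with $\varepsilon = 10^{-8}$; capped
sites are flagged and excluded from the track mean $\overline{f}$, which
must stay finite because the score works on log-ratios.

The genome is then traversed per chromosome and the score at the $i$-th CpG is

$$ s_i = \max\!\left(0,\; s_{i-1} + \log_2\!\frac{f_i}{\overline{f}}
        - p\,(d_i - d_{i-1})\right), $$

where $d_i$ is the genomic position and $p$ the separation penalty
(default 0.02 score units per bp). A region is emitted each time the score
returns to zero after having been positive (plus a flush at the chromosome
end); it spans its first CpG through the CpG attaining the maximal score,
which is also the region's score. Boundary and degenerate policies:

* At each chromosome's first CpG the gap term is dropped
  ($d_{i-1}$ is undefined), so $s_1 = \max(0, \log_2(f_1/\overline{f}))$.
  Everywhere else — including the step that restarts a run after
  $s_{i-1} = 0$ — the literal recursion applies, gap penalty included.
* Sites with $f = 0$ contribute a log-ratio clamped at $-10^9$, which
  resets the score; capped-infinite f enters with its capped value. This
  keeps the arithmetic total without special cases.
* An equivalent closed form, used as the test oracle, is that $s_i$ is the
  best zero-clipped window sum ending at $i$ of the per-site contributions
  (log-ratio minus gap penalty). The package's unit and acceptance tests
  verify exact agreement with an $O(n^2)$ direct maximization on hundreds
  of random tracks, and the Kadane maximum-subarray limit at zero penalty.
* No significance is attached to a region score; region evidence is
  interpreted through the permutation layer.

### Permutation calibration and empirical FDR

`enumerate_group_assignments()` produces all labelled assignments
preserving group sizes — $\binom{12}{6} = 924$ for the 6 vs 6 RRBS design,
$\binom{8}{4} = 70$ for the 4 vs 4 expression design — each annotated with
a composition class ("true", "3+1", "2+2", ...) describing how many samples
of one true group travel together. `random_assignments()` instead draws
label permutations with `sample()`, uniformly and with replacement.

`permutation_discovery_counts()` re-runs an *injected* per-feature test
under every assignment and counts discoveries at a stated p- or q-value
threshold; the same engine therefore serves the expression test and the
methylation test. The empirical false discovery rate is the mean null
count divided by the observed count. Two design choices are worth noting:

* For random permutation sets, draws that happen to equal the true
  assignment are kept in the null summary (a draw is a draw; exclusion is
  available via `include_true_in_null = FALSE`). For exhaustive
  enumerations the two assignments reproducing the true partition are
  excluded from the null mean.
* An observed count of zero leaves the ratio undefined; the function
  returns `NA` rather than a misleading number.

### Expression analysis

The per-gene test is a Welch t-test on $\log_2(\text{abundance}+1)$ —
a declared plumbing test standing in for a full count model, isolated
behind the injected-test interface precisely so the permutation engine is
method-agnostic. Genes with zero variance in both groups get $p = 1$.
Volcano classification uses strict thresholds (fold change $> 2$,
$q < 0.05$). K-means clustering of log-transformed profiles
(`stats::kmeans`, seeded, multiple restarts) summarises expression
patterns; cluster mean profiles are min–max scaled by row as displayed in
heat maps. Directional gene-set enrichment is the upper-tail
hypergeometric probability (`stats::phyper`) of the observed number of
significant down-regulated genes in a set, and
`expression_matched_background()` draws per-expression-decile matched
non-target genes so enrichments can be checked against an
expression-matched control universe.

### Genomic context

Feature sets are derived with GenomicRanges: strand-aware promoters
(5000 bp upstream of the TSS), island shores (within 5000 bp of a CpG
island but outside any island), introns (transcript minus exon space) and
intergenic regions (further than 50000 bp from any transcript). Feature
categories deliberately overlap; each is tested independently with a
two-sided Fisher exact test of the DML/non-DML by inside/outside table,
reported with $\log_2$ enrichment ratios. Overlapping 1000 bp windows
either side of the TSS are tested with upper-tail hypergeometric
probabilities against the global DML rate and Holm-adjusted over exactly
the non-empty windows.

TSS-window methylation matrices average per-site methylation levels
(unweighted; a coverage-weighted variant was considered and rejected so
that a single deep site cannot dominate a window) over all CpGs within
nested extents of each TSS — eight per side, 600 to 4800 bp in 600 bp
steps by default; the extents are configurable because no canonical set
exists. A CpG near several TSSs contributes to each window it falls in.
Each window's samples-by-TSS matrix enters a centred, *unscaled* PCA
(`prcomp(scale. = FALSE)`; methylation levels share a scale, so variance
weighting is meaningful), and PC1 scores are compared between groups with
a Welch t-test and an exact Mann–Whitney U test. Complete separation of
6 vs 6 samples on PC1 has exact two-sided MWU p-value
$2/\binom{12}{6} = 2/924 \approx 0.00216$.

Nearest-gene assignment links regions to genes within 40 kb (distance
measured from the region span, not the peak; ties resolve to the smaller
gene start), and `promoter_meth_expr_association()` reports the Spearman
correlation between promoter methylation and mean log expression with a
permutation p-value.

## What the synthetic generator emulates — and what it does not

Every stage above is exercised against `simulate_annotation()`,
`simulate_methylome()` and `simulate_expression()`, which provide known
ground truth. The generator reproduces the *structure* of RRBS data:

* a strongly bimodal latent methylation mixture (Beta components for
  high/low/intermediate sites). The latent high-class weight defaults to
  0.86 so that, after the TSS dip reassigns promoter-proximal sites, the
  realized genome-wide profile is close to 80% of sites above 0.8 and 6%
  below 0.1 methylation;
* a multiplicative methylation dip within ±200 bp of TSSs (factor 0.25);
* negative-binomial coverage (mean 30, size 8) tripled inside CpG islands,
  emulating RRBS enrichment for CpG-dense sequence, with islands
  preferentially centred on TSSs (70% by default);
* planted differentially methylated CpGs near promoters with a
  configurable group difference (default $\Delta\beta = 0.3$, half
  hyper-, half hypomethylated), and an optional coherent upstream
  methylation shift for PCA power studies;
* beta-binomial count noise with dispersion $\varphi = 0.03$, a moderate
  level of biological replicate variability for inbred-line liver tissue;
* log-normal expression baselines with 100 planted differentially
  expressed genes at $|\log_2 \mathrm{FC}| = 2$, 68% of them
  down-regulated in the treatment group, mirroring the predominance of
  down-regulation such studies report.

It does **not** model read-level artefacts (no FASTQ simulation),
bisulfite conversion failure, non-CpG methylation, strand effects,
sample-level random effects beyond the beta-binomial law, or correlated
methylation between neighbouring CpGs outside the planted effects. Passing
tests therefore demonstrate the correctness and calibration of the
*statistics* under a faithful null and planted alternatives — they do not
certify performance on real libraries, where covariate structure and
spatial correlation are richer.

Determinism: one master seed governs each generator run, with fixed
sub-stream seeds per stage so that, e.g., the methylome can be regenerated
without re-drawing the annotation.

## Problem sizes used by the test suite

The packaged checks run on deliberately desk-scale data chosen to leave
the statistical questions intact: 5000-site null methylomes across 20
seeds for FDR and type-I calibration (with 20 random permutations each),
a 4000-site methylome carrying 100 planted DMLs at $\Delta\beta = 0.3$ and
coverage 30 for recovery and excess-over-null checks (100 permutations),
8000-site genomes for the TSS-window PCA power study, the full default
20000-site genome for generator fidelity, 200 random tracks for the DMR
oracle equivalence, and exhaustive enumeration of every 2×2 table with
$N \le 20$ for the Fisher/hypergeometric tails.

## Known limitations

* The Wald test's normal approximation thins out at very low coverage;
  sites are reported but their q-values lean on the permutation layer for
  honest calibration.
* DMR scores carry no intrinsic significance, matching their intended use
  as a ranking device; adjacent regions are not merged.
* The expression test is a plumbing test; effect sizes for counts near
  zero are compressed by the pseudocount.
* The hypergeometric gene-set tests condition on the chosen background;
  the package defaults leave the background to the caller because no
  universal choice exists.
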