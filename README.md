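# riboapa

Differential translation efficiency and poly(A)-site usage from count
data, for people analysing ribosome profiling (Ribo-seq) and 3'-end
RNA-seq experiments.

## The statistical core

**Translation efficiency (TE)** of a transcript in a sample is modelled as
the odds of drawing a ribosome-protected-footprint (RPF) read rather than
an RNA read from that transcript's pooled reads:

    log TE = log(RPF/RNA) = α + Σᵢ βᵢ Xᵢ

fitted per transcript by binomial logistic regression on the sample
covariates Xᵢ — any number of groups, replicates, batch indicators or
continuous predictors. The translation-efficiency ratio between two
covariate settings is

    TER = TE₂/TE₁ = exp{ Σᵢ βᵢ (Xᵢ,₂ − Xᵢ,₁) }

reported with raw and BH-adjusted p-values. For two unreplicated samples
the fitted contrast equals the 2×2 log odds ratio, and chi-square/Fisher
tests on that table are built in as a cross-check (`ter_2x2()`). For
replicated designs a quasi-binomial dispersion correction
(`dispersion = TRUE`) keeps the test calibrated when counts are
overdispersed. Optionally, codon-level RPF profiles are first cleaned of
ribosome-stalling peaks: profiles are smoothed by a deterministic local
tricube-weighted linear fit over a ±5-codon window, each codon's excess
over the transcript's background median is summarized across samples by a
geometric mean into a bias coefficient b, and smoothed counts are divided
by b and re-summed (`correct_stalling()`).

**Poly(A)-site usage** is tested per transcript by baseline-category
multinomial logistic regression on site counts,
`log(Alt.site/Ref.site) = α + Σ βᵢXᵢ`, in three modes: one overall
deviance test per transcript, every site against a reference site, or all
pairwise site comparisons (`apa_test()`). The headline effect size is
**logAPAR**, the log fold change in proximal-to-distal usage; positive
values mean a shift toward the proximal site in the second condition, so
3' UTR lengthening shows up as negative logAPAR (`compute_logapar()`).

Supporting modules: median-of-ratios normalization
(`normalize_counts()`), equally-populated-bin target-set enrichment
with hypergeometric or logistic per-bin tests and permutation
mutual-information z-scores (`enrichment_analysis()`), Wilcoxon rank-sum
association (`rank_association()`), and seeded synthetic-data generators
with known ground truth (`simulate_ribo()`, `simulate_apa()`).

## Worked example

```r
library(riboapa)

sim <- simulate_ribo(list(n_transcripts = 300, effect_fraction = 0.1),
                     seed = 7)                       # 10% planted at logTER = ln 2
fit <- ter_test(normalize_counts(sim$rpf), normalize_counts(sim$rna),
                sim$design, dispersion = TRUE)
tab <- ter_table(fit, "group=A,B")
head(tab[order(tab$p), c("transcript_id", "logTER", "TER", "p", "fdr")], 5)
#>     transcript_id  logTER    TER        p    fdr
#> 31         tx0031 -0.6199 0.5380 0.002861 0.5744
#> 148        tx0148 -0.7695 0.4633 0.005963 0.5744
#> 16         tx0016  0.4985 1.6462 0.007929 0.5744
#> 237        tx0237  0.8395 2.3153 0.008515 0.5744
#> 255        tx0255  0.9926 2.6983 0.013224 0.5744
```

`logTER` is the fitted log fold change in TE between groups B and A
(`TER = exp(logTER)`; tx0031's TE halves, tx0255's almost triples), `p`
the dispersion-corrected Wald p-value and `fdr` its BH adjustment. Where
do the planted transcripts end up? Bin the logTER values and test the
known effect set:

```r
enr <- enrichment_analysis(setNames(tab$logTER, tab$transcript_id),
                           sim$truth$transcript_id[sim$truth$effect],
                           nbins = 10, n_perm = 1000, seed = 7)
enr$table[c(1, 10), c("bin", "n", "n_targets", "direction", "p", "padj")]
#>    bin  n n_targets direction        p     padj
#> 1    1 30         0  depleted 3.56e-02 5.09e-02
#> 10  10 30        19  enriched 3.66e-15 3.66e-14
c(mi = enr$mi, z = enr$z)
#>      mi       z
#> 0.2172  17.31
```

19 of the 30 planted transcripts land in the top logTER bin
(hypergeometric adjusted p = 3.7e-14), and the global mutual information
between bins and membership is 0.217 bits, 17 permutation standard
deviations above the null.

The same pipeline runs from the shell via the installed `exec/riboapa`
script (`simulate`, `normalize`, `debias`, `ter`, `apa`, `enrich`
subcommands), with every stage reading the previous stage's TSV output.

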