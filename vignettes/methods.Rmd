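---
title: "Models and methods in riboapa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in riboapa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboapa)
```

# Overview

`riboapa` tests two kinds of per-transcript regulatory change from count
data: differential translation efficiency from paired ribosome-profiling
(RPF) and RNA-seq counts, and differential poly(A)-site usage from 3'-end
counts. Both are cast as logistic regressions on read counts, which keeps
the number of distributional assumptions small: no parametric model is
imposed on the *ratio* of two count variables, only on the conditional
odds of read types.

# Translation-efficiency ratio (TER) test

Translation efficiency (TE) for a transcript in a sample is modelled as the
odds of drawing an RPF read rather than an RNA read when sampling from the
pooled reads of that transcript:

$$\log TE = \log\frac{RPF}{RNA} = \alpha + \sum_i \beta_i X_i$$

with sample covariates $X_i$ (group labels, batch indicators, continuous
measurements). The model is fitted per transcript by maximizing the
binomial likelihood in which each sample contributes its RPF count as
successes and its RNA count as failures; modelling each read as a Bernoulli
draw gives a proportional likelihood, so the aggregated binomial fit yields
the identical MLE at a fraction of the cost. Between two covariate settings,

$$TER = TE_2 / TE_1 = \exp\Big\{\sum_i \beta_i (X_{i,2} - X_{i,1})\Big\},$$

reported as `logTER`/`TER` by `ter_table()`. In the degenerate case of two
unreplicated samples the fitted contrast equals the log odds ratio of the
2x2 (sample x read-type) table, and `ter_2x2()` provides the chi-square and
Fisher tests on that table as a built-in cross-check.

Counts enter after median-of-ratios normalization (`normalize_counts()`),
separately for the RNA and RPF matrices, and may be real-valued (normalized
or stalling-debiased); they are used as likelihood weights without
rounding, since rounding would introduce depth-dependent bias.

## Overdispersion

The plain binomial model treats replicates as resamples of the same pool.
Biological replicates are more variable than that: with negative-binomial
counts at dispersion $\phi$, the per-sample log TE carries extra variance
of roughly $2\phi$ that the binomial likelihood does not see, and Wald
p-values become aggressively anticonservative (at $\phi = 0.1$ and typical
depths the nominal 5% test rejects the majority of true nulls). For
replicated designs `ter_test(dispersion = TRUE)` therefore applies the
standard quasi-binomial treatment: standard errors are inflated by
$\sqrt{\max(1, X^2_{Pearson}/\mathrm{df})}$ and p-values use a
$t$-reference with the residual degrees of freedom. This restores nominal
size (verified by simulation in the test suite) at the cost of power when
replication is minimal — with 3 vs 3 samples and 4 residual df, effects
near 2-fold are estimated accurately but rarely reach small adjusted
p-values; the calibration, not the power, is the design goal at that scale.
The uncorrected test remains the default flag value because it is the
literal model; use the flag whenever replicates exist.

Defaults: `min_total = 10` (a transcript is untestable if RPF+RNA falls
below 10 in any sample); `pseudocount = 0`, with `"auto"` adding Haldane's
0.5 only when a zero cell occurs; a fitted |coefficient| above 10 flags
separation and switches that transcript's p-values to a drop-one
likelihood-ratio test, since Wald inference collapses under separation.
Benjamini–Hochberg correction is applied across testable transcripts
("corrected P" is not otherwise specified by the modelling framework; BH
is the field standard).

# Stalling-bias correction

Ribosome stalling (suboptimal codons, RNA structure, RBP obstruction)
creates local RPF peaks that inflate a transcript's footprint total
without reflecting its translational output; left in place they
overestimate TE. `correct_stalling()` measures and removes this bias:

1. Each per-sample codon profile is smoothed by a deterministic local
   linear regression with tricube weights over a fixed window of
   $\pm r$ codons ($r = 5$ by default). Parameterizing the neighbourhood
   by a codon radius, not a span fraction, keeps the window physically
   constant across transcripts; smoothing borrows strength from adjacent
   codons because stalling affects several neighbouring codons and P-site
   assignment is itself uncertain by a few codons. The smoother is exact
   for constant and linear profiles and clips predictions at zero.
2. The per-sample background is the median of the non-zero smoothed
   counts. The bias coefficient at codon $i$ of transcript $j$ is the
   geometric mean across the $K$ pooled samples of the smoothed-to-background
   ratio: $b_{ij} = (\prod_k y^l_{ijk}/M^l_{jk})^{1/K}$ (the printed
   exponent is read as $1/K$, the only dimensionally consistent reading of
   a geometric mean over samples).
3. Smoothed counts are divided by $b_{ij}$ and re-summed into debiased
   transcript x sample counts ($y^{l,C}_{jk}$), ready for `ter_test()`.

Numerical and policy choices: codons where any pooled sample has a zero
smoothed count (or a zero background) keep $b = 1$ — no correction is
manufactured where there are no reads, and no epsilon floor is used;
by default $b$ is applied in both directions (valleys are inflated), with
`clip_at_one = TRUE` restricting correction to peaks only; coefficients are
computed from raw codon counts, which is immaterial for $b$ itself (the
ratio is scale-invariant per sample) and only affects the scale of
exported debiased counts; when group-specific coefficients are requested
the same group subset is used for the backgrounds. Pooled coefficients
cancel partially between conditions, so condition-specific stalling is
*attenuated* rather than removed (the simulation in the test suite shows
the planted TE bias shrinking by roughly a third at the default radius);
full removal of condition-specific stalling requires group-specific
coefficients.

# Poly(A)-site usage (APA) test

For each transcript with $S \ge 2$ annotated poly(A) sites,
`apa_test()` fits a baseline-category multinomial logistic regression

$$\log\frac{\mathrm{Alt.site}}{\mathrm{Ref.site}} = \alpha + \sum_i \beta_i X_i$$

by Newton–Raphson on the exact multinomial likelihood (tolerance $10^{-10}$
on the coefficient step, 100-iteration cap, step-halving, |coefficient|
capped at 15 before a separation flag). Counts may be real-valued (e.g.
EM-apportioned 3'-end quantifications). Three modes:

* **overall** — one deviance test per transcript against the
  intercept-only model, $\chi^2$ with $(S-1) \times p$ df ($p$ =
  non-intercept covariates). One test per transcript keeps multiple-testing
  correction unentangled from the varying number of sites.
* **reference** — every non-reference site against a reference site
  (alphabetically first by default, or the most proximal, or
  user-specified), Wald z per site and covariate.
* **pairwise** — a binomial logistic fit for every unordered pair,
  the highest-resolution view; samples with a zero pair total are dropped
  from that pair and flagged.

At $S = 2$ all three modes coincide; the suite verifies the multinomial
fit equals the binomial fit to $10^{-8}$ and that the overall deviance on a
2x2 example equals the hand-computed G statistic.

`compute_logapar()` reports **logAPAR**, the log fold change in
proximal-to-distal usage: the condition coefficient of the pairwise fit
oriented as $\log(\mathrm{proximal}/\mathrm{distal})$. Sign convention,
fixed here because the quantity's algebraic sign is otherwise ambiguous:
**positive logAPAR means relatively more proximal usage at the second level
of the contrast**; 3' UTR lengthening (a proximal-to-distal switch)
appears as negative logAPAR. Natural log by default (`log2_scale` for
display in log2). By default the most proximal and most distal sites are
paired ("extreme"); `pairs = "adjacent"` tests every rank-adjacent pair
instead — which pair a headline logAPAR should use is a genuine judgement
call, so both are provided and the default documented. PAS counts are
median-of-ratios normalized across the site x sample matrix before
fitting; within-transcript proportions are scale-invariant, so this
matters mainly when absolute usage is inspected.

Site ranks (1 = most proximal, i.e. nearest the stop codon along the
transcript) come from a BED6 of site positions, strand-aware: on the minus
strand the largest genomic coordinate is the most proximal. Without a BED,
ranks fall back to lexicographic site-ID order, with a warning.

# Binned target-set enrichment

`enrichment_analysis()` produces the binned summary commonly drawn above volcano plots: transcripts
are ranked by a statistic (logTER or logAPAR) and split into equally
populated bins (default 10, matching the granularity such figures usually
show; sizes differ by at most one, ties broken by stable transcript-ID
order). Per bin, over/under-representation of a target set is tested by
two one-sided hypergeometric tails (the smaller is reported with its
direction) or by logistic regression of membership on the bin indicator;
BH correction is applied across bins. Global association is summarized by
plug-in mutual information (base 2) between bin and membership — no
pseudocounts, zero cells contribute zero — standardized against a seeded
permutation null of the membership labels (default 1,000 permutations).
`rank_association()` provides the complementary Wilcoxon rank-sum
comparison of a statistic between annotated and background features
(exact for small untied samples, normal approximation with tie correction
otherwise).

# Synthetic data

The generators define the regime in which the statistical guarantees are
demonstrated and power all tests:

* `simulate_ribo()`: RNA counts are negative binomial
  (variance $\mu + \phi\mu^2$, $\phi = 0.1$, the common bulk RNA-seq
  regime) around a log-normal baseline (meanlog $\log 300$, sdlog 0.5, so
  that typical depths sit in the few-hundreds-per-transcript range where
  TER testing is realistic); RPF counts multiply in baseline TE odds, a
  planted group effect ($e^{logTER}$, default $\ln 2$ in a chosen
  fraction), and, for transcripts given stalling spikes, the deterministic
  total inflation $(L - m + f\,m)/L$ for $m$ spiked codons at fold $f$
  (default 5 codons at 10x on a 200-codon CDS, spikes in one condition
  only). Codon profiles are drawn multinomially conditional on the
  transcript totals, so matrix and profile views agree by construction.
  Default design: 3 vs 3 samples, equal depths.
* `simulate_apa()`: 2–4 sites per transcript, baseline usage from a
  symmetric Dirichlet($\alpha = 2$), a condition-B log-odds shift
  $\delta$ (default 1) on the proximal site for a chosen fraction of
  transcripts, multinomial sampling at 500 reads per site, 2 vs 2 samples
  (duplicates being the norm for such experiments).

Both generators take one explicit seed, restore the caller's RNG state,
and are bit-reproducible. What they deliberately do not model: positional
read distributions beyond flat-plus-spikes, sequence content, isoform
mixtures, or correlated dispersion across transcripts — so passing tests
demonstrate correctness of the estimators and calibration under the
assumed count model, not robustness to every artefact of real libraries.

Two empirical notes from these conditions, both visible in the test suite:
median-of-ratios normalization absorbs a few percent of a strictly
one-sided planted effect (the size-factor median shifts when 10% of
transcripts move in the same direction), so recovered mean logTER sits
slightly below the planted $\ln 2$; and at 3 vs 3 with $\phi = 0.1$ the
dispersion-corrected test has little power at 2-fold effects, so
BH-selected discovery lists are short at this scale.

# Command-line interface

`riboapa_main()` (installed as `exec/riboapa`) exposes `simulate`,
`normalize`, `debias`, `ter`, `apa` and `enrich` subcommands whose TSV
outputs are each other's inputs, so whole analyses compose through files;
every stochastic subcommand requires `--seed`, and each run writes a small
log (package version, parameters, seed, input MD5 checksums) beside its
main output. All thresholds discussed above are exposed as flags.

# Worked example

```{r example}
sim <- simulate_ribo(list(n_transcripts = 300, effect_fraction = 0.1),
                     seed = 7)
fit <- ter_test(normalize_counts(sim$rpf), normalize_counts(sim$rna),
                sim$design, dispersion = TRUE)
tab <- ter_table(fit, "group=A,B")
head(tab[order(tab$p), ], 5)

enr <- enrichment_analysis(setNames(tab$logTER, tab$transcript_id),
                           sim$truth$transcript_id[sim$truth$effect],
                           nbins = 10, n_perm = 1000, seed = 7)
enr$table[, c("bin", "n", "n_targets", "direction", "p", "padj")]
c(mi = enr$mi, z = enr$z)
```

# Known limitations

* The quasi-binomial dispersion estimate is per-transcript with few
  residual df; no information is shared across transcripts (no empirical
  Bayes shrinkage), which costs power at minimal replication.
* Pooled stalling coefficients attenuate but do not remove
  condition-specific stalling; use `groups` for group-specific
  coefficients when stalling itself differs between conditions.
* The overall APA deviance test relies on the $\chi^2$ asymptotics of the
  multinomial LRT; at very low per-site counts it becomes conservative.
* Isoform choice is upstream: one representative transcript per gene is
  assumed to have been selected before counting.
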