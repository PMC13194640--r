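---
title: "Methods: cross-model knockdown concordance and survival screening"
author: "kdconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-model knockdown concordance and survival screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdconcord)
```

## The problem this package addresses

When a candidate gene is silenced in two cell-line models with different
histologic backgrounds, the transcriptional response mixes three things:
baseline differences between the lines, a shared knockdown program, and
line-private noise. `kdconcord` implements a complete, deterministic pipeline
for isolating the shared program — normalisation, cell-line-adjusted PCA,
per-line differential expression, a cross-model concordance filter, preranked
gene set enrichment, and condition-level module matrices — together with the
survival statistics (Kaplan–Meier, log-rank, dichotomised hazard ratios, a
multi-gene screen) used to ask whether a gene family's expression predicts
patient outcome. A negative-binomial count simulator and an exponential
survival simulator provide data with exactly the structure the analysis
assumes, so every stage is testable offline.

## Expression model and stage-by-stage procedure

**Normalisation.** For each sample, raw counts are divided by the library
size (the column sum over *all* features, taken before any biotype
restriction) and scaled to counts per million (CPM). Expression values are
`log2(CPM + 1)`; a value is zero exactly when the raw count is zero. No
between-sample normalisation beyond CPM is applied (no TMM or quantile step)
and no low-count filter is used: lowly expressed genes carry little variance
and do not steer the PCA. One consequence worth knowing: CPM is
compositional, so extremely large planted effects on abundant genes shift
every other gene's CPM slightly. This is visible in simulations with few
genes and drastic (±5 log2) effects and is the expected behaviour of the
method, not an artifact of the implementation.

**Protein-coding restriction.** All downstream stages operate on genes
annotated `protein_coding` in the supplied annotation table; the retained
count is logged so manifests can be audited.

**PCA.** Genes are variables: each gene is mean-centered across samples
(never variance-scaled) and samples are projected by SVD. Components are
ordered by explained variance; each component's sign is fixed so its
largest-magnitude gene loading is positive, making scores reproducible. The
*cell-line-adjusted* PCA subtracts each gene's mean within each line before
the decomposition, which removes all between-line baseline structure: the
adjusted analysis is invariant to any per-line per-gene additive shift, and
after adjustment every gene's within-line mean is exactly zero. A line with
a single sample is rejected, since its adjusted values would be identically
zero.

**Differential expression.** Within each line, all knockdown samples (both
hairpins combined) are compared against the non-targeting control. The fold
change is computed on the CPM scale from arithmetic group means with a
0.5-CPM offset, `log2((KD + 0.5)/(NT + 0.5))`, which keeps low-abundance
ratios finite and stable. The test statistic is Welch's two-sided *t* on the
log2-CPM values with Welch–Satterthwaite degrees of freedom. The two scales
are deliberate and distinct: means on CPM, testing on logs. Each gene also
receives a rank score, `sign(log2FC) * (-log10 p)`, the input to preranked
GSEA. P values are reported unadjusted; the volcano flag uses a strict
`p < 0.01` and the concordance filter below ignores FDR entirely.

Degenerate Welch cases are pinned down rather than left to chance: when both
groups have zero variance and equal means, `t = 0, p = 1`; with distinct
means, `p` is set to the smallest representable positive double and the row
is flagged, preserving downstream rankings without dividing by zero. A rank
score at `p = 1` is exactly zero regardless of the fold-change sign. Worth
noting for power calculations: Welch's test is conservative at `n = 4 + 4`;
its true type-I rate at nominal 0.05 is ~0.041, which the acceptance checks
measure directly.

**Core signature.** The two per-line tables are merged on gene id, and a
gene enters the signature when `|log2FC| >= 1` in *both* lines with the same
sign — inclusively, so a gene at exactly 1.0 in both lines is a member. The
filter is symmetric in the two lines and monotone in the threshold. For the
signature heatmap, log2-CPM rows are z-scored across all samples (sample SD,
`n - 1` denominator — a pinned convention, since either denominator is
defensible) and genes are ordered by average-linkage (UPGMA) hierarchical
clustering of Euclidean row distances, taking `stats::hclust`'s
deterministic leaf order without optimal-leaf reordering. Constant rows
z-score to zeros with a warning rather than an error: degenerate but
plottable.

**Preranked GSEA.** Implemented from first principles. For a ranked list of
`N` genes and a set with `n` members present, the running sum gains
`|score|^w / sum(|score_members|^w)` at each member and loses `1/(N - n)` at
each non-member; the enrichment score (ES) is the extremum of the walk by
absolute value (ties resolve to the positive side), and the leading edge is
the members at or before the extremum (positive ES) or at and after it
(negative ES). The default weight `w = 1` is the classic hit-weighting. If
every member score is zero the hit weights degrade gracefully to equal
weights. Because preranked input admits no sample permutation, the null is
gene permutation: uniform random same-size subsets of the ranked universe,
with null distributions shared across sets of equal size. P values are
one-sided within the matching ES sign with the `1/(1 + n_same_sign)` floor —
printed values such as "< 2.2e-16" from other tools are permutation-floor
artifacts this implementation does not emit. NES divides ES by the mean
|null ES| of matching sign, computed separately per tail. FDR is
Benjamini–Hochberg across the tested sets: simpler and deterministic
compared with the tail-ratio FDR some tools use, and a documented deviation
from those tools' internals. Sets are tested only when their intersected
size lies in `[15, 500]`; skipped sets are recorded with reasons.

**Focused modules.** Module membership is expert curation, not an
algorithmic output, so modules are configuration: `default_modules()` ships
four seven-gene modules spanning the axes such a knockdown program touches
(G2M/DNA repair, TNFα/NF-κB, IL-6/inflammatory, EMT/adhesion), and any named
list of symbols can replace them. For each module, log2-CPM is averaged
across replicates within each (line, condition) cell — line 1's control and
knockdowns, then line 2's — z-scored per gene across the six condition
means, and row-ordered by the same UPGMA procedure.

## Survival statistics

The Kaplan–Meier estimator, the two-group log-rank test, and the
single-binary-covariate proportional-hazards fit are implemented directly
(they are the module's subject matter, and the test suite cross-checks all
three against the `survival` package and hand-tabulated fixtures). The Cox
fit maximises the partial likelihood by Newton–Raphson from `beta = 0` with
Efron's approximation for tied event times; for a binary covariate the
second moment equals the first, which simplifies the information. The 95% CI
comes from the observed information on the log scale. When one group has no
events the likelihood is monotone and the HR is reported as 0 or infinity
with a flag, never as a spuriously converged number.

Expression is dichotomised at the median by default, ties going low. A
`best_cutoff` mode scans the 0.2–0.8 quantiles in 0.05 steps and picks the
log-rank-minimising cutoff; because that scan inflates significance it is
labelled exploratory and its full scan is attached to the result. Median is
the primary method precisely to avoid silently optimistic p values. The
screen runs both statistics per gene, ranks by HR descending, reports raw
log-rank p (which drives the "significant" summary counts) alongside a BH
column, and summarises how many genes show HR > 1 and how many of those have
p < 0.05.

## What the simulator emulates — and what it does not

`simulate_counts()` draws negative-binomial counts parameterised by mean and
size (`Var = m + m^2/size`) for a two-line, three-condition (control + two
hairpins), replicated design — twelve samples under the defaults, matching
the two-replicate layout the pipeline targets. Per-gene baselines are
uniform on log2 counts `[4, 11]` (16–2048 expected counts), the detectably
expressed stratum: genes below ~16 counts are dominated by sampling noise at
two replicates, and a planted "program" on unobservable genes would test
nothing downstream. Each gene gets an independent Gaussian per-line baseline
shift (SD 1 by default) — the structure the adjusted PCA removes — and
planted effects act multiplicatively on the mean (`2^effect`), matching
log2FC semantics. Library sizes are uniform on `[5e5, 1.5e6]` and scale all
means, which is what makes CPM normalisation non-trivial. One RNG stream per
call, seeded from the config, restored on exit.

The default planted program contains concordant up- and down-regulated
genes, line-private genes, discordant genes, non-coding genes and nulls; a
gene is "planted concordant" when its effect magnitude is at least 1 in all
lines with a common sign — exactly what the concordance filter detects, so
sensitivity and false-inclusion are directly measurable.

Not emulated: read-level noise (FASTQ/alignment), GC or length bias, batch
effects beyond the line shift, correlated gene modules, and library-size
composition effects beyond those CPM itself induces. Passing tests on this
generator therefore demonstrate that the statistics recover the structure
they claim to recover, not that the pipeline is robust to every artifact of
real sequencing data.

`simulate_survival()` draws an exponential event time with hazard
`h0 * exp(beta * x)` per subject, independent exponential censoring, and
normal expression `x`; `simulate_screen_cohort()` appends independent null
genes for screen calibration. Proportional hazards holds exactly by
construction; the simulator cannot probe violations of it.

## Problem sizes and verification

The test suite verifies each statistic against an independent oracle
(closed-form Welch formulas and `stats::t.test`; a literal O(N) running-sum
walk and `fgsea::calcGseaStat`; a naive UPGMA agglomerator; hand-tabulated
six-subject KM/log-rank fixtures; `survival::coxph` with Efron ties), then
checks calibration and recovery by simulation at sizes chosen to keep the
default run around half a minute: 10^6 null draws for the Welch type-I rate
(the true rate ~0.041 sits close to the 0.040 band edge, so the estimate
must be precise), 200 random sets at 1000 permutations for GSEA null
uniformity, 200 cohort seeds for log-rank uniformity, and 20 seeds each for
hazard-ratio recovery (two 1000-subject strata one expression unit apart,
true HR 2) and core-signature recovery (100 planted genes of 2000 at
|log2FC| = 2, dispersion 10, three replicates). `scripts/acceptance.R`
recomputes the same quantities from scratch at any seed.

## Known limitations

* The concordance filter is a hard threshold on point estimates; genes
  hovering at |log2FC| ≈ 1 enter or leave the signature by noise, which the
  recovery simulations quantify but cannot remove.
* Permutation p values are floored at `1/(1 + n_perm)`; distinguishing
  pathways beyond that resolution requires more permutations.
* The BH FDR across gene sets treats set p values as exchangeable;
  overlapping sets are positively dependent, for which BH is conservative in
  the usual direction but not exact.
* The screen tests one gene at a time; no multivariable or penalised models
  are attempted, and the best-cutoff mode must be read as exploratory.
* Duplicate symbols in a ranked list are an error by design — no aggregation
  rule is silently assumed.
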