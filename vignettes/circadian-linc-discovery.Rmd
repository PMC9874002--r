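---
title: "Dual-cohort discovery of clock-correlated lincRNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-cohort discovery of clock-correlated lincRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlinc)
```

## The problem

Spontaneous preterm birth (sPTB) has been linked to dysregulation of the
placental molecular clock — the transcription–translation feedback loop
spanning ARNTL/BMAL1, CLOCK, the PER and CRY repressors, the nuclear
receptors NR1D1/2 and RORA, and their paralogs. Long intergenic non-coding
RNAs (lincRNAs) are attractive markers and therapeutic candidates because of
their tissue specificity, and many are themselves clock-controlled.

`circlinc` implements a replication-first screening pipeline for "circadian
lincRNAs": lincRNAs that are (i) differentially expressed between sPTB and
term placentas, (ii) correlated with a composite risk score built from the
differentially expressed core clock genes, and (iii) significant in **two
independent cohorts** with the same correlation sign. A pathway stage
repeats the differential and correlation screens on per-sample gene-set
variation scores to find the biological programs that track the same signal.

Each cohort is processed fully independently — its own expression filter,
normalization factors, moderated-t fit, clock panel, and reflection
constants — and results only meet at the sign-concordant overlaps. This
mirrors a two-dataset replication design and is what makes the final call
robust to cohort-specific technical structure.

## Transcript-level model

**Preprocessing.** Duplicated transcript identifiers are resolved by keeping
the row with the highest total count (ties: first occurrence). A transcript
is kept when its CPM exceeds 0.5 in at least 70% of the cohort's samples
(both groups pooled, ceiling on the sample count); CPM uses pre-filter
library sizes, so the rule is depth-free. Between-sample normalization uses
trimmed-mean-of-M-values (TMM) scaling factors — a doubly trimmed (30% on
the log-ratio scale, 5% on absolute intensity), precision-weighted mean of
log2 proportion ratios against an upper-quartile reference, anchored to
geometric mean 1 — computed through edgeR, the estimator's reference
implementation. Reported expression is `log2(CPM + 1)` on TMM-effective
library sizes: non-negative, zero counts map to 0, CPM 1 maps to 1. The
logarithm base is configurable; base 2 is the toolchain convention.

**Differential testing.** The test statistic is a precision-weighted
moderated t. Counts are transformed to `log2((count + 0.5) /
(effective library size + 1) * 1e6)`; a two-group least-squares fit gives
per-gene residual SDs whose square roots are lowess-regressed on average
log2 count; each observation's fitted count maps through this trend to a
predicted SD and a weight equal to its inverse fourth power. If the trend is
degenerate (all residual SDs equal — e.g. an exactly constant matrix) the
weights fall back to 1, preserving ordinary least squares. Per gene, the
weighted fit of expression on the group indicator (effect = sPTB − term, so
negative t means down in sPTB) yields a residual variance that is shrunk
toward an empirical-Bayes prior `(s0², d0)` estimated by moment matching of
the log variances (digamma/trigamma inversion; infinite `d0` — a point-mass
prior at the mean variance — when the observed spread of log variances is
below its theoretical minimum). The moderated statistic is referred to a
t-distribution on the residual-plus-prior degrees of freedom, capped at the
pooled residual df. Two conventions worth noting:

* group means and SDs in the output table are computed on the reporting
  scale `log2(CPM + 1)`, while the statistic itself uses the offset
  log2-CPM matrix — the two scales differ by the 0.5/1.0 offsets, and both
  are retained;
* `d0 = 0` recovers the ordinary equal-variance t-test and `d0 = Inf` a
  fixed-variance z-like statistic; both limits are exposed through the
  `prior` argument and tested.

FDR control is Benjamini–Hochberg throughout (the default of the named
toolchain; the selection gates are `p < .05` and `FDR < .25` for the
differential screens and `p < .05` and `FDR < .10` for the correlation
screens).

## The composite risk score

The clock-gene risk score is an unweighted linear combination of the
DE clock transcripts. A transcript that is *down* in sPTB is "protective":
it enters as `c − x`, reflected about a constant `c` set to the smallest
integer at or above its observed maximum across all samples of the cohort.
Up-regulated transcripts enter as `x` directly. Reflection makes every term
of the sum point in the "risk" direction, so a higher score always means a
more sPTB-like clock profile. Constants are cohort-specific, as are the
panels.

Two details are deliberate. The integer ceiling reconciles the published
formula style (small integer constants) with the verbal "maximum over all
samples" rule; an `exact_max` mode is provided, and because both modes shift
every sample's score by the same amount, all downstream correlations are
identical. The score is linear with unit slopes, so it is strictly
decreasing in each protective transcript — the negative correlation between
a down-regulated lincRNA and the score is therefore the natural sign of
co-alteration.

The same construction applied to the replicated (common) lincRNAs gives the
lincRNA-based risk score used by the pathway stage.

## Correlation screen and replication

Each DE lincRNA is Pearson-correlated with the clock risk score:
`t = r sqrt(n−2) / sqrt(1−r²)` two-sided, 95% CI by Fisher z
(`z ± 1.96/sqrt(n−3)`, clamped to ±1 at `|r| = 1`). The BH family is the
features entering the screen (the DE lincRNAs, not the transcriptome),
matching the pipeline's order of operations; zero-variance features are
flagged and excluded from the family rather than silently dropped. The
replicated set is the identifier intersection of the two cohorts'
significant lincRNAs **with equal correlation sign**.

A small PCA (centered, not variance-scaled, sample scores rescaled to
unit-norm columns so coordinates land roughly in (−1, 1)) summarizes the
heterogeneity of the replicated panel across samples.

## Per-sample gene-set variation scores

The pathway stage converts expression into a bounded per-sample enrichment
score per gene set, written from first principles:

1. **Kernel CDF.** For each gene, `z(g,j) = mean_k Φ((x(g,j) − x(g,k))/h_g)`
   with a Gaussian kernel and bandwidth `h_g = SD_g/4` (floored for constant
   genes). This is a smoothed within-gene quantile of sample `j`.
2. **Symmetric rank statistic.** Within each sample, genes are ranked by
   decreasing `z` (ties: stable gene order) and weighted by
   `s = |p/2 − rank|`, so both tails of the profile carry the most weight.
   With integer ranks the two extreme weights differ by one unit — the
   statistic is symmetric about `p/2` in the continuous sense only.
3. **Random walk.** Walking down the ranked list, in-set genes add
   `s^τ / Σ_set s^τ` (τ = 1) and out-of-set genes subtract `1/(p − m)`. The
   enrichment score is the maximum positive plus the minimum negative
   deviation of the walk (signed "max-diff" form), which is bounded in
   [−1, 1] and zero-centered for unstructured sets.

Sets are intersected with the expression universe and size-filtered
(default 2–500) before scoring; excluded sets are reported, not silently
dropped. The score matrix then re-enters the same machinery as the
transcripts: moderated t with unit weights (scores are not counts, so no
mean–variance trend is fitted), BH gates, Pearson screen against the
lincRNA risk score restricted to the DE pathways, and the sign-concordant
cross-cohort overlap.

## The synthetic study generator

Because the pipeline is a composition of screens, every stage needs data
with a recoverable target. `generate_cohort()` draws negative-binomial
counts around log-normal baseline abundances (meanlog 2, sdlog 2.5 — the
heavy right tail makes the CPM filter act on roughly 5–10% of genes), with
log-normal library sizes (default mean 2×10⁶ reads, CV 0.2) and gene-level
dispersion 0.1, values typical of bulk placental RNA-seq at the gene level.
Planted structure has two layers:

* **Group effects**: selected genes get a signed log2 fold change in the
  case group. The default truth plants five down-regulated clock genes
  (log2FC −1.5), five down-regulated lincRNAs (−2), and a pool of 50
  "factor genes" (−1.5), chosen a priori so that a 16v16 design detects the
  planted transcripts through the joint `p`/FDR gates with high margin.
* **A latent factor**: one `N(0,1)` draw per sample loads (0.6 log2 units
  per SD) on the planted lincRNAs, the down clock genes, and the factor
  genes — all with the same sign. Because the risk score reflects
  protective genes (`c − x`), co-movement of lincRNAs with the down clock
  genes is exactly what produces the *negative* lincRNA-versus-score
  correlation the screen looks for. Gene sets seeded from the factor pool
  (`generate_gene_sets`) become score-correlated pathways for the same
  reason.

Planted and clock genes are re-drawn into the 40th–90th baseline percentile
band so the filter cannot erase them; abundances are renormalized to
proportions per sample, so column sums track the target depths and the
planted effects are mildly compositional, as in real data. All randomness
in a cohort flows from one `set.seed()` with a fixed draw order; the
two-cohort wrapper derives fixed sub-seed offsets.

What the generator does **not** emulate: sampling-region or ancestry
strata, gestational-age covariates, gene length (no RPKM/TPM), GC or batch
effects, and any dependence between genes beyond the single shared factor.
Passing recovery tests therefore demonstrate that the pipeline's gates and
overlaps are wired correctly and calibrated under a faithful noise model —
not that real cohorts carry signals this clean.

## Numerical choices and degenerate inputs

* De-duplication ties break to the first occurrence; the filter threshold
  uses a ceiling on the sample count.
* A zero-variance feature in the correlation screen is flagged and excluded
  from the BH family; an expression value above a reflection constant warns
  (panel/population mismatch) but still scores.
* Constant genes in the kernel CDF get a floored bandwidth (all samples at
  0.5); a set whose in-walk weights are all zero takes uniform in-set steps.
* A cohort with no DE clock gene halts the study with an explicit
  `empty_clock_panel` status rather than an exception — an empty panel is a
  scientific outcome, not an error.
* The moderated-t reference df is capped at the pooled residual df so the
  infinite-prior limit keeps a proper t reference.

## Problem sizes used in the shipped studies

The packaged statistical checks run the null calibration at 100 cohorts of
2,000 genes (16v16), the replication null at 50 study pairs, and the
recovery study at 50 seeds of the default two-cohort design (10v20 and
16v16); the pathway recovery study uses a reduced design (600 genes, 8v8,
30 sets) that preserves per-gene power by the same effect-size reasoning.
These sizes give binomial Monte-Carlo error well inside the margins being
tested while keeping each study in the tens of seconds.

## Known limitations

* The pipeline tests replication by intersection of significant sets, not
  by a joint model; a lincRNA just missing one cohort's FDR gate is
  dropped, which is conservative by design.
* The correlation screen is Pearson-only (no rank-based or
  covariate-adjusted option), matching the method it implements.
* Pathway scores inherit the gene-set collection's coverage; sets reduced
  below the size floor by universe intersection are excluded.
* With two groups and no covariates, the moderated t assumes equal
  residual variance across groups per gene (the pooled fit); the
  empirical-Bayes prior moderates but does not remove that assumption.
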