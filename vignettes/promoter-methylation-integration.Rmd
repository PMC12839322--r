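---
title: "Identifying methylation-regulated genes in CIMP-stratified cohorts"
author: "promethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying methylation-regulated genes in CIMP-stratified cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promethyl)
```

## The problem and the model

Promoter hypermethylation is one of the canonical routes by which tumors
silence genes. In cohorts that contain CpG Island Methylator Phenotype
(CIMP) tumors, contrasting CIMP-high against Non-CIMP samples concentrates
exactly the genes whose expression is under methylation control. `promethyl`
operationalizes that contrast as a two-step screen:

1. a gene must be **both** differentially methylated (promoter-average
   Δβ) and differentially expressed (log₂FC of log₂CPM) between CIMP-H and
   Non-CIMP — a necessary but not sufficient condition for epigenetic
   regulation; then
2. the **per-sample association** between promoter methylation and
   expression is scored, either non-parametrically (Spearman ρ) or by an
   ordinary least-squares fit whose adjusted R² measures how much of the
   expression variance promoter methylation explains.

The central modelling commitment is the regression with *all* promoter CpGs
as predictors ("regression-single"): expression of gene $g$ in sample $s$ is
modelled as

$$y_{gs} = \alpha_g + \sum_{j \in \mathrm{prom}(g)} \gamma_{gj}\,\beta_{js} + \varepsilon_{gs},$$

scored by $\mathrm{adj}\,R^2 = 1 - (1 - R^2)\frac{n-1}{n-k_\mathrm{eff}-1}$
and the F-test p-value. The adjustment penalizes promoter size, making genes
with 2 and with 30 CpGs comparable; the per-CpG coefficients let the model
capture combined or opposite-sign effects of individual CpGs that any
promoter-level summary (mean beta, methylated-CpG ratio) averages away.
Assumptions worth keeping in mind: linearity of log-expression in beta,
independent errors across samples, and no adjustment for confounders such as
copy number, purity or batch — associations are descriptive, not causal.

## Data containers and interchange

Cohorts are held in a `MethExpCohort`, a pair of `SummarizedExperiment`
objects (probe-level betas with the manifest annotation as `rowData`;
gene-level counts) sharing one `colData` sample sheet. Every pipeline stage
also reads and writes plain TSV (tab-separated, `NA` for missing, reals at
17 significant digits so files round-trip exactly), matching the
tab-separated culture of GDC-style exports without binding to a platform
reader. Betas at exactly 0 or 1 — file rounding artifacts; array betas are
theoretically open-interval — are clamped to $(10^{-6}, 1-10^{-6})$ and
counted rather than rejected.

## Tunable parameters

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `delta_beta_min` | 0.2 | beta difference | widely used biological-relevance cutoff for promoter DM |
| `abs_log2fc_min` | 1.3 | log₂CPM | retains ≥ 2.5-fold expression differences |
| `alpha` | 0.05 | probability | BH-adjusted significance for DM/DE, Spearman; raw model p for regression |
| `meth_cpg_beta_min` | 0.3 | beta | "methylated CpG" for the ratio summary and the CIMP-index; captures partially methylated CpGs |
| `spearman_abs_min` | 0.4 | \|ρ\| | moderate monotone association, strict inequality |
| `adj_r2_min` | 0.5 | adj R² | methylation explains the majority of expression variance, strict inequality |
| `cimp_index_hi` / `lo` | ±0.5 | standardized index | balanced three-way CIMP split |
| `silencing_sample_frac` | 0.01 | fraction of samples | external silencing definition |
| `silencing_z_max` | −1.65 | z-score | methylated group sits in the lower expression tail |
| `silencing_alpha` | 0.001 | FDR | external silencing definition |

Spearman selection uses $|\rho|$: promoter methylation that silences a gene
produces *negative* correlations, so thresholding the signed value would
discard exactly the biology of interest.

## Numerical choices

- **Differential testing** uses two-sided Welch t-tests on promoter-average
  betas and on log₂CPM. The screen consumes only thresholded effect sizes
  and BH-adjusted p-values, so a plain location test is sufficient and keeps
  the module free of empirical-Bayes machinery; with ≥ 40 samples per group
  the Welch test is well calibrated on both data types (verified under the
  global null in the acceptance suite). Degenerate rows (zero variance in
  both groups, equal means) get p = 1.
- **BH adjustment** is the standard step-up, applied separately within the
  methylation analysis, the expression analysis, and each association
  method, across all tested genes.
- **TMM normalization** follows the published algorithm: gene-wise
  M = log₂ relative-proportion ratios against a reference library chosen by
  the upper-quartile criterion, double trimming (30% on M, 5% on A),
  inverse-variance weighting, factors rescaled to geometric mean 1. The
  implementation agrees with the reference implementation to machine
  precision on count fixtures. log₂CPM uses prior counts 0.5/1.0, so values
  stay finite at zero counts. Note TMM is only *approximately* invariant to
  rescaling one library — the inverse-variance weights shift — and the
  reference implementation shifts identically.
- **Regression** reduces rank-deficient promoter designs to an independent
  column basis (`k_eff` = effective rank); genes with $k \ge n-2$ predictors
  are reported as `underdetermined` rather than silently dropped, and fits
  with fewer than 3 residual degrees of freedom are skipped with a status.
  A perfect fit reports model p = 0.
- **spearman-single** needs a gene-level p-value for a set of per-CpG
  correlations; Fisher's combination is used. Promoter CpGs are correlated,
  so this combination is anti-conservative — it is reported as method
  metadata and the selection behaviour of the Spearman family should be read
  accordingly.
- **Ties in argmax counting** credit every tied method; with continuous
  scores ties have measure zero, and the rule is deterministic and
  symmetric. Selection ranks break score ties lexicographically by gene
  symbol.
- **CIMP-index**: the published ±0.5 class thresholds cannot apply to a raw
  proportion in [0, 1]; the index is therefore z-scored across the cohort
  (sample sd, ddof = 1) before thresholding, and both raw and standardized
  indices are reported. When a sample sheet already carries CIMP labels they
  take precedence and the index is reported for reference only.
- **Promoter membership** is taken from the manifest (TSS1500 ∪ TSS200 ∪
  promoter-associated) instead of recomputing distances from TSS
  coordinates; the array's TSS1500 label covers 200–1500 bp and excludes
  TSS200, so the union realizes "within 1500 bp upstream". Strand handling
  is thereby delegated to the manifest. The TSS groups are configurable in
  `buildPromoterMap()`.
- **Silencing calls**: the external definition leaves the z-score and test
  constructions open; this module standardizes expression per gene over all
  samples and uses a one-sided Welch test (methylated < unmethylated) with
  BH across all tested probes. The per-(gene, sample) call — needed for the
  group percentages — is defined as a majority-methylated promoter within a
  silenced gene. Both choices are isolated in `silencingCalls()` so
  alternatives can be swapped in. The beta cutoff is strict (> 0.3) here but
  inclusive (≥ 0.3) in the ratio summary, each following its own published
  clause.

## What the synthetic generator emulates

`simulateCohort()` draws probe-level betas around a per-gene, per-sample
promoter state (baseline Beta(2,10), hypermethylated Beta(10,2), probe noise
sd 0.05), so CpGs within a promoter are realistically co-methylated;
counts are negative binomial (dispersion 0.1) around per-sample expected
proportions with library sizes log-uniform in 0.5–2× of 200,000. Planted
structure: 10% methylation-driven genes (log₂ expression =
baseline − 3 × promoter-mean beta, giving Δβ ≈ 0.67 and log₂FC ≈ −2), 10%
DM-only and 10% DE-only (shift −2) decoys, plus decoy probes on X/Y,
SNP-flagged, and NA-bearing. A 30% fraction of null genes receives mild
CIMP-H promoter hypermethylation (Beta(3.5,6.5)), reproducing the global
methylation excess that makes the CIMP-index separate the groups. Everything
derives from one seeded RNG stream; identical seed and settings give
bit-identical cohorts.

Two scenario variants matter for validation:

- **Opposing-CpG mode** adds per-CpG expression effects with
  alternating-sign coefficients (and probe noise 0.15) on top of the mean
  effect. Promoter summaries cancel the per-CpG part, so the all-CpG
  regression must out-score the average/ratio variants — this isolates the
  mechanism that motivates regression-single.
- **Silencing scenario** (penetrance 0.3 within CIMP-H, baseline Beta(2,18),
  probe noise 0.03). The external silencing definition requires the mean
  expression z-score of the *methylated* samples to fall below −1.65 after
  standardizing over all samples. That is arithmetically impossible when
  half the cohort is methylated (the mean z of any fixed half of a
  standardized variable is bounded near −1), and a Beta(2,10) baseline
  leaves ~11% of unmethylated samples above the 0.3 beta cutoff,
  contaminating the methylated group with normal-expression samples.
  Silencing in real tumors hits a minority of samples against a sharply
  bimodal background, and the scenario encodes exactly that: ~15% of
  samples methylated, ~1% background exceedance.

What the generator does **not** model: copy-number variation, tumor purity,
cell-type composition, batch effects, probe cross-hybridization, and the
correlation structure of real CpG islands beyond the shared promoter state.
Passing tests therefore demonstrate that the implementation recovers the
relationships it targets under clean planted signal — not that the method is
robust to the confounders of real tumor data.

## Validation design and problem sizes

The test suite checks each statistical primitive against an independent
oracle (closed-form rank formula for Spearman, normal-equations OLS for the
regression, naive step-up enumeration for BH, a reference implementation for
TMM), and the whole pipeline against planted ground truth: 20 seeded default
cohorts (200 genes, 40+40 samples) for sensitivity, null selection and
effect-size recovery; 50 seeded null cohorts for type-I calibration of the
Welch tests (raw p below α within two-sided binomial 95% bounds) and of the
five-way classifier (significant-category fraction at or below the upper
binomial bound — a classifier stacking BH with effect thresholds sits far
*below* the nominal rate under the null, which is the designed behaviour,
so a two-sided band around α would be the wrong check); 3 opposing-mode
cohorts for the argmax mechanism; and 5 silencing-scenario cohorts for the
perc.diff consistency metric. These sizes keep the default suite under a
minute of cohort simulation while leaving the binomial and recovery checks
well powered. `scripts/acceptance.R` recomputes the same quantities from
scratch at any seed.

## Known limitations

- Associations are correlational; no covariate adjustment is offered.
- The Fisher-combined spearman-single p-value is anti-conservative under
  CpG correlation (flagged above).
- Promoter definitions inherit the array manifest's annotation choices and
  coverage; distal enhancers and alternative promoters are invisible.
- Welch tests do not borrow strength across genes; at much smaller sample
  sizes than the defaults, moderated tests would be preferable.
- The five-way classifier treats thresholds as sharp cutoffs; genes with
  Δβ = 0.19 are "not significant" by fiat.
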