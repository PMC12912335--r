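---
title: "Two-step drug-target MR mediation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step drug-target MR mediation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The scientific question

Statins lower LDL cholesterol and the risk of ischemic heart disease (IHD),
but the molecular pathways that carry the benefit beyond LDL itself are
largely uncharacterised. Two-step drug-target Mendelian randomization (MR)
addresses this with summary-level GWAS data alone. A variant in the drug
target gene (*HMGCR* for statins) that lowers LDL acts as a genetic proxy
for pharmacological exposure. Step 1 asks which circulating proteins that
proxy shifts; step 2 asks which of those proteins in turn shift disease
risk; a protein implicated in both steps, with directions that fit the
protective total effect, is a candidate mediator, and the product of its
two step estimates divided by the total effect is its proportion mediated.

`mrmediate` implements the full workflow — instrument construction,
harmonization, estimators, sensitivity analyses, colocalization, FDR
screening and mediation — together with a seeded synthetic
summary-statistics generator, so every stage can be exercised and
validated with known ground truth and no restricted data.

## Data model

Everything operates on per-variant summary statistics: effect estimate
`beta` (SD units for quantitative traits, log odds ratio for binary
ones), its standard error, effect-allele frequency, p-value and sample
size. `gwas_table()` validates the invariants (positive SEs, p-values in
(0, 1], distinct alleles, unique ids); `harmonize()` aligns an outcome
table to the exposure's effect alleles, resolving allele swaps and strand
flips and dropping palindromic variants whose strand cannot be resolved.

### Harmonization policy

The sources this workflow is designed for do not publish a harmonization
recipe, so the package fixes a conservative, conventional one:

* palindromic (A/T, C/G) variants are dropped when either trait's
  effect-allele frequency falls in `0.5 ± 0.08` (or is missing); outside
  that window the strand is inferred from frequency concordance;
* non-palindromic variants with missing frequency are matched by allele
  identity alone;
* variants whose alleles cannot be reconciled even after strand
  complementing are dropped; every drop is counted per reason in the
  harmonization report.

The 0.08 half-window is a deliberate default, not an estimate: it trades
a small loss of variants for protection against silently mis-oriented
effects, and it is exposed as `palindrome_eaf_window` for users whose
sources report strand explicitly.

## Instruments

`select_cis_instruments()` implements the drug-target construction: the
gene region plus a symmetric flank (default 100 kb, boundaries
inclusive), an association filter (default p < 5e-8), greedy LD pruning
(keep the smallest p, discard everything with r² at or above the
threshold — strictly-below survives, matching the "r² < t" convention),
and optionally the single lead variant. `select_pqtl_instruments()`
applies the proteomic convention (p < 1.7e-11, r² < 0.01) genome-wide;
reverse-MR disease instruments reuse it with p < 5e-8 and r² < 0.001.
Per-variant F-statistics `(beta/se)²` are recorded and values at or
below 10 flagged as weak. Pruning ties on p are broken lexicographically
by variant id so selection is deterministic under input reordering.

## Estimators

With per-variant Wald ratios `b_out/b_exp` and first-order weights
`(se_out/|b_exp|)^-2`:

* **IVW** is the weighted mean of ratios, identical to weighted least
  squares of outcome on exposure betas through the origin. The
  fixed-effects SE is `(Σw)^{-1/2}`; the multiplicative random-effects
  (MRE) SE multiplies it by `sqrt(max(1, Q/(k-1)))` with `Q` Cochran's
  statistic. The `auto` model follows the applied rule: MRE with three or
  more variants, FE below. The dispersion floor at 1 prevents
  underdispersion from shrinking the SE below its fixed-effects value —
  the named model leaves the formula open, and this is the standard
  multiplicative-random-effects choice.
* **Weighted median**: ratios sorted, cumulative normalized weights
  interpolated at 0.5; robust while at least half the weight is valid.
* **Weighted mode**: maximiser of an inverse-variance-weighted Gaussian
  kernel density over a 512-point grid spanning the ratios ± 3
  bandwidths; bandwidth `h = φ·0.9·min(sd, IQR/1.349)·k^{-1/5}` (modified
  Silverman rule, `φ = 1` by default), floored at 1e-8 so degenerate
  ratio sets return their common value.
* **MR-PRESSO**: residual-sum-of-squares test against a seeded parametric
  simulation with leave-one-out IVW predictions; empirical p-values use
  the add-one rule `(r+1)/(n_sim+1)` so they are never zero; per-variant
  outlier tests are Bonferroni-adjusted; the corrected estimate refits
  IVW without outliers and the distortion test compares the induced shift
  to random same-size removals.
* **Steiger**: compares instrument-explained variance
  `r² = t²/(t² + n − 2)` summed over variants on each side via Fisher's
  z with variances `1/(n−3)`; the implementation requires `n > 3`
  accordingly.
* Wald-ratio SEs default to first order (exposure-side uncertainty is
  negligible for the strong instruments this workflow mandates); the
  second-order form is available where instrument strength is marginal.
* All normal-theory p-values are two-sided; bootstrap SEs for the median
  and mode resample per-variant betas parametrically from their reported
  SEs, with a caller-supplied seed (default 1000 resamples).

## Colocalization

`coloc_abf()` tests whether the drug-target association with LDL and
with a candidate protein share one causal variant in the cis region
(default window ±200 kb) via per-variant Wakefield approximate Bayes
factors, `lABF = 0.5(log(1−r) + r z²)` with `r = W²/(W² + se²)`. Prior
effect SDs are fixed at 0.15 (quantitative) and 0.2 (binary log OR), the
method's conventional defaults, rather than estimated — the sources in
scope publish neither priors nor the inputs to estimate them. Priors
`p1 = p2 = 1e-4`, `p12 = 1e-5`. All five hypothesis weights are
accumulated in log space with log-sum-exp; the distinct-variants weight
excludes the diagonal through a guarded log-difference, so the
computation is exact and overflow-free for |z| up to 100 across tens of
thousands of variants. A high PP_H3 (two distinct variants in LD) flags
confounding by genotype; a high PP_H4 supports a shared signal.

## Screening, mediator selection and mediation

Step 1 orients the cis instrument to the LDL-lowering allele, so protein
effects read "per SD reduction in LDL" — a protein lowered by the drug
has a negative beta, matching the sign conventions of drug-target
reports. The scaled Wald ratio is invariant to which allele the source
happened to code. Benjamini–Hochberg FDR (via `stats::p.adjust`) is
applied across all analyzable proteins, default threshold 0.05.

Step 2 runs the auto-model IVW per selected protein against the disease
GWAS, plus weighted median, weighted mode, leave-one-out and MR-PRESSO
when enough variants are available (sensitivity estimators need three,
MR-PRESSO four; with fewer the skip is logged, never silent). FDR is
computed over the primary outcome's IVW p-values — the replication
outcome and the fixed-effect meta-analysis are reported alongside but do
not drive selection, mirroring the screen-then-replicate design.

A protein is a direction-consistent mediator when its two step estimates
have opposite signs, so their product matches a protective (negative)
total effect; same-signed proteins are retained with the reason
recorded, since they are informative about pathways that oppose the
drug's benefit. The mediation identities are exact by construction:
indirect = step1 × step2, proportion = indirect / total; proportions
outside [0, 1] are returned with a warning flag, never clamped, because
clamping would hide incoherent inputs. Replication of an association
requires presence, the same sign and p < 0.05 in the replication panel —
a stated decision, since published replication narratives rarely print
their rule; proteins absent from the replication panel are flagged
missing rather than failed.

Reverse MR (disease as exposure against each selected protein, with
Steiger) is reported but not auto-adjudicated: directionality judgments
belong to the analyst.

## The synthetic generator

The generator works at the summary-statistic level: with MAF `f` and
sample size `n`, `se = 1/sqrt(2 f (1−f) n)` (standardized-trait model)
and the observed beta is drawn from `N(true beta, se²)`. That is exactly
the information every estimator in scope consumes, which is why no
individual-level genotypes are simulated. Binary traits are generated
directly on the log-OR scale with effective `n` = cases + controls.

The default scenario (`statin_truth()`) encodes the study conditions the
workflow is designed around: a cis instrument lowering LDL by 0.1 SD per
allele; one mediator protein planted at the published effect scale
(step-1 beta −0.63 per SD LDL reduction, step-2 log OR 0.60 per SD
protein) with the direct effect set so the total effect per SD LDL
reduction is −0.49 — hence a true proportion mediated of about 0.77; a
panel of 100 proteins (desk-scale stand-in for a proteome-wide panel);
sample sizes 173,082 (LDL), 35,000 (proteins; 35,559 for the replication
panel), and effective 184,305 / 218,792 for the two disease GWAS; MAFs
uniform on (0.05, 0.5). At these sizes the planted step-1 signal has
|z| ≈ 6, large enough that the screen's operating characteristics —
not raw power — are what the tests measure. pQTL panels draw per-variant
protein effects from `N(0.15, 0.05²)` with random signs, and pleiotropy
configurable as balanced (mean-zero), directional (a fraction of
variants sharing a mean shift) or a single planted outlier in units of
the outcome SE. MR instrument panels are LD-free by construction — they
represent post-pruning instrument sets — while the colocalization
scenario carries AR(1) LD (`ρ = 0.5`, 200 variants) with z-vectors drawn
from `MVN(Rλ, R)`, `λ = effect·sqrt(n)` at the causal indices.

What the generator deliberately does not emulate: realistic genome-wide
LD, sample overlap between GWAS, population stratification,
winner's-curse selection of instruments, and liability-scale binary
traits. Passing tests therefore demonstrate that the estimators and the
pipeline are correct under their own assumptions, not that those
assumptions hold in any particular real dataset.

## Numerical choices and degenerate inputs

* Empirical p-values (MR-PRESSO) use the add-one rule; analytic
  p-values are floored at the smallest positive double so they stay in
  (0, 1].
* The weighted-mode bandwidth is floored at 1e-8; degenerate ratio sets
  return the common ratio.
* LD pruning and all selections sort on `(p, variant_id)`, making every
  result deterministic under permutation of the input.
* `coloc_abf()` and `logsumexp` never leave log space until the final
  normalization.
* Zero exposure betas are dropped from IVW with a warning (the ratio is
  undefined), and error if nothing remains.
* Pipeline runs are pure functions of (config, seed): per-protein seeds
  are derived arithmetically from the base seed, and rerunning a config
  yields byte-identical output tables.

## Problem sizes used in the validation suite

The packaged validation suite runs at desk scale, chosen so the whole
suite completes in minutes while keeping Monte-Carlo error well inside
the asserted margins: 200 replicates for estimator recovery, coverage
and FDR control, 100 for MR-PRESSO operating characteristics,
100-protein panels, 20-variant instrument sets, 200-variant
colocalization regions, and bootstrap/simulation counts of 10–1000
depending on whether a point estimate or a tail probability is being
measured.

## Known limitations

* Only summary-level two-sample methods are implemented; no
  individual-level or one-sample corrections.
* MR-Egger, multivariable MR and SuSiE-style multi-signal
  colocalization are out of scope.
* The effective-n convention for binary traits (cases + controls)
  matches the generator; users with `4/(1/cases + 1/controls)` scaling
  should supply that number directly.
* The proportion-mediated is a ratio of noisy estimates; its sampling
  error is substantial whenever the step-1 or total effect is imprecise,
  and the package reports it without delta-method intervals.
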