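---
title: "Rank-based lncRNA pair signatures: models, parameters and design"
author: "irlncPairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based lncRNA pair signatures: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irlncPairs)
```

# The model

## Pair features

For genes $a < b$ (lexicographic, the canonical orientation) and sample
$s$, the pair feature is
$$P_{ab}(s) = \mathbf{1}\{x_a(s) > x_b(s)\},$$
with ties scoring 0. Because each feature only compares two measurements
made inside the same sample, any strictly increasing transform applied
per sample — rescaling, log, rank, power — leaves the whole pair matrix
bit-identical. That invariance is the reason to prefer pair features over
absolute expression when a signature must survive normalization and
platform changes; it is enforced by property tests (random monotone
distortions per sample) and propagates to every downstream risk score.
The orientation choice is immaterial: flipping a pair complements the
indicator, which the sign of its Cox coefficient absorbs.

A pair whose indicator is nearly constant across the cohort carries no
usable contrast and is unstable in a partial-likelihood fit, so pairs are
kept only when their 1-frequency lies **strictly** inside
$(\mathrm{low}, \mathrm{high}) = (0.2, 0.8)$. Strict inequalities make
the boundary deterministic; both bounds are configurable.

## Screening

Upstream of pairing, lncRNAs are screened twice:

* **Immune coexpression**: Pearson correlation of each lncRNA against
  each immune-annotated mRNA; a lncRNA is immune-related when at least
  one partner has $|r| \ge 0.4$ and $p \le 0.001$ (two-sided $t$
  approximation on $n-2$ degrees of freedom, the standard test for a
  Pearson coefficient). In the pipeline this screen runs on tumor samples
  so that a tumor/normal location shift cannot masquerade as
  coexpression.
* **Differential expression**: $\log_2$ fold change from pseudocounted
  group means, $\log_2\frac{\bar{x}_T + c}{\bar{x}_N + c}$ with $c = 1$
  on the normalized scale, and a two-sided Wilcoxon rank-sum p-value with
  Benjamini–Hochberg correction; flagged when $|\mathrm{logFC}| > 1$ and
  FDR $< 0.05$. The rank-sum test was chosen over a moderated linear
  model because it is distribution-free and exactly reproducible; the
  thresholds, not the test statistic, are the operative contract of this
  step. The pseudocount is configurable.

## Signature selection and risk score

Each valid pair enters a univariate Cox proportional-hazards fit (Efron
tie handling, Wald inference) and survives at $p < 0.001$. The retained
pairs enter an L1-penalized Cox model (`glmnet`). Because a single
cross-validation is noisy in small-event cohorts, the penalty is chosen
by **repeated CV**: `n_cycles` independent $k$-fold cross-validations
with freshly randomized folds (defaults 1000 cycles, 10 folds), each
recording its partial-likelihood-optimal $\lambda_{\min}$ along a fixed
path of 100 log-spaced values from the all-zero penalty down to 1 % of
it; the final penalty $\lambda^\*$ is the **median** of the recorded
optima (robust to the occasional degenerate cycle; the aggregation is a
package choice since "repeat the CV many times" does not define one),
and the signature is the nonzero support of one full-cohort fit at
$\lambda^\*$. Per-pair selection frequencies across cycles are kept as
diagnostics in the model's provenance. Binary covariates are not
standardized. Everything is deterministic given the seed.

The risk score is the linear predictor
$\mathrm{RiskScore}(s) = \sum_i \beta_i P_i(s)$.

## Evaluation

Discrimination at horizon $t$ (default 365 days; 3/5/10-year extras)
uses the cumulative-case / dynamic-control time-dependent ROC of
Heagerty, Lumley and Pepe: cases are subjects with an event by $t$,
controls those event-free beyond $t$, both estimated under right
censoring. Two estimators are provided:

* `method = "km"` — the Kaplan–Meier plug-in. When no censoring occurs
  by $t$ it reduces *exactly* to empirical counting (that identity is
  used verbatim in that case, and is what the counting-oracle tests
  assert bit-exactly). It can produce a locally non-monotone curve under
  censoring, which is a known property of this estimator.
* `method = "nne"` (default) — nearest-neighbour smoothing of the
  conditional survival in marker percentile, half-width
  $\mathrm{span} = 0.25\,n^{-0.20}$ unless overridden; always monotone.

AUC is the trapezoidal area of the $(1-\mathrm{spec}, \mathrm{sens})$
curve anchored at $(0,0)$ and $(1,1)$. The operating cutoff maximizes
Youden's $J = \mathrm{sens} + \mathrm{spec} - 1$, ties broken toward the
smaller threshold; group assignment is **strict** (`high` iff score >
cutoff), so a score exactly at the cutoff is low-risk. Groups are then
compared by Kaplan–Meier curves with the two-group log-rank test,
Pearson's $\chi^2$ (no continuity correction, since not all tables are
2×2) for categorical clinical features, Wilcoxon rank-sum (two levels)
or Kruskal–Wallis (more) for risk-score differences across feature
levels, and univariate plus multivariate Cox models for independence of
the risk score from age, sex and stage. Although group comparisons are
sometimes labelled "signed rank" in this literature, the designs compare
*independent* groups, so the rank-sum (Mann–Whitney) test is what is
computed throughout. PCA is centered and unscaled, on the binary pair
matrix by default.

Two cohort-scope questions are left to configuration because the
published workflow is ambiguous about them: whether the LASSO fit uses
the full cohort or only the training half (`fit_scope`, default
`"full"`, with the 1:1 split always computed and train/test AUCs always
reported), and the Youden cutoff is always derived from the cohort the
model was evaluated on at the primary horizon.

## Immune landscape

Deconvolved infiltration tables, ESTIMATE-style scores and predicted
IC50s are *inputs*: the algorithms producing them are published
third-party methods, so the package defines their schemas (samples ×
features, optional per-sample deconvolution p-value filtered at
$p < 0.05$) and computes the downstream statistics — Spearman
correlation with the risk score and rank-sum contrasts between risk
groups (exact when both groups have ≤ 10 samples and ties are absent,
normal approximation with continuity correction otherwise), with
significance stars at 0.05 / 0.01 / 0.001.

# The synthetic cohort generator

`generateCohort()` draws log-normal expression: gene baseline
$\mu_g \sim N(2, 0.3)$ plus, for immune-module members, a per-sample
latent factor $z_s \sim N(0,1)$ with loading
$\pm\sqrt{\mathrm{immune\_corr}}$ (default $\sqrt{0.6}$, giving pairwise
log-scale correlations of 0.6 so module lncRNAs clear the $|r| \ge 0.4$
screen with margin at the default 500 tumor samples), and residual
log-scale noise of $\sigma = 0.5$. DE lncRNAs shift by
$\log(\mathrm{de\_fold})$ (default four-fold) in tumor samples, half up
and half down via the sign of their module loading. Three generator
choices matter and are deliberate:

* module loadings alternate in **blocks of two**, and the members of
  each planted pair get **matched baselines** $\mu$: otherwise the
  default planted pairs (consecutive DE lncRNAs) would combine opposite
  tumor shifts or unequal baselines into a near-constant indicator that
  the validity filter deletes — the planted truth must be recoverable by
  the very pipeline it is meant to validate;
* survival is exponential with hazard
  $h_0 \exp(\sum_i \beta_i P_i)$, $h_0 = \log 2 / 1095$ per day (3-year
  median at baseline — short enough that 1-year ROC horizons see events;
  closed-form inversion keeps the generator exact, and a constant hazard
  is sufficient for proportional-hazards recovery checks);
* pair indicators driving the hazard are computed from **pre-distortion**
  expression, making the optional per-sample monotone distortion a pure
  measurement-layer effect; censoring times are uniform on $(0, H)$ with
  $H$ calibrated by bisection to the target fraction (default 0.3,
  realized within ±5 points at $n \ge 300$).

What the generator does **not** emulate: TCGA-like marginal
distributions per gene, batch or library-size artifacts beyond the
monotone distortion, correlated censoring, or clinical covariates that
confound the risk score (they are drawn independently; confounding is
exercised separately in the evaluation tests). Passing tests on these
cohorts therefore demonstrate correctness of the machinery and
recoverability of planted signal — not clinical performance on real
tumors.

# Numerical choices and degenerate inputs

* Ties in a pair comparison score 0; strict group assignment at the
  cutoff; strict validity bounds; ties in the Youden scan go to the
  smaller threshold. Every boundary is deterministic.
* Constant-expression genes are skipped (with a warning) by the
  correlation screen; constant pairs are skipped by the Cox screen; a
  feature constant across samples is skipped by the Spearman step;
  single-level clinical features are skipped by the association step.
* Cohorts without events, empty sample intersections, all-zero LASSO
  solutions, missing signature pairs and collinear covariate sets are
  hard errors with named offenders.
* Samples with non-positive follow-up cannot contribute to a partial
  likelihood and are dropped with a logged count.
* The 504-patient 1:1 split convention gives `round(0.5 × 504) = 252`
  training samples; the rounding rule is `round(ratio × n)` clamped to
  leave both halves non-empty.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen so the full suite completes in minutes on one CPU: the default
synthetic bundle is 600 genes × 558 samples (500 tumor + 58 normal) with
five planted pairs at $|\beta| = 1$; repeated-CV selection uses 50
cycles there (the package default remains 1000); planted-recovery
properties use 50 pair features, $n = 300$ training samples and 20
seeds; the log-rank calibration check uses 1000 replicates at $n = 100$.
The tiny bundle (40 genes × 60 samples) exists for smoke tests and
examples; at that size the $p < 0.001$ univariate screen would keep
nothing, so its generated config relaxes `cox_p_max` to 0.2 and plants
$|\beta| = 1.5$ — the default bundle keeps the published thresholds.

# Known limitations

* The univariate Cox screen fits one model per pair; at hundreds of
  thousands of pairs a vectorized score test would be preferable.
* The KM-variant ROC can exceed monotonicity locally under heavy
  censoring (inherent to the estimator; use `nne` for reporting).
* With very few events, repeated CV can select a penalty at the edge of
  the path; the all-zero error message suggests remedies rather than
  silently returning an empty signature.
* A concordance ceiling applies to any pair signature: with $k$ binary
  pair features of effect $|\beta|$, even the true linear predictor has
  bounded C-index (about 0.69 for three pairs at $|\beta| = 1$, 0.73 for
  five); expectations for held-out discrimination should be set against
  that ceiling, not against 1.
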