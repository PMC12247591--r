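---
title: "Weighted path-length analysis of structural connectomes: methods"
author: "connectopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted path-length analysis of structural connectomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deterministic diffusion tractography summarises a subject's white-matter
anatomy as a square ROI-by-ROI matrix of tract counts. Treating regions as
nodes and counts as connection strengths turns each subject into a weighted
graph, and global graph measures become candidate imaging markers for
psychiatric conditions — here, chronic post-traumatic stress disorder (PTSD)
in a trauma-exposed responder cohort, with major depressive disorder (MDD)
comorbidity as a complicating factor. The package implements the complete
analysis chain: matrix validation, network measures, a synthetic-cohort
generator that stands in for restricted clinical imaging data, the
group-comparison and correlation battery, and ROC discrimination analysis.

## Network model

Edge length is defined as the reciprocal of the tract count,
$d_{uv} = 1/w_{uv}$, so strongly connected region pairs are *close*; absent
connections have infinite length. The path length between nodes $i$ and $j$
is the minimum total length over paths, computed by Dijkstra's algorithm
from every source (`shortest_paths_all()`, via igraph).

The four global measures are:

* **wCPL** — the weighted characteristic path length: the arithmetic mean of
  the shortest path lengths over unordered node pairs. Disconnected pairs
  are excluded from the mean and counted (`n_disconnected_pairs`), rather
  than rendering the measure infinite; the count is surfaced for quality
  control. On empirical near-connected networks this choice keeps the
  statistic finite while making any disconnection visible.
* **GE** — global efficiency, the mean of inverse shortest path lengths with
  disconnected pairs contributing zero. GE is dominated by short paths where
  wCPL is dominated by long ones; on a connected graph the AM–HM inequality
  forces $GE \ge 1/\mathrm{wCPL}$ with equality only when all pairwise
  distances are equal (this is tested).
* **CC** — the weighted clustering coefficient in the geometric-mean
  triangle form with weights normalised by the global maximum (the Onnela
  form, the default of the standard brain-connectivity toolbox). Nodes with
  binary degree below two contribute zero. This form is invariant under
  uniform rescaling of all counts.
* **SWN** — small-worldness. The plain definition used here is the ratio
  CC/wCPL. Because that ratio is scale-dependent (it scales linearly with a
  uniform rescaling of counts), a normalised variant is also provided:
  CC and wCPL are each divided by their means over an ensemble of
  degree-preserving rewired null networks (`rewire_null()`), giving the
  conventional small-world sigma. Rewiring uses weighted double-edge swaps
  in which each edge carries its weight, so the binary degree sequence and
  the weight multiset are both preserved exactly. Log-transformed SWN is
  carried alongside, since the ratio is strongly right-skewed in practice;
  non-positive values are rejected before the logarithm.

A documented ambiguity: characteristic path length is sometimes described as
a harmonic mean of distances. The arithmetic mean is implemented, matching
the operational definition the reference toolbox uses; the harmonic
counterpart is effectively what GE reports (as an inverse), so both
perspectives are available.

## Synthetic cohort generator

No clinical imaging data ship with the package; `generate_cohort()` creates
cohorts with the statistical structure the analysis assumes, so every
downstream stage is testable end to end.

* **Design.** Default group sizes are 9 unexposed controls, 53 trauma-exposed
  responders without PTSD and 47 with PTSD (N = 109), with MDD comorbidity
  drawn at rate 0.4 inside the PTSD group — within the 30–50% comorbidity
  range reported for trauma populations. Symptom-checklist eligibility
  follows the case definition: cases keep PCL > 40, non-cases PCL < 30; the
  filter is applied and its removals logged (by construction of the PCL draw
  it removes nobody under defaults, which is itself asserted in tests).
* **Anatomy.** 62 nodes (the DKT cortical parcellation size) are placed on a
  unit sphere; an edge backbone is drawn with presence probability decaying
  exponentially in inter-node chord distance (rate 3 relative to the maximum
  distance), augmented by a random ring to guarantee connectivity. Base
  tract counts are log-normal (meanlog −3.6, sdlog 0.6).
* **Subject variation.** Each subject scales the backbone by a log-normal
  factor (sdlog 0.45) and multiplies per-edge log-normal noise (sdlog 0.2).
  Because wCPL is approximately inversely proportional to the subject
  factor, the resulting wCPL distribution is right-skewed. These values were
  fixed once so that the synthetic wCPL distribution matches the scale of
  published subject-level values (median near 50–60 in arbitrary inverse
  count units, a long right tail with roughly a tenth of subjects above the
  report threshold of 80, sample skewness above 1).
* **Group effect.** PTSD subjects have their long-range edges (above-median
  inter-node distance) divided by $1 + a$. Attenuating long edges is the
  minimal mechanism that lengthens paths without changing node count or
  density; the knob $a$ maps monotonically to the realized Cohen's d of the
  PTSD-vs-exposed wCPL contrast. `calibrate_attenuation()` bisects $a$ until
  the mean realized d over replicate cohorts hits a target; the default
  $a = 0.5$ is the calibration output for a target d of 0.42 (the published
  contrast magnitude) and achieved d ≈ 0.38 at calibration tolerance 0.05.
* **Symptoms.** Domain scores (re-experiencing, avoidance, hyperarousal,
  negative affect) are drawn per group with the published group means and
  SDs, coupled to the realized wCPL through a Gaussian copula on
  within-subgroup rank-normal scores. Correlation targets are configured on
  the disjoint partition non-PTSD / PTSD-without-MDD / PTSD-with-MDD
  (defaults +0.25 / −0.2 / −0.6), reproducing the qualitative pattern of
  positive symptom–wCPL association outside MDD and strong negative
  association in comorbid subjects. The overall score is the sum of the four
  domains. Marginal means and SDs are preserved up to Monte-Carlo error and
  mild truncation at zero; rank correlations land within ±0.1 of target at
  subgroup sizes of 200 or more (tested).
* **Reproducibility.** A single master seed fans out to per-subject
  substreams through a fixed integer recurrence, so cohorts are bit-identical
  across runs and subsetting a cohort does not perturb other subjects'
  draws.

What the generator does *not* emulate: real DKT geometry or tract anatomy,
tractography error structure, scanner effects, or any nodal-level group
difference. Passing tests therefore demonstrate that the analysis chain is
correct and well-calibrated under its own assumptions, not that those
assumptions hold in any particular imaging study.

## Statistical battery

All tests return a uniform `stat_result` row (method, contrast, estimate,
effect size, statistic, df, p, adjusted p, n), and every analysis reports
the n actually used, so listwise deletion is visible.

* `welch_t()` — Welch's unequal-variance t-test; the companion effect size
  is Cohen's d with the pooled-SD convention (the most common companion to
  Welch reporting; users comparing variants should note this choice).
* `one_way_anova()` — classical equal-variance F test.
* `trend_test()` — Cuzick's Wilcoxon-type trend test across the ordered
  groups (control < exposed < PTSD), normal approximation with tie
  correction. The published analysis names only "non-parametric trend
  tests"; Cuzick's is the standard choice.
* `adjusted_group_contrast()` — Gaussian linear model of metric on group
  plus covariates; with three groups each pairwise contrast is fit on its
  subset. Constant covariates are dropped (reducing to the unadjusted
  pooled test), confounded designs raise a rank-deficiency error.
* `adjusted_spearman()` — the partial-Spearman construction: rank-transform
  both variables, residualize each on the covariates by least squares,
  correlate the residuals, with $t = \rho\sqrt{(n-2-q)/(1-\rho^2)}$ on
  $n-2-q$ df where $q$ counts the covariate design columns. With no
  covariates this reduces to plain Spearman with the t approximation.
* `bh_fdr()` — Benjamini–Hochberg step-up; applied per subgroup over the
  five symptom domains in the correlation stage (configurable family).
* `ols_standardized()` — OLS on z-scored response and continuous predictors,
  reporting standardized betas.
* `distribution_diagnostics()` — moment skewness $g_1$ and kurtosis in both
  conventions (Pearson and excess), since published kurtosis values often
  leave the convention unstated.
* `outlier_sensitivity()` — removes the k highest-wCPL subjects within one
  named group only, re-runs a supplied analysis on both samples and counts
  subjects above a reporting threshold.
* `roc_auc()` — Mann–Whitney AUC (ties half-weighted) with the DeLong
  placement-variance 95% CI; `combined_score()` fits an in-sample logistic
  model of the label on imaging features plus demographics and reports the
  apparent AUC, flagged as uncorrected — matching a single-cohort design in
  which no held-out data exist. Perfect separation falls back to a
  ridge-penalized fit (glmnet, small fixed penalty) with a warning. For the
  "PTSD without MDD" contrast, comorbid subjects are excluded from the
  comparison set.

Type-I error of every test is verified by null simulation (2000 replicates,
rejection rate required inside [0.03, 0.07] at the 5% level), BH by 5000
mixed null/alternative replicates, and the DeLong interval by coverage
simulation at 50 + 50 binormal scores.

## Numerical and degenerate-input choices

* Asymmetric input matrices are mean-symmetrized when the maximum asymmetry
  is within a relative tolerance (default 1e-6) of the largest weight, with
  a logged message; larger asymmetries are errors naming the offending cell.
  Deterministic tract counting should produce symmetric matrices, so the
  default tolerance is strict.
* Nonzero diagonals are zeroed (self-tracts carry no path information).
* Identical samples in `welch_t` return t = 0, p = 1 rather than the 0/0
  failure of the raw formula; zero variance in *both* samples with unequal
  means is an error.
* Saturated correlations (|rho| = 1) report p = 0 rather than a failed t.
* All-tied ROC scores return AUC 0.5 with a warning.
* Tie handling in ranks uses midranks throughout; the trend test applies the
  standard tie correction to its variance.

## Problem sizes

The shipped tests and drivers use the study-design cohort (109 subjects,
62 nodes) for end-to-end runs, 20-node cohorts for generator property
checks, graphs of up to 12 nodes (200 replicates) against an independent
Floyd–Warshall oracle for the shortest-path engine, 50 replicate cohorts for
effect-size recovery, and the simulation sizes listed above for the
statistical calibration checks. These sizes were chosen to make the full
suite comfortably reproducible on a laptop.

## Typical use

```{r example}
library(connectopath)
cfg <- cohort_config(seed = 1)
run <- run_pipeline(cfg, out_dir = "results/run")
report_run(run)
```

The numbered scripts under `analysis/` execute the same stages one at a
time, writing each table under `results/`.

## Known limitations

* Global measures only — no nodal, edge-wise, modularity or rich-club
  statistics.
* Apparent (in-sample) AUC only; no cross-validation or bootstrap optimism
  correction.
* The generator's effect mechanism (uniform long-range attenuation) is one
  of many that could produce a group wCPL shift; recovery results do not
  identify the mechanism.
* No imaging-format input (NIfTI/DICOM/tractograms): the package consumes
  the tract-count matrices a tractography pipeline emits.
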