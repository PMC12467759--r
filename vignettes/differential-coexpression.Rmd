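---
title: "Methods: differential expression and co-expression across two IDH-status cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and co-expression across two IDH-status cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

Lower-grade gliomas split into two clinically distinct groups by isocitrate
dehydrogenase (IDH) mutation status, and the mutation leaves a broad
transcriptomic footprint. This package implements a deliberately simple,
rank- and correlation-based workflow for characterising that footprint across
two independent cohorts measured on different platforms (e.g. RNA-seq counts
summarised by RSEM, and normalised microarray intensities), where anything
that depends on a distributional model of one platform would not transfer to
the other.

The workflow has seven stages, each a plain function:

1. **Differential expression (DEG).** Per gene, a two-sided Wilcoxon rank-sum
   test between MUT and WT samples; direction is called from the group means
   (UP = higher in MUT). Both Bonferroni and Benjamini–Hochberg (BH)
   adjustments are computed over the family of all genes tested in that
   cohort.
2. **Cross-cohort DEG replication.** Genes significant in both cohorts *with
   the same direction* are kept. The intended usage, mirrored in the
   defaults, is Bonferroni in the well-powered cohort and BH in the small
   one: a stringent family-wise criterion in a small, unbalanced cohort
   leaves almost nothing to replicate, so the second list is relaxed to an
   FDR criterion — explicitly, never silently.
3. **Differential co-expression (DCE).** Genes are filtered to the top 25% by
   pooled variance; all remaining pairs are tested for a change in Pearson
   correlation between groups using the Fisher z statistic
   \( Z = \frac{\operatorname{atanh} r_1 - \operatorname{atanh} r_2}
   {\sqrt{1/(N_1-3) + 1/(N_2-3)}} \),
   referred to the standard normal, with the pair family
   \(\binom{m}{2}\) as the correction family.
4. **Cross-cohort DCE replication.** Three views: strict overlap of
   significant pairs (canonical pair keys, so (A,B) matches (B,A)); the
   relaxed direction-consistent rule (same sign of \(r_\mathrm{mut} -
   r_\mathrm{wt}\) in both cohorts, corrected-significant in one and at least
   nominally significant, raw \(p < 0.05\), in the other); and the
   intersection of the genes participating in each cohort's significant
   pairs.
5. **Integration.** The replicated DEG list intersected with the common DCE
   genes, with provenance — genes whose mean expression *and* co-expression
   partners both change are candidates for core processes.
6. **Enrichment and network clustering.** Hypergeometric (one-sided,
   over-representation) tests against user-supplied GMT collections with BH
   FDR per collection, and Markov clustering (MCL) of the integrated genes on
   a user-supplied weighted interaction network.
7. **Classification and signature export.** LASSO logistic selection of
   predictor genes in one cohort, plain logistic evaluation on the other,
   AUC-scored; and export of the top-150 up/down replicated DEGs as GRP
   lists for connectivity-map-style queries.

# Statistical assumptions

* The Wilcoxon test assumes exchangeability under the null and nothing about
  the expression scale — it is invariant under strictly monotone transforms,
  which is exactly why it is used on platform-native values. No internal log
  transform is applied anywhere.
* The Fisher z test assumes approximate bivariate normality of each pair
  within each group, and \(N > 3\) per group (the variance of
  \(\operatorname{atanh} r\) is \(1/(N-3)\)). At the cohort sizes targeted
  here (N from 14 to 415) the normal approximation of the z difference is
  accurate; the smallest group drives the power.
* Direction calls use group means ("mean expression changes"); exact mean
  ties give direction `NONE`, which never replicates.
* Both DEG and DCE p-values are two-sided: gains and losses of expression
  and of co-expression are equally interesting.

# Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `alpha` | 0.05 | FWER or FDR level | conventional |
| `fraction` (variance filter) | 0.25 | fraction of genes | keeps the pair family tractable while retaining the variable genes that can show correlation changes |
| correction methods | Bonferroni (large cohort), BH (small) | — | the stringent-then-relaxed two-step described above |
| `nominal_alpha` (relaxed replication) | 0.05 | raw p | the standard nominal level |
| MCL `inflation` / `expansion` | 2.0 / 2 | — | canonical MCL defaults |
| MCL `prune`, `tol`, `max_iter` | 1e-5, 1e-6, 100 | — | below the scale of any attractor mass at these graph sizes |
| `top_k` (GRP export) | 150 | genes per direction | the connectivity-map input limit |
| `n_folds` | 10 | CV folds | glmnet convention; folds are stratified by class, with a fixed seed, because a 14-sample WT group otherwise produces single-class folds |

# The synthetic-data generator

`default_simulation_config()` fixes the study conditions: a large cohort of
93 WT / 415 MUT and a small one of 14 WT / 166 MUT (the two cohorts' group
splits), 2,000 genes, 50 DE genes at a ±2 SD shift with alternating signs,
and 20 DCE pairs whose group correlations change by the magnitudes seen in
replicated real pairs (0.93 vs 0.75 up to 0.88 vs 0.05, including sign
flips). Half of all planted signals are shared between the platforms;
platform-private signals are relocated to genes untouched on the other
platform. Ten of the DCE pairs sit inside the DE gene set, so the integrated
(DEG∩DCE) set is non-empty by construction. Correlated blocks are drawn from
a multivariate normal with an exchangeable correlation matrix — the minimal
structure that reproduces a target pairwise correlation — and generation is a
pure function of (seed, config, platform), with per-platform RNG substreams
so adding a platform never perturbs another's draws.

What the generator does *not* emulate: count-like marginals and
mean–variance coupling of RNA-seq (a lognormal marginal is available but the
tests use the Gaussian one), batch effects, probe-level noise,
heteroscedastic arrays, and correlated *backgrounds* (non-planted genes are
independent). Passing recovery tests therefore demonstrates the statistics
and the plumbing — sensitivity, direction handling, family-size correction,
cross-platform bookkeeping — not robustness to real-data artefacts.

# Numerical choices

* **Fisher transform at the boundary.** \(|r| \ge 1-10^{-7}\) is clamped to
  that boundary and flagged, so degenerate perfect correlations yield large
  finite statistics instead of infinities.
* **Tiny p-values.** The two-sided normal tail is computed in log space;
  `log_p` stays finite and exact far below the double-precision underflow of
  `p` itself, and tables serialise p-values at full precision.
* **Wilcoxon at tiny n.** An exact-enumeration mode (all
  \(\binom{n_1+n_2}{n_1}\) labelings, mid-ranks, doubled-tail two-sided p)
  backs the normal approximation. At \(n_1+n_2 \le 12\) the exact null is
  discrete — a single labeling can carry ~0.05 of probability — so pointwise
  agreement with the approximation is bounded by that granularity (mean
  agreement is ~0.01; see the test suite). At \(n = 30+30\) the approximation
  agrees with a \(10^5\)-rep permutation p within 0.02.
* **Permutation checks for the z test.** The label-permutation null of the
  correlation-difference statistic conditions on the pooled sample; its width
  varies from pool to pool (unlike a rank statistic, Z is not pivotal).
  Agreement with the asymptotic p is therefore asserted *on average across
  pools*, not within one pool's Monte-Carlo error.
* **Zero-variance genes.** Genes constant within a group have undefined
  correlations and are excluded from pairing (counted, reported); genes
  constant overall are handled by the variance filter. All-tied Wilcoxon
  inputs are flagged degenerate with p = 1.
* **Ties.** Variance-filter ties at the cutoff, GRP ranking ties, and MCL
  cluster-ranking ties all break by gene symbol, making every output
  deterministic and order-invariant.
* **MCL interpretation.** Self-loops use each node's maximum incident weight
  (1 for isolated nodes); attractor rows sharing nodes are merged, resolving
  the classic overlapping-attractor ambiguity deterministically. Clusters
  always refine connected components.
* **Logistic refit.** The cross-platform evaluation refits an unpenalised
  logistic model; aliased coefficients are zeroed and iterations capped,
  which is sufficient because AUC depends only on the score ordering, not on
  converged coefficient magnitudes under separation.

# Design decisions on genuinely open points

* **Probe collapsing** keeps the max-variance probe per gene — a standard
  convention (the upstream study does not state its rule) that interacts
  coherently with the downstream variance filter.
* **Variance filter on pooled samples** (both groups together), matching a
  filter described without a group qualifier.
* **Equation form.** The z statistic uses the standard Fisher form
  (\(\tfrac12\ln\frac{1+r}{1-r}\), square-root-combined variances). Published
  statements of such formulas sometimes lose the ½ and the radical to
  typesetting; the standard form is the one whose p-values match the
  magnitudes reported for replicated pairs (Z ≈ 6, not ≈ 12).
* **Enrichment background** defaults to the genes tested in the calling
  stage (a cohort's gene list, or the two cohorts' intersection for the
  replicated DEG list) — the universe from which the query could have been
  drawn. BH is used for FDR; no attempt is made to reproduce web-service
  specific corrections.
* **Classification protocol.** The published protocol fits the logistic
  model on the *target* cohort with the source-selected genes and reports its
  in-sample AUC; `cross_platform_eval()` implements that as `"refit"` and
  offers the stricter `"transfer"` protocol (fit on source, score target) as
  an option.
* **LASSO penalty** at minimum cross-validated loss ("minimal lambda"), with
  the cross-validated AUC computed from held-out prevalidated scores.

# Problem sizes

The bundled study and the verification suite run at desk scale: 2,000 genes
(500 after the variance filter, 124,750 pairs) per cohort, 20 null
replicates of a 50-gene study for test calibration, 100 replicates for
planted-pair power, and \(10^5\) permutations per oracle comparison. These
sizes were chosen so the whole suite re-runs in about a minute of compute
while every Monte-Carlo band stays narrow enough to be meaningful; all of
them scale up by changing one config argument.

# Limitations

* Enrichment and network stages depend entirely on user-supplied GMT and
  edge-list files; no annotation databases ship with the package.
* The MCL cluster count on a real protein-interaction network depends on the
  network provider's weighting and granularity settings; only the algorithm,
  not any provider's exact output, is reproducible here.
* The relaxed replication rule trades family-wise stringency for power
  exactly as described; it is a replication heuristic, not a joint test with
  a proven error rate.
* Connectivity-map scoring (tau) is out of scope: the package exports GRP
  signatures and stops there.
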