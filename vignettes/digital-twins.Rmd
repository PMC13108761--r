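---
title: "Digital-twin normative modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-twin normative modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmltwin)
```

## The model

`gmltwin` scores an individual's regional brain morphometry against a
*personalised* healthy reference rather than a population norm. The pipeline
has five statistical components.

**Feature space.** Each subject contributes 196 ICV-normalised regional
volumes (`volume / ICV`, dimensionless) plus one asymmetry index per
Left/Right pair, `AI = 2(L − R)/(L + R)`, which is bounded in `[−2, 2]` and
antisymmetric under hemisphere swap. The asymmetry index has no canonical
formula in the morphometry literature; this bounded form is the common
choice and is the one we test. Features are standardised by centre/scale
parameters learned on the healthy reference *only* and frozen before any
clinical subject is transformed — the reference defines the coordinate
system, and clinical data can never leak into it. ICV normalisation is by
ratio rather than residualisation: it matches how segmentation pipelines
report ICV and keeps the generative model closed under the normalisation.

**Manifold and digital twin.** The reference is embedded by principal
component analysis of the standardised features (default `d = 10`
dimensions), with component signs fixed so the fit is fully deterministic
and the out-of-sample transform is exact linear algebra: a reference row
transforms onto its own embedding coordinates to machine precision. We
chose a linear spectral embedding deliberately: every downstream contract —
neighbourhood preservation, determinism under a seed, exact reproduction of
reference coordinates, serialisability — is a property PCA provides by
construction, and the neighbour graph it induces on realistic morphometric
covariance (one dominant ageing axis plus disease-related directions) is
the quantity the twins actually consume. The embedding dimension matters
only through neighbour selection; `d = 10` keeps ~60% of reference variance
under the default generator and is configurable.

A subject's *digital twin* is the unweighted mean feature vector (original
feature units) of their `k = 30` nearest reference neighbours by Euclidean
distance in embedding space, ties broken by reference index. A
distance-weighted mean is a natural variant, but the unweighted mean is the
default because it has an exact hand-computable oracle and the difference
is negligible at `k = 30`.

**Local variability and GeoNorm z.** The 5% abnormality call needs a
*local* noise scale: variability among healthy brains that look like this
subject. For every reference subject *j* we precompute a leave-one-out
twin — the mean of *j*'s own 30 nearest neighbours excluding *j* — and the
residual `actual_j − twin_j`. A patient's per-feature `σ` is the SD of
those precomputed residuals over the patient's own 30 neighbours, floored
at `sigma_floor = 1e-6` standardised units so degenerate neighbourhoods
cannot produce infinite z. Then `z_r = (x_r − twin_r)/σ_r`, flagged when
`|z_r| > 1.96`. Asymmetry features participate in the manifold and are
scored, but only the 196 ROI z-scores count towards `n_abnormal`, which is
how regional deviation burdens are reported. Because `σ` is itself a
30-sample estimate, the null flag rate is not exactly 5%: the ratio is
approximately t-distributed with ~29 df, giving ≈ 6% in expectation. The
package's calibration checks therefore accept a [3%, 8%] band, and the
per-ROI mean/SD calibration is asserted on the bulk of regions (90% of 196)
rather than the extremes, which finite samples necessarily exceed.

**Brain age gap.** Brain age is the mean age of the 30 nearest healthy
neighbours; BAG subtracts chronological age (years). Nearest-neighbour age
averaging has an unavoidable regression-to-the-mean bias at the edges of
the reference age range — the youngest subjects can only have older
neighbours — so the package tests assert the *sign* of that edge bias
rather than pretending it is absent. Matched group contrasts are
unaffected because all groups share the bias.

**Downstream statistics.** Group comparisons are nonparametric
(`stats::kruskal.test`, `stats::wilcox.test`), with explicit degenerate
contracts (all-identical data gives H = 0, p = 1). "Most discriminative"
regions are ranked by ascending Mann–Whitney p, ties by |rank-biserial
effect| then ROI order, so the top-10 table is deterministic; direction
(increase vs atrophy) is the sign of the group-median z difference.
Column similarity between top-10 sets is Jaccard overlap. No
multiple-testing correction is applied to the per-ROI screen — it is a
descriptive ranking, not an inference, and the report says so.
The 2×2 Fisher exact test is implemented in-package by direct
hypergeometric enumeration (two-sided p = the sum of table probabilities
not exceeding the observed one, with a 1e-7 relative guard on the
comparison); the test suite verifies it against both an independent
log-factorial enumerator on every table with N ≤ 40 and
`stats::fisher.test`. K×2 biomarker tests use `stats::fisher.test`'s
network algorithm with a flagged chi-square fallback. Cluster membership
models use `nnet::multinom` with Wald summaries and a runaway-coefficient
separation flag. Bootstrap CIs for cluster conversion rates are percentile
intervals over within-cluster resampling (default 2000 replicates);
clusters smaller than 5 are flagged unstable.

**Pseudo-time.** Progression scores are graph geodesics: a symmetrised
k-NN graph over all embedded subjects plus a healthy-centroid node, edge
weights Euclidean, shortest-path distance from the centroid, min–max
normalised to `[0, 1]`. If the graph is disconnected the neighbour count is
raised (in steps of 5) until it connects, and the value used is recorded.
Trajectories of per-ROI z along pseudotime are penalised thin-plate-spline
GAMs (`mgcv::gam`, GCV-selected roughness), sampled at 10 equally spaced
pseudotimes, with the threshold crossing (smallest t where fitted
|z| ≥ 1.96) refined by root-finding between grid points; a smooth that
never crosses inside `[0, 1]` is reported censored. Calendar-time
interpretation of pseudotime is *not* computed: nothing in the method
identifies a months-per-unit scale, so the package reports normalised
pseudotime and leaves any calendar calibration to a user-supplied slope.

## What the synthetic generator emulates

`simulate_cohort()` is first-class, tested code. It plants exactly the
structure the analysis assumes, on a fixed deterministic ROI atlas
(`roi_catalog()`: 69 bilateral pairs, 9 midline structures, 49
hemisphere-merged "Sym" structures — a synthetic atlas echoing standard
whole-brain segmentation vocabularies):

* **Volumes** are a multiplicative model on the log scale:
  baseline × ICV scale × age factor × sex factor × disease factor ×
  log-normal noise (`noise_sd = 0.05`, i.e. ~5% volumetric noise, the
  scan–rescan ballpark for automated segmentation). Log-normality keeps
  volumes positive and all invariants closed under noise.
* **Ageing** is log-linear per ROI: parenchyma declines 0.25–0.45%/year,
  ventricles grow 1.2–1.8%/year. No growth-curve data informs the
  generator, so the simplest monotone model is used.
* **Disease severity** is a latent scalar with group means
  HC = 0 < RIS-NC = 0.35 < RIS-C = 0.55 < MS = 1.1 and a per-subject
  log-normal jitter (SD 0.2) that creates within-group progression spread
  (this is what gives pseudo-time something to order). Severity units are
  arbitrary; only the ordering and ratios matter. Early-involved structures
  (deep grey, white matter, ventricles) respond linearly in severity;
  diffuse cortical atrophy accrues as severity^1.5, making widespread
  cortical involvement disproportionately an established-disease feature —
  consistent with deep-grey-first atrophy sequences described in MS.
  Ventricles enlarge (3rd ventricle strongest), parenchyma atrophies.
* **Latent RIS subgroups** (4, equal sizes) carry five-year conversion
  risks 0.10/0.15/0.25/0.39; `converted` is a Bernoulli draw from the
  subgroup risk and defines the RIS-C/RIS-NC split. Structurally each
  subgroup has (i) a graded ventricular scale (0.4–1.2; higher-risk
  subgroups enlarge earlier — this is the planted onset gradient the
  trajectory analysis recovers) and (ii) a trait-like cortical signature:
  two reserved ROI sets span a rank-2 "block plane", and each subgroup
  atrophies its own linear combination of the two. The rank-2 construction
  is deliberate: a 2-D reduction can separate at most a plane of subgroup
  means, so four mutually orthogonal signatures would be geometrically
  unrecoverable by design, whereas the block plane makes the
  well-separated regime genuinely well separated (`subgroup_effect` scales
  it; 0 removes it for "hard" regimes).
* **Demographics and biomarkers.** Clinical groups are 77% female (exact
  count, so the cohort table reproduces the printed composition
  deterministically), ages ~N(41.2, 13.8²) truncated to the reference
  range (18–85, uniform for the reference). The four-biomarker panel
  (spinal cord lesion, infratentorial lesion, gadolinium enhancement, CSF
  oligoclonal bands) is *jointly* missing for an exact
  `1 − 94/152` fraction of RIS subjects, mirroring subject-level
  availability gaps; spinal-cord lesion probability varies by subgroup
  (0.20/0.45/0.45/0.20) — the planted cluster–biomarker association —
  while the others are constant.

What the generator does **not** emulate: scanner/site batch effects beyond
an optional multiplicative offset, realistic spatial covariance between
neighbouring regions, non-monotone ageing (childhood growth), lesion-driven
segmentation failure, and any image-level process. Passing tests on this
generator therefore demonstrate that the *pipeline* recovers planted
structure of realistic size and noise — not that it would survive every
artefact of real multi-site MRI.

## Numerical choices and degenerate inputs

* All embeddings are deterministic; every stochastic stage (cohort
  simulation, k-means starts, bootstraps) takes an explicit seed, and
  `run_pipeline()` derives per-stage seeds from one master seed by a single
  seeded `sample.int()` draw recorded in the manifest. Two runs with the
  same configuration are bit-identical.
* Neighbour ties are broken by reference index; k-means uses 25 random
  starts; cluster labels are renumbered by ascending conversion rate so
  reports are invariant to label permutation.
* Degenerate contracts are explicit: identical data gives H = 0/p = 1;
  a zero-variance neighbourhood hits the sigma floor; an all-converter
  cluster bootstraps to the degenerate CI [1, 1]; a constant biomarker
  tests at p = 1; a trajectory that never reaches the threshold is
  censored, not extrapolated into a crossing.
* Configuration validation rejects non-positive counts, conversion risks
  outside the open unit interval, and severity orderings that decrease
  across HC → RIS-NC → RIS-C → MS (all-equal severities are allowed — the
  null generator is a legitimate configuration).

## Problem sizes

The shipped tests run the full default study (1000 reference + 3×152
clinical subjects, 196 ROIs) for the end-to-end recovery checks, a
600-subject null cohort for calibration, an exhaustive Fisher comparison
over all 135,751 tables with N ≤ 40, and 500 bootstrap-coverage
replicates at cluster size 38 — sizes chosen so the whole suite documents
the method at the study's own scale while completing in about a minute.

## Known limitations

* The twin is only as healthy as the reference: pathology present in the
  reference population would be normalised away.
* BAG inherits the neighbour-age edge bias discussed above; absolute BAG
  near the reference age limits should not be over-read.
* The per-ROI screen is descriptive; its top-10 tables are stable under
  the planted effect sizes but are not corrected inferences.
* Pseudo-time is a cross-sectional ordering. It is *not* longitudinal
  time, and the package deliberately refuses to guess a calendar scale.
* K = 4 clusters is a fixed default matching the intended study design;
  silhouette-style diagnostics can inform other choices, but no automatic
  selection is performed.
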