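---
title: "Methods: 3D spinal-curve classification and outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D spinal-curve classification and outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinepath)
```

## The model

`spinepath` treats one spine at one timepoint as the 3D polyline through
the 17 vertebral-body centroids T1–L5, in millimetres, with x the
frontal-lateral axis (+ toward the patient's left), y the sagittal axis
(+ anterior) and z vertical (+ cranial). The pipeline assumes z is
strictly decreasing from T1 to L5 — true of any clinically plausible spine
— and rejects, rather than reorders, curves that violate it.

The analysis proceeds in four stages.

**Normalization.** Spinal size is a nuisance: a tall and a short patient
can carry the same deformity pattern. Each spine is therefore divided by
its vertical chord `z(T1) − z(L5)` (a single isotropic factor in all three
axes, so shape is preserved exactly) and translated so `z(L5) = 0`. The
"height" here is the vertical chord, not arc length — the chord is
well-defined for any monotone curve and keeps scaling linear. A z-grid
common to all patients is then built by averaging the scaled z-levels of
the non-scoliotic control spines per vertebra, and every patient's x(z)
and y(z) are resampled at those 17 levels by piecewise-linear
interpolation (no smoothing; linear interpolation reproduces the observed
centroids exactly and adds no model assumptions). Two decisions deserve
note:

* x and y are **not** re-centred. Lateral and sagittal offsets of T1
  relative to L5 are clinically meaningful (frontal/sagittal imbalance)
  and distinguish "balanced" from "unbalanced" curve types, so they are
  kept in the feature vector.
* After resampling, every curve is the 34-vector
  `(x₁…x₁₇, y₁…y₁₇)`; z carries no information because it is identical
  across patients by construction.

**Clustering.** K-means with squared-Euclidean cost is run on the
34-vectors at each timepoint independently. Implementation: Lloyd's
algorithm with k-means++ seeding, 100 restarts, convergence when
assignments stop changing or the within-cluster sum of squares improves by
less than 1e−10; the restart with minimal cost wins, and the cost is
asserted non-increasing at every iteration. The number of clusters k
maximizes the mean silhouette width over k ∈ {2, …, 6} (ties toward the
smaller k); points in singleton clusters are given silhouette 0, the
standard convention. Because K-means numbering is arbitrary, labels are
canonicalized: clusters are renumbered by descending size, ties broken by
lexicographic center comparison, which makes runs bit-reproducible under a
fixed seed (default 20181102).

**Fusion groups and treatment paths.** Patients sharing the same upper and
lower instrumented vertebrae (UIV, LIV) form a fusion group. Groups are
numbered in anatomical order of (UIV, LIV) — any deterministic rule works,
as group identity, not its printed number, is what enters the analysis.
Groups with fewer than 3 patients are excluded (default `min_group_n = 3`)
and the cohort retained after exclusion is what gets clustered, so cluster
sizes refer to analyzable patients. Each patient's treatment path is the
triple PO_i–EP_j–F_m. Within a (PO, EP) stratum, fusion groups whose
patients share the same modal two-year cluster are merged into one path
(counts added); this is a formalization of "fusion groups with the same 2Y
outcome" — the published compound paths cannot be regenerated from any
patient-level rule because one printed stratum assigns a fusion group to
two different merged paths, so the merge rule here is the package's own,
tested on synthetic data, and published tables are consumed as printed
counts.

**Outcome analytics.** The path-by-2Y contingency table yields per-path
concordance (modal-outcome share, reported as integer percent; paths with
at least `min_path_n = 3` patients qualify — "more than two") and coverage
(qualifying patients / all included patients). The path→outcome
association is tested by multinomial logistic regression with a
likelihood-ratio χ² against the intercept-only model,
`df = (non-intercept coefficients per equation) × (K − 1)`. Two encodings
are offered because the published model specification is ambiguous: the
default enters PO, EP and F as three nominal main effects (fitted with
`nnet::multinom`); the alternative enters the whole path as one saturated
factor, whose MLE is closed-form (per-path observed proportions), making
the LR statistic exactly the contingency G-statistic
`2 Σ n log(n/E)` and handling zero cells (complete separation) without
divergent iteration — separated coefficients are reported as infinite and
flagged rather than crashing. Predictions are empirical by default (modal
outcome of the observed triple; an unseen triple returns an explicit
no-data result, never a guess; ties go to the lower cluster index and are
flagged ambiguous).

## Clinical-style curve measures

Endplate Cobb angles, apical rotations and pelvic parameters require
vertebral orientation or pelvic imaging that centroid data do not contain.
The package computes centroid-curve surrogates instead: tangent-direction
range angles (central differences, one-sided at span ends) over standard
spans — proximal thoracic T1–T6, main thoracic T5–T12, lumbar T12–L5 in
the frontal plane; T1–T12 and T4–T12 kyphosis and L1–L5 lordosis in the
sagittal plane (the lordosis span ends at L5 because the curve does) — and
T1-versus-L5 balance offsets. All angle surrogates are invariant to rigid
translation and isotropic scaling. Rotational and pelvic values can be
supplied as pass-through columns. Between-cluster comparisons follow a
two-stage rule: Shapiro–Wilk within every cluster at α = 0.05; if all
clusters pass, one-way ANOVA with Tukey HSD, otherwise Kruskal–Wallis with
Dunn's rank post-hoc (implemented in-package; unadjusted p-values by
default, `p_adjust` available). Judging normality per cluster (rather than
pooled) is the package's formalization; a constant-valued cluster is
treated as non-normal. A simulation test verifies the two-stage omnibus
holds its nominal type-I error under the null.

## The synthetic-cohort generator

The generator exists so every stage is testable without imaging data. It
emulates a surgical right-thoracic AIS cohort: 67 patients with fusion
levels at the reference frequencies (including one 2-patient and one
1-patient level that the filter later removes), 20 controls, three PO /
two EP / three 2Y shape clusters with membership probabilities
proportional to the reference cluster sizes, and a planted
path→outcome map followed with fidelity φ (default 0.85, in the range of
the reference per-path concordances; the remaining mass is spread
uniformly over the other outcome clusters).

Templates are sums of Gaussian lobes in normalized height: frontal lobes
(a main thoracic bow with optional proximal and lumbar counter-lobes of
opposite sign, plus a constant lateral shift) and sagittal
kyphosis/lordosis lobes. Gaussian bumps were chosen because they are
smooth, compactly parameterized, and let apex level, amplitude and width
be controlled independently. The three PO templates encode qualitatively
distinct morphologies (balanced hypokyphotic; laterally shifted with a
large main lobe; S-shaped with proximal kyphosis and a strong lumbar
counter-curve); EP and 2Y templates have reduced frontal amplitudes
(post-correction shapes) and differ mainly in shift and kyphosis. Lobe
parameters were fixed once, during generator design, to satisfy two
structural conditions: minimum pairwise template feature distance of at
least 0.15 in unit-height scale (achieved: 0.40 PO, 0.36 EP, 0.48 Y2) and
roughly equilateral cluster geometry per timepoint — silhouette-based k
selection systematically merges the closest pair of clusters when the
third lies much farther away, so lopsided geometries would test the
selector's failure mode rather than its intended operation.

Noise is i.i.d. Gaussian with SD 0.02 (unit-height scale) added to x and y
only; z stays equally spaced over a per-spine height drawn uniformly from
380–480 mm, which keeps the monotone-z invariant by construction and makes
the control template exactly the equally spaced grid. Everything derives
from a single integer seed; the same seed yields byte-identical files.

What the generator does **not** emulate: vertebral orientation and axial
rotation (only pass-through scalars), arc-length effects of severe
deformity, measurement error structure of stereoradiographic
reconstruction, within-patient correlation of shapes across timepoints
beyond the planted cluster memberships, and any biomechanics of
instrumentation. Passing recovery tests therefore shows the pipeline
recovers planted low-dimensional curve structure under realistic noise —
not that it would classify real radiographic reconstructions identically.

## Numerical choices and degenerate inputs

* Convergence: restart-level tolerance 1e−10 on SSE improvement; the SSE
  is recomputed from final members so centers are exactly member means.
* Empty K-means clusters during iteration are re-seeded at the
  worst-fitted point; all-identical inputs are rejected for k ≥ 2.
* Silhouette with coincident points (a = b = 0) contributes 0.
* Modal and probability ties in prediction go to the lower cluster index
  and are flagged `"ambiguous"`.
* Non-monotone z, missing or duplicate vertebrae, unknown timepoint
  tokens, inverted fusion levels and non-finite coordinates are all
  rejected with errors naming the offending record.
* Landmark files are written at 17 significant digits so write∘read is
  the identity.

## Problem sizes used in the test suite

The suite verifies K-means against exhaustive enumeration of all
partitions (200 random instances, n ≤ 8, k ≤ 3), silhouette against a
brute-force oracle to 1e−12 (n ≤ 30), and the saturated LR statistic
against an independent G-statistic oracle (100 random tables). Parameter
recovery runs the full generator-to-clustering loop over 100 seeds at the
default study conditions, requiring the planted (3, 2, 3) cluster counts
and adjusted Rand index ≥ 0.9 in at least 95 of them, and checks planted
fidelity φ = 0.8 against its 95% binomial interval. These sizes make the
oracle checks exhaustive where exhaustiveness is feasible and keep the
stochastic checks well-powered.

## Known limitations

* The merge rule for equivalent fusion groups is a formalization; printed
  compound paths from the reference cohort are reproduced as data, not
  regenerated.
* The main-effects and saturated encodings bracket, but need not match,
  any particular published regression's degrees of freedom.
* Surrogate angles approximate, and are not interchangeable with,
  radiographic Cobb measurements.
* Empirical outcome prediction is frequency-based and silent (by design)
  on paths never observed.
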