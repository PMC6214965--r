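# spinepath

Data-driven classification of 3D spinal curves and surgical-outcome
prediction in adolescent idiopathic scoliosis (AIS).

## The problem

AIS is a three-dimensional deformity of the spinal column. Surgical
planning for posterior spinal fusion still leans on 2D radiographic
measurements and subjective curve typing, and outcomes at long-term
follow-up are hard to anticipate. `spinepath` implements an objective
alternative for cohorts observed at three timepoints — pre-operative (PO),
early post-operative (EP) and two-year follow-up (2Y) — using only the 3D
positions of the 17 vertebral-body centroids T1–L5 per spine:

1. **Two-step curve normalization.** Each spine is scaled isotropically by
   its vertical height `z(T1) − z(L5)` so that height equals 1, then the
   (x, y) coordinates are linearly resampled at the 17 reference z-levels
   obtained by averaging scaled non-scoliotic control spines. Every curve
   becomes a 34-vector `(x₁…x₁₇, y₁…y₁₇)` on a common vertical grid.
2. **Cluster classification.** K-means (Lloyd's algorithm, k-means++
   seeding, best of 100 restarts) clusters these vectors at each timepoint;
   the number of clusters k maximizes the mean silhouette width
   `s = (b − a)/max(a, b)` over candidate k ∈ {2,…,6}.
3. **Treatment paths.** Each patient's fusion level — the pair of upper and
   lower instrumented vertebrae (UIV, LIV) — defines a fusion group F_m;
   groups with fewer than 3 patients are excluded. The triple
   PO_i–EP_j–F_m is the patient's *treatment path*; within a (PO, EP)
   stratum, fusion groups with the same modal 2Y outcome are merged.
4. **Outcome prediction.** The path-by-2Y-cluster contingency table gives
   per-path concordance (the share of a path's patients in its modal
   outcome) and empirical predictions f(PO_i, EP_j, F_m) → 2Y_k; a
   multinomial logistic regression with a likelihood-ratio χ² test
   quantifies the association (main-effects or saturated-path encoding —
   the saturated LR statistic equals the contingency G-statistic).

A parametric synthetic-cohort generator with planted cluster templates,
fusion-level frequencies and a planted path→outcome map (followed with
fidelity φ) makes the whole pipeline testable end to end without any
imaging data.

## Worked example

```r
library(spinepath)

co  <- generate_cohort(cohort_spec(seed = 1))   # 67 patients + 20 controls
fit <- spinepath(co$landmarks, co$fusions)
fit
#> Spinal-curve classification and outcome model
#>   patients included: 64 (removed by fusion-group filter: 3)
#>   clusters (silhouette-selected): PO 3, EP 2, 2Y 3
#>   fusion groups: 6; treatment paths (merged): 17
#>   concordance: 11 paths with >= 3 patients cover 54/64 patients (84%)
#>   LR test (main encoding): chi-square = 38.50, df = 16, p = 0.00128
```

The fit recovered the three planted PO shapes, two EP shapes and three 2Y
shapes; 3 patients in rare fusion levels were excluded; 11 of the merged
paths contain at least three patients and cover 84% of the cohort, and the
path→outcome association is significant at α = 0.05. Predictions for new
path triples:

```r
predict(fit, data.frame(po = 3, ep = 1, fusion_group = 6))
#>         path outcome status
#> 1 PO3-EP1-F6       1     ok
```

On the packaged reference tables (a 67-patient right-thoracic AIS cohort),
the same machinery reports 8 distinct fusion levels, 3 excluded patients,
64 retained in 6 groups, 17 treatment paths of which 10 hold ≥ 3 patients
covering 56 patients (88%), and an 83% majority outcome for path
PO3-EP1-F6:

```r
concordance(reference_path_outcomes(), min_path_n = 3)
```

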