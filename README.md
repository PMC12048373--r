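# nodulematch

Tracking pulmonary nodules across serial chest CT examinations — deciding
that lesion *i* on today's scan is the same lesion as nodule *j* on the scan
three months ago — is tedious, error-prone, and increasingly delegated to
automated systems. `nodulematch` implements, as a tested R library and
command-line tool, a coordinate-level (data-minimalistic) matching pipeline
of the kind used in cloud-deployed follow-up software, together with the
evaluation machinery needed to characterize when and why such matching
fails. It is aimed at imaging scientists who evaluate lesion-tracking
algorithms and need a transparent reference implementation with ground-truth
simulation.

## The method

Given two exams of one patient, each reduced to a set of anatomical landmark
points and a table of detected nodule centroids (mm, patient space):

1. **Affine co-registration.** The baseline landmark set $X = \{x_i\}$ is
   registered onto the follow-up set $Y = \{y_j\}$ by a trimmed iterative
   closest point (ICP) solver over affine maps $T(x) = Ax + t$,
   $A \in \mathbb{R}^{3\times3}$. Each iteration assigns every transformed
   baseline landmark its exact nearest neighbour in $Y$, discards the
   $\lceil f n \rceil$ worst correspondences (default trim fraction
   $f = 0.1$, tolerating occluded or spurious landmarks), and solves the
   least-squares problem
   $\min_{A,t} \sum_{(i,j)} \lVert A x_i + t - y_j \rVert^2$
   in closed form, until the trimmed RMS distance stabilizes
   (tolerance $10^{-6}$ mm). No image intensities are used.
2. **Target-lesion selection.** At baseline, the ten largest solid lesions
   with diameter in [5, 30] mm are selected for evaluation.
3. **Distance-threshold pairing.** Selected baseline centroids are mapped by
   $T$ into the follow-up frame; a baseline/follow-up pair is a match
   candidate iff its Euclidean distance is strictly below 15 mm. One-to-one
   assignment is enforced greedily in ascending distance order.
4. **Outcome taxonomy and statistics.** Against ground truth, each selected
   lesion is exactly one of: *correct match*, *missed matching* (counterpart
   present but not linked), *incorrect assignment* (linked to a different
   nodule), or *false-positive detection*. Matching rates are reported with
   two denominators — all true nodules, and only nodules detected in both
   scans — stratified by localization (parenchymal / peripheral /
   juxtavascular / juxtaphrenic) and by per-exam nodule count (<20 / 20–50 /
   >50), with Pearson χ² tests, per-cell Pearson residuals
   $(O-E)/\sqrt{E}$, and Mann–Whitney U tests on per-exam rates.

Because no public dataset accompanies this problem, the package ships a
**synthetic-thorax simulator**: stylized lung geometry (ellipsoidal lungs,
diaphragm dome, line-segment vessel tree), landmarks on that geometry,
nodules placed according to a configurable localization mix, a random affine
exam-to-exam motion plus a caudal diaphragm displacement field that decays
away from the diaphragm, landmark occlusion/noise, detection dropout, true
disappearance, and false-positive injection — all deterministic given a
seed, with the true transform and true correspondences recorded.

## Worked example

```r
library(nodulematch)

cfg   <- synthetic_config(n_cases = 25, seed = 7)
study <- generate_study(cfg)        # 38 follow-up pairs
study[[1]]
#> <case_pair> C001_P1: 51 true nodules (>50), 51 baseline / 46 follow-up detections

res <- run_case_pair(study[[1]])    # register + select + match one pair
res$transform
#> <affine_transform> det = 0.9939 (orientation-preserving)
#> linear:
#>           [,1]      [,2]      [,3]
#> [1,]  0.982323  0.050658 -0.103757
#> [2,] -0.053376  0.991090  0.014446
#> [3,]  0.105434 -0.017482  1.006713
#> translation (mm):  11.1381 -19.2302  -9.7824
res$matches
#> <match_result> 10 pairs (< 15.0 mm), 0 baseline / 36 follow-up unmatched

ev <- evaluate_study(study)
ev$table
#> <outcome_table>
#>   lesions evaluated:    341
#>   overall rate:         88.8% (301/339)
#>   conditional rate:     100.0% (301/301)
#>   false positives:      0.6% (2/341)
#>   missed matching:      9.7% (33/339)
#>   incorrect assignment: 1.5% (5/339)
#>   per-case rate: median 90.0% (IQR 83.9-100.0%), n = 38
```

The estimated transform is a small rotation/scale (determinant ≈ 0.99,
orientation-preserving) with a ~25 mm translation — typical repositioning
between visits. Of the 341 selected baseline lesions, 2 were injected
false positives; of the 339 true nodules, 88.8% were correctly linked
overall. The conditional rate of 100% says every nodule *detected in both
exams* was linked correctly — here all errors stem from follow-up detection
dropout (missed matching), not from registration. `ev$by_localization` and
`ev$by_count_bin` hold the stratified tables, χ² results, and tidy Pearson
residual exports for association plots.

The same pipeline is scriptable from a shell via `inst/exec/nodulematch`
(`simulate`, `register`, `match`, `evaluate`, `report` subcommands), whose
defaults reproduce the constants above without any flags.

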