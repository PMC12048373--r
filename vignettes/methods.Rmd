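---
title: "Methods: landmark-based registration and longitudinal nodule matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark-based registration and longitudinal nodule matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulematch)
```

## The problem and the model

Serial chest CT of patients with pulmonary nodules — typically metastatic
disease under surveillance — requires linking each nodule on the follow-up
exam to its counterpart on the baseline exam before any size change can be
assessed. `nodulematch` implements a *coordinate-level* matching pipeline:
the only inputs are labeled 3-D anatomical landmark points and nodule
centroid tables (mm, patient space), never voxel data. This mirrors
data-minimalistic cloud deployments in which the prior exam's image volume
is no longer available at follow-up time, and it fixes the model class: the
exam-to-exam deformation is approximated by a single global affine map.

The pipeline is: (1) trimmed iterative-closest-point (ICP) estimation of an
affine transform between the two landmark sets; (2) selection of the ten
largest solid baseline lesions of 5–30 mm; (3) mapping of their centroids
into the follow-up frame and strict-inequality pairing under a 15 mm
Euclidean threshold with greedy one-to-one assignment; (4) classification of
each selected lesion against ground truth into correct match / missed
matching / incorrect assignment / false-positive detection, followed by
stratified χ² and Mann–Whitney analysis.

Key modelling assumptions, and where they bite:

* **A single affine map suffices.** True respiratory and postural change is
  nonrigid; the affine model absorbs global rotation, scaling and shear but
  not localized motion. The simulator's diaphragm displacement field exists
  precisely to probe this residual: nodules near the diaphragm move in a way
  the landmark-fitted affine cannot represent, which is the mechanistic
  reading of why juxtaphrenic nodules match worst.
* **Landmarks are informative but imperfect.** Nearest-neighbour ICP needs
  no label agreement between exams, and trimming (default 10%) tolerates
  landmarks occluded or spuriously detected in one exam. When both exams
  carry reliable labels, `use_labels = TRUE` reduces registration to one
  least-squares fit.
* **Matching is one-to-one.** Nodules do not merge or split within the
  15 mm scale of interest; greedy ascending-distance assignment is used
  (see *Design choices*).

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `threshold_mm` | 15 | mm | match iff distance strictly below; clinical operating point of the evaluated system class |
| `top_k` | 10 | – | evaluated baseline lesions per pair |
| `d_min_mm`, `d_max_mm` | 5, 30 | mm | inclusive diameter window of target lesions |
| `pleura_margin_mm` | 10 | mm | peripheral = within this distance of the pleura |
| `contact_tol_mm` | 2 | mm | operationalizes "directly adjacent" for juxtavascular/juxtaphrenic; the taxonomy never quantifies contact, and 2 mm is of the order of slice spacing |
| ICP `rms_tol_mm` | 1e-6 | mm | tight enough that exact-recovery experiments converge to numerical precision; cheap at landmark scale (tens of points) |
| ICP `max_iter` | 100 | – | never reached in practice at this scale |
| ICP `trim_fraction` | 0.1 | – | minimal robustness mechanism for missing/extra landmarks; set 0 for exact-recovery work |

## What the simulator emulates — and what it does not

`synthetic_config()` defaults encode the structure of the clinical cohort
the pipeline is meant for: ~100 cases of which 53% contribute a second
follow-up pair (~153 pairs in expectation), per-exam nodule counts from a
<20 / 20–50 / >50 regime mixture with weights 0.608/0.203/0.190, a
localization mix of 49.7/31.3/14.9/4.1% (parenchymal/peripheral/
juxtavascular/juxtaphrenic), and diameters from a log-normal truncated to
[5, 30] mm whose *truncated* median is 9.0 mm with IQR 7.1–11.7 mm
(meanlog 2.1502, sdlog 0.4128, fitted numerically to those quantiles).
Detection-error parameters were chosen once to be of the clinically
plausible order: follow-up dropout probability 0.09 (of the order of
reported missed shares), 0.25 expected injected false positives per baseline exam
(≈ reported false-positive counts per follow-up), disappearance probability
0.02, diaphragm shift 5 mm with 40 mm decay length (breath-hold
variability), 1 mm residual centroid jitter, 1 mm landmark noise, 10%
landmark occlusion.

Geometry is deliberately stylized — ellipsoidal lungs, a Gaussian diaphragm
dome, a line-segment vessel fan per lung — because only *distance queries*
(to pleura, diaphragm, nearest vessel) carry semantic weight for the
localization taxonomy. The pleura distance uses a radial approximation to
the point–ellipsoid distance; since the same query drives both nodule
placement and classification, the two are consistent by construction.

What passing tests on this simulator do **not** show about real data: there
is no intensity information, so detection difficulty is reduced to a flat
dropout probability rather than a contrast/size-dependent one; nodule
counts beyond the evaluated ten influence outcomes only through the
configured landmark occlusion, not through genuine detector confusion; the
diaphragm displacement is a single smooth caudal field, not true
respiratory kinematics; and the affine ground truth means the registration
model is well specified by design except where the displacement field
breaks it. Cohort-level medians and p-values of any real study are
therefore emulated qualitatively (directions and orderings), never
numerically.

## Numerical choices

* **Affine fit.** The least-squares problem is solved by QR on the
  homogeneous design `[X 1]`. If the paired source points are affinely
  dependent (rank < 4, e.g. coplanar), the minimum-norm solution is
  returned via the SVD pseudoinverse and flagged `rank_deficient`; callers
  see a well-defined transform rather than an error, since trimmed ICP can
  transiently select degenerate subsets.
* **ICP initialization** translates the moving centroid onto the fixed
  centroid with identity linear part — the standard start, and sufficient
  within the jitter ranges the simulator produces (rotations ≤ 10°, scale
  0.95–1.05, translations ≤ 20 mm).
* **Monotonicity.** The recorded per-iteration trimmed RMS is non-increasing
  by construction (new correspondences can only shorten distances; the fit
  can only reduce the residual on its own pairs); the test suite asserts
  this to 1e-12 relative tolerance. Divergence beyond 10× the initial RMS
  aborts with an error.
* **Determinism.** Nearest-neighbour ties break toward the lower fixed-point
  index; pairing ties break by (baseline id, follow-up id); selection ties
  at the k-th diameter break by lexicographically smaller lesion id. All
  randomness flows from one master seed through fixed per-pair derived
  streams, so studies are bit-reproducible and individual pairs can be
  regenerated in isolation.
* **Degenerate inputs.** Empty lesion tables yield empty match results;
  zero-denominator rates are reported as `NA` with a `defined = FALSE` flag;
  contingency tables with a zero margin raise a "degenerate table" error;
  expected cells below 5 warn.

## Design choices where the design was open

* **Strict threshold.** "Below 15 mm" is read as a strict inequality; a pair
  at exactly 15.0 mm is unmatched. The boundary has measure zero in
  practice, but tests pin the convention.
* **Greedy vs optimal assignment.** Greedy ascending-distance one-to-one
  assignment is deterministic, order-independent, and O(n² log n). It is
  *not* globally optimal on adversarial configurations (two near-tied
  candidates can force a worse total), but in the operating regime — nodule
  spacing large against residual registration error — it coincides with the
  max-cardinality, minimum-total-distance assignment, which the test suite
  verifies against exhaustive enumeration on a thousand domain-realistic
  instances. An optimal assignment solver was deliberately not substituted:
  the greedy rule is the behaviour being characterized.
* **Localization precedence** is juxtaphrenic > juxtavascular > peripheral >
  parenchymal, rarest and most specific first, so a nodule touching the
  diaphragm within 10 mm of the pleura is juxtaphrenic.
* **Two denominators.** The overall rate divides correct matches by all true
  nodules; the conditional rate divides by lesions whose counterpart was
  detected in both exams. The package keeps the both-scans set an explicit
  input (`followup_detected`), so simulation can distinguish
  registration-induced misses (counterpart detected but out of threshold)
  from detection dropout — in strict both-scans accounting the former sit in
  the conditional denominator.
* **Count bins** are [1, 19], [20, 50], [51, ∞): "less than 20 / 20 to 50 /
  more than 50" with an inclusive middle bin.
* **Per-case rates** use only the selected (≤ 10) lesions of that follow-up
  pair, excluding false positives from the denominator; pairwise
  Mann–Whitney p-values are reported unadjusted (a Holm flag would be easy
  to add, but unadjusted mirrors standard practice in this literature and is
  what the package reports).
* **χ²** is plain Pearson, no Yates correction, with residuals
  $(O-E)/\sqrt{E}$; Mann–Whitney is two-sided, exact by enumeration when the
  smaller group has ≤ 8 observations without ties, tie-corrected normal
  approximation otherwise.

## Problem sizes used by the test suite

The suite's simulation experiments are sized to be statistically decisive
yet quick: exact-recovery registration uses 60-landmark sets; the
end-to-end recovery and dropout-separation experiments use 70 pairs × 8
nodules (≥ 500 evaluated nodules, binomial SE ≈ 1.5 percentage points); the
localization-mix law-of-large-numbers check uses 2,000 nodules; the
diaphragm sweep uses 60 pairs × 10 nodules at shifts of 0/12/25 mm; the
count-bin sweep uses three 40-pair regimes with landmark occlusion growing
from 10% to 50% and landmark noise from 1 to 4 mm, emulating landmark
coverage loss in nodule-crowded lungs. The oracle-equivalence battery runs
1,000 matching instances of ≤ 6 lesions per side against exhaustive
enumeration.

## Known limitations

* Matching is pairwise (baseline vs one follow-up); longitudinal chains
  over three or more time points are out of scope.
* The simulator cannot validate image-level failure modes (attenuation,
  atelectasis, fibrosis); its false positives are geometric stand-ins.
* The radial pleura-distance approximation degrades far from the ellipsoid
  surface; it is accurate in the ≤ 10 mm shell where the peripheral
  definition operates.
* Real per-exam nodule counts correlate with detection difficulty in ways
  the flat dropout probability does not capture; count-bin effects in
  simulation are driven by the explicit occlusion configuration.
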