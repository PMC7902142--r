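---
title: "Online gait anomaly detection: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online gait anomaly detection: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitanomaly)
```

## The model

The package classifies walking subjects as normal or abnormal from
ordered binary silhouette frames, online: each subject is scored the
moment it passes, using only what has been observed so far plus the
labels of the first `L` subjects.

The working assumption is that *deviation from the population's normal
gait envelope indicates anomaly*: normal walkers resemble one another
strongly, abnormal walkers resemble normal walkers weakly. The
population envelope is the **full gait energy image (F-GEI)** — the
pixel-wise mean over subjects of each subject's **gait energy image
(GEI)**, itself the pixel-wise mean of that subject's `N` binary
frames. Pixels bright in the F-GEI are positions where walkers' bodies
dwell most; thresholding it yields a binary high-energy mask `E`. For
subject `i`, the fraction of `E` covered by frame `j` defines the
overlap vector `o_i`, and the feature used for classification is the
pair `(mean(o_i), sd(o_i))`.

Two properties of this feature matter:

* It requires neither gait-cycle detection nor frame synchronization.
  Because the mean and standard deviation ignore frame order, two
  subjects photographed at different gait phases are directly
  comparable. The flip side is that purely *temporal* anomalies
  (e.g., abnormal cadence with normal posture) are invisible to it.
* Both coordinates are proportions on the same scale, so clustering
  uses plain Euclidean distance without standardization.

Classification is **BC-COP-K-means**: boundary clamping, then
constrained clustering only if clamping is inconclusive.

* *Boundary clamping*: per labeled class, the per-dimension min/max box
  over that class's labeled members (never over predicted members —
  predictions must not widen the boxes). A new feature inside exactly
  one box takes that class directly, with no distance computation over
  the point set. Inside zero boxes, or inside two overlapping boxes,
  the decision defers to clustering. Bounds are inclusive.
* *COP-K-means* (`K = 2`): K-means in which each point is assigned to
  the nearest center not violating a must-link or cannot-link against
  already-assigned points. Constraints come from the labeled sets:
  must-links within a class, cannot-links across classes. The cluster
  holding the majority of labeled normals maps to "normal".

## The online flow

The first `L` subjects (labeled by visual inspection) form the
initiation stage: their GEIs seed the F-GEI (`m_count = L`), their
features seed the class boxes, and no predictions are emitted. Each
later subject triggers: GEI → incremental F-GEI update → mask `E`
recomputed → features → BC-COP-K-means → one detection record.

With `λ = 1` (all initiation labels normal — the deployment-relevant
case), `K = 2` still forces a split of what may be an all-normal
population, so early false alarms are an inherent cost of the
clustering component; boundary clamping is precisely the mitigation,
since most normal newcomers fall inside the normal box and never reach
the clustering step. We accept the forced split rather than special-case
it.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `L` | 4 | labeled initiation subjects (4–8 typical) |
| `N` | 16 | frames per subject after selection |
| `target_w` × `target_h` | 88 × 128 px | canonical silhouette canvas (the conventional energy-image template size) |
| `kernel_size` | 3 | side of the square closing element (denoising) |
| `bottom_cut_fraction` | 0.05 | bottom fraction of the body bounding box removed (floor contact) |
| `threshold_method` | `"otsu"` | F-GEI segmentation threshold rule |
| `frozen_features` | `FALSE` | see recomputation policy below |

## Numerical and design choices

**Threshold selection.** Otsu's criterion is evaluated over the
strictly positive F-GEI pixels only: the zero background outside the
walking envelope would otherwise dominate the histogram and drag the
threshold toward zero. Candidate thresholds are the observed gray
levels (any value between two adjacent levels induces the same split,
so this scan is exhaustive); an image whose positive pixels are all
equal has no class structure and is rejected as degenerate. A fixed
threshold remains available.

**Feature recomputation policy.** The mask `E` changes with every
F-GEI update, so by default the overlap features of *all* involved
subjects are recomputed from the current mask before each clustering
run — all vectors entering one clustering run are then commensurate.
The alternative (`frozen_features = TRUE`) freezes each subject's
feature at its own detection moment; it is cheaper and kept as a
sensitivity check, but mixes features measured against different masks.

**Standard deviation convention.** Population (divisor `N`): the
overlap vector is a complete fixed-length description of one subject,
not a sample from a larger population. The sample convention is
available for sensitivity analysis.

**Constraint handling.** Must-links are transitively closed into
components and cannot-links lifted to component pairs before
assignment. The raw pairwise check of the classical greedy algorithm is
order-dependent: two ends of a must-link chain can drift into different
clusters before the middle point is visited, declaring spurious
infeasibility. Component-level checking removes that artifact and
detects genuinely inconsistent constraint sets up front.

**Infeasibility and restarts.** Even with consistent constraints the
greedy assignment can strand a point whose cannot-link partners occupy
both clusters. Up to 10 seeded restarts are attempted — fresh centers
and, from the second attempt on, a reshuffled assignment order — before
the documented hard failure is raised. In the detection pipeline proper
this cannot occur: constraints there are complete cliques from at most
two labeled classes.

**Other clustering details.** Centers initialize to `K` distinct data
points drawn uniformly without replacement (seeded). A cluster emptied
during iteration is reseeded to the point farthest from its assigned
center. Convergence means an unchanged assignment, capped at 100
iterations. Frame-selection ties (two frames equidistant from a key
location point) resolve to the earlier frame, and a frame never serves
two key points.

**Morphology and components.** Denoising is one dilation followed by
one erosion (closing) with a square element, computed on a zero-padded
copy so the result is the closing of the foreground point set itself
rather than an artifact of any border convention. Body extraction keeps
the largest 8-connected component (silhouette parts frequently touch
only diagonally, which 4-connectivity would sever).

**Evaluation denominators.** CCR averages over post-initiation subjects
only (`i = L+1 … S`); initiation subjects are ground truth, not
predictions. ACCR consequently scores the abnormal subjects *with
detection records* — an abnormal subject inside the initiation window
has no prediction to score.

**Per-step seeds.** The clustering seed at detection step `m` is
`seed + 131 m`, so a replayed stream reproduces its records exactly
while successive steps do not share one initialization.

## The synthetic cohort generator

Real silhouette corpora for this task are rare, so the package renders
its own: a side-view binary walker (rectangular torso, disc head, two
legs whose horizontal spread follows one sinusoidal gait cycle over the
`N` frames), rasterized with integer arithmetic for bit-for-bit
reproducibility, with optional salt-and-pepper noise and interior
holes emulating segmentation defects.

Abnormality is expressed in silhouette *geometry* — postural lean
(shear), asymmetric leg swing, or reduced stride — never in timing,
because the overlap-summary feature is phase-insensitive by design; a
timing-only anomaly would be invisible to the method and make any test
built on it vacuous. The default cohort mirrors a small clinical study:
62 subjects, 12 abnormal, 16 frames each, subjects streamed in
seeded random order.

`effect_size` scales the perturbed parameter so that `effect_size = 1`
reproduces the normal distribution exactly (a null cohort). The default
is 5, which in lean mode shears the body by 0.32 px/row (≈ 18°) — a
gross, clinically obvious postural lean of the kind produced by
splinting or immobilizing a leg. This value was chosen to make the
default cohort *strongly* separable: at mild effect sizes the two
classes' feature tails overlap enough that even the globally optimal
two-cluster partition mixes them, which measures the cohort, not the
algorithm. Per-subject jitter on torso, head, leg and stride geometry
provides realistic within-class spread.

What the generator does **not** emulate: clothing and footwear
variation, carried objects, imperfect background subtraction beyond
pixel noise, perspective and scale change along the path, or multiple
subjects in frame. Passing tests on synthetic cohorts therefore
demonstrate the pipeline's correctness and its behavior under the
stated geometry, not field performance on camera data.

## Problem sizes used by the test suite

The end-to-end study runs the default 62-subject cohort under 10 random
subject orders for each of 5 cohort seeds (2,900 scored detections),
plus a smaller null-cohort grid; unit and property tests use reduced
canvases (44 × 64) and shorter sequences. These sizes keep the full
suite and the acceptance script each within a few minutes on one CPU
core while still exercising every stage at the study's native scale.

## Known limitations

* Phase-insensitive features cannot see temporal anomalies (cadence,
  freezing episodes shorter than a frame interval).
* The F-GEI is a single population template: a site whose normal
  population is multimodal (children and adults, say) violates the
  "one normal envelope" assumption.
* Early in a deployment (small `M`) the F-GEI and mask are noisy and
  the forced two-cluster split can flag normal subjects; accuracy
  stabilizes as subjects accumulate.
* Stream order genuinely affects results (the F-GEI each subject is
  scored against depends on who passed before); the tests assert
  determinism per order, never order-invariance.
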