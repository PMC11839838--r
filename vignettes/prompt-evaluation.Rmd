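---
title: "Evaluating promptable segmentation models on volumetric tumor MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating promptable segmentation models on volumetric tumor MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promptseg)
```

## The problem

Promptable 2D segmentation foundation models (Segment Anything and its
successors) accept *point prompts* — pixels marked foreground or background —
and return candidate masks. Used interactively, they are an attractive tool
for tumor contouring in radiotherapy planning: an expert clicks, inspects the
suggestion, and clicks again where the contour is wrong. `promptseg`
implements the automated stand-in for that expert: a simulation loop that
places prompts against a known ground truth, measures how the contour
improves with every click, and aggregates the result over whole 3D studies.

The package evaluates, for each tumor-containing 2D slice of a volume:

1. an initial foreground prompt at the tumor center — the argmax of the
   Euclidean distance transform of the ground-truth mask;
2. a model query returning **three** candidate masks with confidence scores
   (the ambiguity-aware contract of promptable models);
3. selection of one candidate by a configurable strategy;
4. the intersection over union (IoU) of the selection against ground truth;
5. a corrective prompt: foreground at the center of `gt \ pred` when the
   ground truth area is at least the predicted area, otherwise background at
   the center of `pred \ gt` — "center" again meaning the distance-transform
   argmax, restricted to the largest 8-connected component of the set
   difference, so the prompt always lands inside the region it is meant to
   fix;
6. repeat from 2 until the selection equals the ground truth or nine prompts
   have been placed.

The per-slice summary is the *best achieved IoU* over the (at most nine)
iterations and the first iteration attaining it.

## Mask-selection strategies

* **oracle** — the candidate with the highest IoU against ground truth. This
  emulates an expert who always keeps the best of the three suggestions; it
  is the primary metric because interactive use makes that choice cheap.
* **suggested** — the candidate with the highest model-reported confidence,
  i.e. what a non-interactive pipeline would take.
* **prev_slice** — the candidate most similar (by IoU) to the finalized mask
  of the previous slice. In sequential slice-wise contouring of redundant 3D
  data the previous slice approximates the current ground truth, so this
  strategy approaches oracle accuracy without requiring the expert to
  inspect all three candidates. The first slice of a volume has no
  predecessor and falls back to oracle selection.

Ties in any argmax resolve to the lowest candidate index; distance-transform
ties resolve to the lexicographically smallest (row, col); component-size
ties go to the component containing the lexicographically smallest pixel.
These conventions are arbitrary but frozen, because 3D stacking and the
byte-identical-rerun guarantee require bit-stable choices.

## From slices to volumes

Per-slice best masks are stacked back into a 3D volume per orientation
(transverse, sagittal, coronal; axes 3, 1, 2 of the voxel grid). Planes
without tumor ground truth are never evaluated and stay background. Volumes
from the three orientations are fused by per-voxel majority vote (foreground
iff at least two of three agree), and scored with the volumetric Dice
coefficient `2|A∩B|/(|A|+|B|)`. Because per-orientation errors are partly
independent, fusion reliably improves Dice on phantoms — the package asserts
the ordering, not any particular magnitude.

Cropped-mode experiments first fit a cuboid ROI to the 3D tumor extent plus
a margin (default 20 mm, voxelized by `round(margin / spacing)` per axis,
clipped to the grid; half-open 1-based boxes) and run the same loop on the
cropped grid. Masks are mapped back to full-grid coordinates through the
recorded ROI offset before stacking, so cropped and full runs fuse and score
on the same grid. Normalization — `round(v / max(volume) * 255)`, computed
once per 3D dataset *before* any cropping — is shared by both modes; the
alternative (renormalizing after cropping) would give the two experiments
different intensities and confound the comparison.  Rounding is half-up;
the choice only matters at exact .5 grey levels.

## The synthetic cohort

Real studies (e.g. BraTS-format NIfTI image/label pairs, tumor core =
necrotic + enhancing classes) plug in through `read_labeled_volume()`. The
default, fully self-contained mode generates phantoms:

* ground truth: a smooth union of `n_lobes` ellipsoidal lobes — each lobe
  contributes `exp(-2 q)` (`q` = squared normalized ellipsoidal distance)
  and the mask is `sum > exp(-2)`, so one lobe is exactly a sphere of the
  requested radius and extra lobes (0.3–0.5 of the primary radius, centers
  within one radius) blend into an irregular connected core;
* intensities: dark air, a bright brain ellipsoid, a 2-voxel
  contrast-enhanced rim at the mask boundary whose brightness scales with
  `rim_contrast`, a dimmed necrotic interior covering the deepest
  `necrotic_fraction` of the core (necrosis changes intensity only — the
  core mask always includes it), plus Gaussian noise.

`rim_contrast` is the morphology axis: ≥ 0.5 is tagged `HGG_like` (sharp,
strongly enhancing), below `LGG_like` (diffuse, low-contrast). The phantoms
deliberately do **not** model MRI physics (bias fields, sequence contrast,
edema, skull): passing tests demonstrate that the pipeline's bookkeeping,
statistics and orderings are correct, not that any particular model achieves
clinical accuracy on real MRI.

## The mock promptable predictor

The mock predictor closes the loop without model weights. Its candidates are
the slice ground truth degraded by a per-candidate morphological operation
(erode, dilate, or translate — assigned reproducibly per slice) whose pixel
magnitude is

```
max(0, corruption_level − improvement_rate · (n_prompts − 1))
  · (1 + 3.5 · (1 − contrast)²)
  · scale_j,   scale = (0.7, 1.0, 1.3)
```

where `contrast` is measured from the image itself (mean rim intensity minus
mean just-outside-ring intensity, on the 0–255 scale). The convex response
in lost contrast encodes that diffuse boundaries are disproportionally
harder to delineate; a linear response under-separates the two morphology
groups once magnitudes are rounded to integer pixel radii. Prompts are
honored locally with a fixed 3-px influence radius: a foreground prompt
falling outside a candidate forces its whole neighborhood in, a background
prompt inside forces it out — including the overshoot a real model would
show, which is why few-pixel tumors can never be repaired exactly and
accuracy rises with tumor area. Confidences blend the true-IoU rank with
uniform noise under `confidence_calibration` (1 = faithful ranking, 0 =
uninformative). `ambiguity_mode = "whole_object"` replaces one candidate at
the single-prompt stage with the whole bright-object support, reproducing
the well-known whole-brain-instead-of-tumor failure of ambiguous single
prompts.

All randomness is keyed by stable 31-bit hashes of
`(seed, image-content hash, candidate, n_prompts)`; the structural choice of
corruption operator omits `n_prompts` so candidates improve smoothly as the
degradation magnitude shrinks. The predictor is therefore a pure,
deterministic function of (image, prompts) — the same contract a real model
adapter must satisfy — and recovers each slice's ground truth through a
content-addressed registry populated by the study driver. It is a test
harness with controllable difficulty, not an emulation of any specific
model's error morphology.

## Statistics

* `summarize_values()` — mean and IQR (quantile type 7, linear interpolation
  between order statistics).
* `compare_groups()` — Wilcoxon signed-rank (paired) or rank-sum (unpaired),
  two-sided normal approximation with tie and continuity correction.
* `spearman_correlation()` — midrank Spearman ρ with the asymptotic
  two-sided p.
* `maxstat_threshold()` — maximally selected rank statistics for the optimal
  tumor-area cutpoint: the standardized two-sample Wilcoxon statistic is
  scanned over all distinct covariate values inside an inner quantile band
  (default 10–90%, at least 2 observations per side), and the cutpoint
  maximizing |z| is returned. The selection effect is adjusted by seeded
  permutation of the x–y pairing (default 1000 permutations, p = (1 + #{perm
  max ≥ observed}) / (B + 1)), which bounds the family-wise error over all
  candidate cutpoints exactly in distribution — a deliberate substitute for
  the asymptotic improved-Bonferroni approximation, chosen because it is
  language-agnostic and directly testable against brute force. Two caveats
  are recorded rather than corrected: slice-level observations are treated
  as independent (slices of one patient are in truth clustered), and with
  unbalanced groups the |z|-maximizing cutpoint can sit one datum beyond the
  planted boundary, because shifting the cut toward balanced group sizes
  shrinks the variance denominator — cutpoint recovery is therefore accurate
  to one datum, not to the exact gap.

## Determinism and problem sizes

Every sub-seed derives from one root seed via a stable polynomial hash; no
global RNG state crosses component boundaries, and the whole pipeline is
byte-identical across reruns of the same configuration. The shipped test
suite and the acceptance script run desk-scale studies — 32–40 voxel grids,
6.5–9 mm tumors, cohorts of 2–50 phantoms, corruption 3 px with improvement
0.25 px per prompt (so residual corruption persists at nine prompts;
with faster improvement every slice is solved exactly and orderings such as
high- vs low-grade accuracy become degenerate). These sizes were chosen as
the smallest cohorts at which the asserted orderings are stable across
seeds, and are stated here as the package's reference conditions.

## Known limitations

* The phantom's intensity model is geometric, not physical; no multi-sequence
  input, no edema class, no bias field.
* The mock predictor's corruption model is a stand-in: nothing is known
  quantitatively about a real foundation model's error morphology beyond
  published failure examples, so only *relative* statements (orderings,
  monotonicities, calibration contrasts) transfer to real models.
* Box, mask, and text prompts are out of scope; the evaluated interaction is
  points only.
* The permutation adjustment makes `maxstat_threshold()` O(B · n log n);
  for very large slice tables reduce `n_perm` or pre-aggregate.
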