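# promptseg

Automated evaluation of promptable 2D segmentation models on volumetric
tumor MRI, simulating the expert-interactive point-to-mask workflow used in
radiotherapy contouring.

Promptable foundation segmentation models (Segment Anything and its kin)
return **three** candidate masks per prompt set, each with a confidence
score. For tumor contouring, the questions that matter are: how good is the
best candidate after *k* corrective clicks, how much worse is the model's
own most-confident pick, how does accuracy depend on tumor size and
morphology, and how far does stacking 2D contours get you in 3D?
`promptseg` answers these with a fully automated simulation:

* **Prompt simulation** — the initial foreground prompt is placed at the
  tumor center (argmax of the Euclidean distance transform of the
  ground-truth mask); each corrective prompt goes to the center of the
  largest connected component of the error: foreground in `gt \ pred` when
  the ground truth area is at least the prediction's, background in
  `pred \ gt` otherwise, up to nine prompts per slice. The per-slice metric
  is the best IoU over iterations.
* **Triple-mask selection** — `oracle` (best calculated IoU vs. ground
  truth), `suggested` (highest model confidence), or `prev_slice` (most
  similar to the previous slice's mask, the automatic stand-in for an
  expert's choice in sequential slice-wise contouring).
* **3D evaluation** — per-slice best masks are stacked per orientation
  (transverse / sagittal / coronal), fused by per-voxel two-of-three
  majority vote, and scored with volumetric Dice
  (`D = 2·IoU / (1 + IoU)`).
* **ROI cropping** — experiments can run on sub-volumes fitted to the 3D
  tumor extent plus a 2-cm margin, with masks mapped back to the full grid.
* **Area-threshold analysis** — maximally selected rank statistics
  (standardized Wilcoxon statistic scanned over candidate cutpoints of the
  per-slice tumor area, permutation-adjusted p), Spearman correlation of
  best IoU vs. area, and Wilcoxon arm comparisons.
* **Synthetic mode (default)** — a phantom generator (bright-rim /
  necrotic-core tumors with a high- vs. low-contrast morphology axis on a
  brain-like background) plus a deterministic mock promptable predictor, so
  the entire pipeline runs and is tested without external data or model
  weights. Real NIfTI image/label pairs and any predictor satisfying the
  `(image, prompts) -> prediction_triple` contract drop in unchanged.

## Worked example

```r
library(promptseg)

ph <- generate_phantom(phantom_params(grid_shape = c(40, 40, 40),
                                      tumor_radius_mm = 9, n_lobes = 2,
                                      rim_contrast = 0.9, seed = 42))
ph
#> <labeled_volume> phantom_00042 [HGG_like] grid 40x40x40, spacing 1x1x1 mm, 3157 core voxels

reg <- gt_registry()
predictor <- make_mock_predictor(
  mock_predictor_params(corruption_level = 3, improvement_rate = 0.25,
                        confidence_calibration = 0.25, seed = 1),
  reg$lookup)

res <- run_study(list(ph), predictor,
                 strategies = c("oracle", "suggested"),
                 orientations = c("transverse", "sagittal", "coronal"))
subset(res$aggregates, grade == "all",
       c(strategy, orientation, n, mean_best_iou, mean_prompts_to_best))
#>   strategy orientation  n mean_best_iou mean_prompts_to_best
#>     oracle  transverse 18         0.785                 7.44
#>     oracle    sagittal 18         0.732                 7.83
#>     oracle     coronal 19         0.743                 7.53
#>  suggested  transverse 18         0.764                 7.28
#>  suggested    sagittal 18         0.725                 7.33
#>  suggested     coronal 19         0.721                 7.84

subset(res$volumes, strategy == "oracle")[c("orientation", "dice")]
#>  orientation  dice
#>   transverse 0.881
#>     sagittal 0.865
#>      coronal 0.875
#>        fused 0.914
```

Reading: on this high-contrast phantom the expert-interactive (oracle)
workflow reaches a mean best IoU of 0.785 on transverse slices after on
average 7.4 of the nine allowed prompts; selecting by model confidence
alone is consistently worse; and fusing the three orientations lifts the
volumetric Dice from 0.87–0.88 (single orientation) to 0.914.

The tumor-area threshold analysis runs on any per-slice table:

```r
thr <- maxstat_threshold(res$slices$gt_area_mm2, res$slices$best_iou, seed = 1)
thr
#> <threshold_result> best cutpoint 245 (|z| = 4.433, adjusted p = 0.000999, 41 candidates)
#>   mean response below/above: 0.7349 / 0.8127
```

i.e. slices with less than ~245 mm² of tumor are segmented markedly worse —
the scaled-down analogue of the few-tumor-voxel failure mode on real data.

## Command line

A thin CLI over the same functions ships at
`system.file("cli", "promptseg.R", package = "promptseg")` with subcommands
`generate`, `simulate`, `fuse`, `stats`, `report`, `all`, driven by a YAML
configuration (`experiment_config()` / `write_config()`); `--seed` and
`--outdir` override the file. `run_experiment()` is the equivalent R entry
point and writes per-trace, aggregate and volumetric CSVs, a threshold
JSON, and a log with the configuration hash.

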