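#' Intersection over union of two binary masks
#'
#' @param a,b Binary masks of identical shape.
#' @return `|a ∩ b| / |a ∪ b|`; defined as 1 when both masks are empty.
#' @export
compute_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- a > 0
  b <- b > 0
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' Bundle of three candidate masks with confidences
#'
#' The return contract of a promptable predictor: exactly three candidate
#' binary masks (to cover prompt ambiguity) plus the model's own IoU estimate
#' for each.
#'
#' @param masks List of 3 binary matrices of identical shape.
#' @param confidences Numeric vector of 3 finite confidence scores.
#' @return An object of class `prediction_triple`.
#' @export
prediction_triple <- function(masks, confidences) {
  if (!is.list(masks) || length(masks) != 3) stop("exactly 3 masks required")
  if (length(confidences) != 3 || !all(is.finite(confidences))) {
    stop("3 finite confidences required")
  }
  if (!identical(dim(masks[[2]]), dim(masks[[1]])) ||
      !identical(dim(masks[[3]]), dim(masks[[1]]))) {
    stop("candidate masks must share one shape")
  }
  structure(list(masks = lapply(masks, function(m) m > 0),
                 confidences = as.numeric(confidences)),
            class = "prediction_triple")
}

#' Place the initial foreground prompt at the tumor center
#'
#' The center is the foreground pixel with the highest Euclidean distance
#' transform (distance to the nearest background pixel); ties are broken by
#' the lexicographically smallest (row, col). If the mask covers the whole
#' image the geometric image center is used.
#'
#' @param gt Nonempty binary mask.
#' @return Data frame with one prompt (`row`, `col`, `label`, `iteration`).
#' @export
place_initial_point <- function(gt) {
  fg <- gt > 0
  if (!any(fg)) stop("cannot place a prompt on an empty mask")
  if (all(fg)) {
    p <- c(row = round((nrow(gt) + 1) / 2), col = round((ncol(gt) + 1) / 2))
  } else {
    dm <- dist_transform(fg)
    p <- dist_argmax(dm, fg)
  }
  data.frame(row = as.integer(p["row"]), col = as.integer(p["col"]),
             label = "foreground", iteration = 1L,
             stringsAsFactors = FALSE)
}

#' Compute the next corrective prompt
#'
#' If the ground-truth area exceeds the predicted area (ties included), a
#' foreground point is placed at the center of `gt \ pred`; otherwise a
#' background point at the center of `pred \ gt`. The "center" is the
#' distance-transform argmax of the largest 8-connected component of the
#' chosen set difference (component-size ties go to the component containing
#' the lexicographically smallest pixel), so the point always lies inside the
#' set difference.
#'
#' @param gt Nonempty binary ground-truth mask.
#' @param pred Binary predicted mask, different from `gt`.
#' @param iteration Iteration number recorded on the prompt.
#' @return One-row prompt data frame.
#' @export
next_prompt <- function(gt, pred, iteration) {
  gt <- gt > 0
  pred <- pred > 0
  if (!identical(dim(gt), dim(pred))) stop("mask shapes differ")
  if (!any(gt)) stop("ground truth is empty")
  if (identical(gt, pred)) {
    stop("prediction equals ground truth; no corrective prompt is defined")
  }
  fg_label <- sum(gt) >= sum(pred)
  diffmask <- if (fg_label) gt & !pred else pred & !gt
  lab <- label8(diffmask)
  sizes <- tabulate(lab[lab > 0])
  best_size <- max(sizes)
  cands <- which(sizes == best_size)
  if (length(cands) > 1) {
    # component containing the lexicographically smallest (row, col) pixel
    first_pix <- sapply(cands, function(ci) {
      px <- which(lab == ci, arr.ind = TRUE)
      px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
      px[1, ]
    })
    cands <- cands[order(first_pix[1, ], first_pix[2, ])]
  }
  comp <- lab == cands[1]
  dm <- dist_transform(comp)
  if (all(comp)) {
    p <- c(row = round((nrow(comp) + 1) / 2), col = round((ncol(comp) + 1) / 2))
  } else {
    p <- dist_argmax(dm, comp)
  }
  data.frame(row = as.integer(p["row"]), col = as.integer(p["col"]),
             label = if (fg_label) "foreground" else "background",
             iteration = as.integer(iteration),
             stringsAsFactors = FALSE)
}

#' Select one of the three candidate masks
#'
#' Strategies: `"oracle"` picks the candidate with the highest calculated
#' IoU against ground truth (an expert retaining the best suggestion),
#' `"suggested"` the candidate with the highest model confidence, and
#' `"prev_slice"` the candidate most similar (by IoU) to the finalized mask
#' of the previous slice. All ties resolve to the lowest index.
#'
#' @param triple A [prediction_triple()].
#' @param gt Ground-truth mask (used by `"oracle"`).
#' @param strategy One of `"oracle"`, `"suggested"`, `"prev_slice"`.
#' @param prev_mask Previous-slice mask, required for `"prev_slice"`.
#' @return List with `mask` and `index`.
#' @export
select_mask <- function(triple, gt,
                        strategy = c("oracle", "suggested", "prev_slice"),
                        prev_mask = NULL) {
  stopifnot(inherits(triple, "prediction_triple"))
  strategy <- match.arg(strategy)
  score <- switch(strategy,
    oracle = vapply(triple$masks, compute_iou, numeric(1), b = gt),
    suggested = triple$confidences,
    prev_slice = {
      if (is.null(prev_mask)) {
        stop("'prev_slice' selection requires a previous-slice mask")
      }
      vapply(triple$masks, compute_iou, numeric(1), b = prev_mask)
    })
  idx <- which.max(score)
  list(mask = triple$masks[[idx]], index = idx)
}

#' Simulate interactive point-to-mask segmentation of one slice
#'
#' Runs the automated evaluation loop: place the initial prompt at the
#' ground-truth distance-transform center; query the predictor; select a
#' candidate per the strategy; record its IoU; then, while fewer than
#' `max_points` prompts have been placed and the selected mask still differs
#' from the ground truth, place a corrective prompt against the currently
#' selected mask, re-query with the full prompt list, select, and record.
#' The best recorded IoU and the first iteration attaining it summarize the
#' slice.
#'
#' @param sample A [slice_sample()].
#' @param predictor A `promptable_predictor`.
#' @param strategy Mask-selection strategy (see [select_mask()]).
#' @param max_points Maximum number of prompts (default 9).
#' @param prev_mask Previous-slice mask for `"prev_slice"`.
#' @return An object of class `slice_trace` with fields `prompts`,
#'   `iou` (per iteration), `selected_index`, `best_iou`, `best_iteration`,
#'   `best_mask`, `terminated_early`, plus the sample's bookkeeping.
#' @export
simulate_slice <- function(sample, predictor,
                           strategy = c("oracle", "suggested", "prev_slice"),
                           max_points = 9, prev_mask = NULL) {
  stopifnot(inherits(sample, "slice_sample"))
  strategy <- match.arg(strategy)
  if (strategy == "prev_slice" && is.null(prev_mask)) {
    stop("'prev_slice' strategy requires 'prev_mask'")
  }
  gt <- sample$gt_mask
  prompts <- place_initial_point(gt)
  ious <- numeric(0)
  sel_idx <- integer(0)
  best_iou <- -1
  best_iter <- NA_integer_
  best_mask <- NULL
  selected <- NULL

  repeat {
    triple <- predict_masks(predictor, sample$image, prompts)
    check_triple_shape(triple, dim(gt))
    sel <- select_mask(triple, gt, strategy, prev_mask)
    selected <- sel$mask
    iou <- compute_iou(selected, gt)
    ious <- c(ious, iou)
    sel_idx <- c(sel_idx, sel$index)
    if (iou > best_iou) {
      best_iou <- iou
      best_iter <- length(ious)
      best_mask <- selected
    }
    done <- identical(selected, gt)
    if (done || nrow(prompts) >= max_points) break
    prompts <- rbind(prompts, next_prompt(gt, selected, nrow(prompts) + 1L))
  }

  structure(list(study_id = sample$study_id,
                 grade = sample$grade,
                 orientation = sample$orientation,
                 slice_index = sample$slice_index,
                 gt_area_mm2 = sample$gt_area_mm2,
                 roi_offset = sample$roi_offset,
                 full_shape = sample$full_shape,
                 strategy = strategy,
                 prompts = prompts,
                 iou = ious,
                 selected_index = sel_idx,
                 best_iou = best_iou,
                 best_iteration = best_iter,
                 best_mask = best_mask,
                 terminated_early = identical(selected, gt)),
            class = "slice_trace")
}

check_triple_shape <- function(triple, dims) {
  for (j in 1:3) {
    if (!identical(dim(triple$masks[[j]]), dims)) {
      stop(sprintf("predictor candidate %d has shape %s, expected %s",
                   j, paste(dim(triple$masks[[j]]), collapse = "x"),
                   paste(dims, collapse = "x")))
    }
  }
  invisible(TRUE)
}

#' Run a full evaluation study
#'
#' Enumerates volume x orientation x strategy x (full | cropped) arms. For
#' each arm all tumor-containing slices are simulated; per-orientation best
#' masks are stacked to 3D volumes, and when all three orientations are run
#' they are fused by majority voting. The `"prev_slice"` strategy processes
#' slices in ascending order and selects against the previous slice's
#' finalized mask (the first slice of a volume falls back to oracle
#' selection).
#'
#' @param volumes List of [labeled_volume()] objects (raw intensities;
#'   normalization is applied internally once per dataset).
#' @param predictor A `promptable_predictor`.
#' @param strategies Character vector of selection strategies.
#' @param orientations Character vector of slice orientations.
#' @param cropped Logical vector: run on full grids (`FALSE`), grids cropped
#'   to the tumor ROI plus `margin_mm` (`TRUE`), or both.
#' @param max_points Maximum prompts per slice.
#' @param margin_mm ROI margin for cropped arms (default 20 mm).
#' @return An object of class `study_result`: `traces` (list of
#'   `slice_trace`), `slices` (per-slice data frame), `volumes` (per-study
#'   volumetric Dice data frame, incl. fused rows when applicable), and
#'   `aggregates` (per-arm summaries).
#' @export
run_study <- function(volumes, predictor,
                      strategies = "oracle",
                      orientations = "transverse",
                      cropped = FALSE,
                      max_points = 9,
                      margin_mm = 20) {
  stopifnot(length(volumes) >= 1)
  strategies <- match.arg(strategies, c("oracle", "suggested", "prev_slice"),
                          several.ok = TRUE)
  orientations <- match.arg(orientations, names(.ORIENTATIONS),
                            several.ok = TRUE)
  traces <- list()
  vol_rows <- list()

  for (vol in volumes) {
    nv <- normalize_volume(vol)
    for (cr in cropped) {
      work <- if (cr) crop_volume(nv, fit_roi(nv, margin_mm)) else nv
      for (strat in strategies) {
        stacks <- list()
        for (ori in orientations) {
          samples <- extract_slices(work, ori)
          prev_mask <- NULL
          arm_traces <- vector("list", length(samples))
          for (i in seq_along(samples)) {
            s <- samples[[i]]
            register_sample(predictor, s)
            eff_strat <- strat
            pm <- NULL
            if (strat == "prev_slice") {
              if (is.null(prev_mask)) eff_strat <- "oracle" else pm <- prev_mask
            }
            tr <- simulate_slice(s, predictor, eff_strat, max_points, pm)
            tr$strategy <- strat
            tr$cropped <- cr
            prev_mask <- tr$best_mask
            arm_traces[[i]] <- tr
          }
          traces <- c(traces, arm_traces)
          stacks[[ori]] <- stack_traces(arm_traces, vol$full_shape)
          vol_rows[[length(vol_rows) + 1]] <- data.frame(
            study_id = vol$study_id, grade = vol$grade, strategy = strat,
            cropped = cr, orientation = ori,
            dice = volumetric_dice(stacks[[ori]], nv$gt_mask))
        }
        if (all(c("transverse", "sagittal", "coronal") %in% names(stacks))) {
          fused <- majority_vote(stacks[["transverse"]], stacks[["sagittal"]],
                                 stacks[["coronal"]])
          vol_rows[[length(vol_rows) + 1]] <- data.frame(
            study_id = vol$study_id, grade = vol$grade, strategy = strat,
            cropped = cr, orientation = "fused",
            dice = volumetric_dice(fused, nv$gt_mask))
        }
      }
    }
  }

  slices <- trace_table(traces)
  structure(list(traces = traces,
                 slices = slices,
                 volumes = do.call(rbind, vol_rows),
                 aggregates = aggregate_slices(slices)),
            class = "study_result")
}

#' Tabulate slice traces
#'
#' @param traces List of `slice_trace` objects.
#' @param max_points Number of per-iteration IoU columns to emit.
#' @return Data frame with one row per trace, including `iou_iter1..k`
#'   columns (NA beyond the trace length).
#' @export
trace_table <- function(traces, max_points = 9) {
  rows <- lapply(traces, function(tr) {
    iou_cols <- rep(NA_real_, max_points)
    iou_cols[seq_along(tr$iou)] <- tr$iou
    df <- data.frame(study_id = tr$study_id, grade = tr$grade,
                     orientation = tr$orientation,
                     slice_index = tr$slice_index,
                     strategy = tr$strategy,
                     cropped = isTRUE(tr$cropped),
                     gt_area_mm2 = tr$gt_area_mm2,
                     n_prompts = nrow(tr$prompts),
                     best_iou = tr$best_iou,
                     best_iteration = tr$best_iteration,
                     terminated_early = tr$terminated_early)
    df[paste0("iou_iter", seq_len(max_points))] <- as.list(iou_cols)
    df
  })
  do.call(rbind, rows)
}

aggregate_slices <- function(slices) {
  if (is.null(slices) || nrow(slices) == 0) return(NULL)
  arms <- unique(slices[c("strategy", "cropped", "orientation")])
  rows <- list()
  for (i in seq_len(nrow(arms))) {
    sel <- slices$strategy == arms$strategy[i] &
      slices$cropped == arms$cropped[i] &
      slices$orientation == arms$orientation[i]
    for (gr in c("all", unique(slices$grade[sel]))) {
      s2 <- sel & (gr == "all" | slices$grade == gr)
      sm <- summarize_values(slices$best_iou[s2])
      rows[[length(rows) + 1]] <- data.frame(
        strategy = arms$strategy[i], cropped = arms$cropped[i],
        orientation = arms$orientation[i], grade = gr,
        n = sm$n, mean_best_iou = sm$mean,
        iqr_lower = sm$iqr[1], iqr_upper = sm$iqr[2],
        mean_prompts_to_best = mean(slices$best_iteration[s2]))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d slice traces, %d studies\n",
              length(x$traces), length(unique(x$slices$study_id))))
  print(x$aggregates, digits = 3)
  invisible(x)
}

#' Export per-trace results
#'
#' @param result A `study_result`.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_trace_csv <- function(result, path) {
  utils::write.csv(result$slices, path, row.names = FALSE)
  invisible(result$slices)
}
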