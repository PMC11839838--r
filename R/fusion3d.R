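#' A stacked 3D mask volume
#'
#' @param mask 3D logical array on the full study grid.
#' @param orientation Provenance: slicing orientation or `"fused"`.
#' @param study_id Study identifier.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(mask, orientation, study_id) {
  stopifnot(length(dim(mask)) == 3)
  structure(list(mask = mask > 0,
                 orientation = match.arg(orientation,
                                         c(names(.ORIENTATIONS), "fused")),
                 study_id = study_id),
            class = "mask_volume")
}

#' Stack per-slice best masks into a 3D volume
#'
#' Each trace contributes its best-iteration selected mask at its slice
#' index; planes without a trace stay background (only tumor-containing
#' slices are ever evaluated, so the stacked volume is zero elsewhere by
#' construction). Masks from cropped-frame runs are mapped back to the full
#' grid using the recorded ROI offset.
#'
#' @param traces List of `slice_trace` objects sharing study and
#'   orientation, at most one per slice index.
#' @param grid_shape Full study grid shape.
#' @return A [mask_volume()].
#' @export
stack_traces <- function(traces, grid_shape) {
  stopifnot(length(traces) >= 1)
  ori <- unique(vapply(traces, `[[`, character(1), "orientation"))
  sid <- unique(vapply(traces, `[[`, character(1), "study_id"))
  if (length(ori) != 1 || length(sid) != 1) {
    stop("traces must share one study_id and one orientation")
  }
  ax <- orientation_axis(ori)
  pax <- plane_axes(ori)
  full_idx <- vapply(traces, function(tr) tr$slice_index + tr$roi_offset[ax],
                     numeric(1))
  if (anyDuplicated(full_idx)) stop("duplicate slice index in traces")
  vol <- array(FALSE, grid_shape)
  for (tr in traces) {
    m <- tr$best_mask
    k <- tr$slice_index + tr$roi_offset[ax]
    ri <- seq_len(nrow(m)) + tr$roi_offset[pax[1]]
    ci <- seq_len(ncol(m)) + tr$roi_offset[pax[2]]
    plane <- matrix(FALSE, grid_shape[pax[1]], grid_shape[pax[2]])
    plane[ri, ci] <- m
    if (ax == 1) vol[k, , ] <- vol[k, , ] | plane
    else if (ax == 2) vol[, k, ] <- vol[, k, ] | plane
    else vol[, , k] <- vol[, , k] | plane
  }
  mask_volume(vol, ori, sid)
}

#' Majority-vote fusion of three mask volumes
#'
#' A voxel is foreground in the fused volume iff it is foreground in at
#' least two of the three inputs.
#'
#' @param v1,v2,v3 [mask_volume()] objects on identical grids.
#' @return A fused [mask_volume()].
#' @export
majority_vote <- function(v1, v2, v3) {
  stopifnot(inherits(v1, "mask_volume"), inherits(v2, "mask_volume"),
            inherits(v3, "mask_volume"))
  if (!identical(dim(v1$mask), dim(v2$mask)) ||
      !identical(dim(v1$mask), dim(v3$mask))) {
    stop("mask volumes must share one grid")
  }
  votes <- v1$mask + v2$mask + v3$mask
  mask_volume(votes >= 2, "fused", v1$study_id)
}

#' Volumetric Dice score
#'
#' @param pred A [mask_volume()] or 3D binary array.
#' @param gt 3D binary ground truth on the same grid.
#' @return `2 |pred ∩ gt| / (|pred| + |gt|)`; 1 when both are empty.
#' @export
volumetric_dice <- function(pred, gt) {
  p <- if (inherits(pred, "mask_volume")) pred$mask else pred > 0
  g <- gt > 0
  if (!identical(dim(p), dim(g))) stop("grid shapes differ")
  denom <- sum(p) + sum(g)
  if (denom == 0) return(1)
  2 * sum(p & g) / denom
}

#' Write a mask volume as a NIfTI label
#'
#' @param mv A [mask_volume()].
#' @param path Output path.
#' @param spacing_mm Voxel spacing to record in the header.
#' @return Invisibly, the path.
#' @export
write_mask_nifti <- function(mv, path, spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(mv, "mask_volume"))
  img <- RNifti::asNifti(array(as.integer(mv$mask), dim(mv$mask)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask volume from a NIfTI label
#'
#' @param path NIfTI file path.
#' @param orientation,study_id Provenance to attach.
#' @return A [mask_volume()].
#' @export
read_mask_nifti <- function(path, orientation = "fused", study_id = "study") {
  mask_volume(as.array(RNifti::readNifti(path)) > 0, orientation, study_id)
}
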