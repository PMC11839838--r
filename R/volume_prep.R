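# Orientation convention: axis 1 = sagittal, axis 2 = coronal,
# axis 3 = transverse. Slicing along an orientation fixes that axis; the
# remaining two axes, in ascending order, form the (row, col) plane.

.ORIENTATIONS <- c(transverse = 3L, sagittal = 1L, coronal = 2L)

orientation_axis <- function(orientation) {
  orientation <- match.arg(orientation, names(.ORIENTATIONS))
  .ORIENTATIONS[[orientation]]
}

plane_axes <- function(orientation) {
  setdiff(1:3, orientation_axis(orientation))
}

#' Normalize a volume to the 8-bit range
#'
#' Divides every voxel by the dataset maximum, multiplies by 255, and rounds
#' half-up to the nearest integer, so the maximum voxel maps to 255.
#' Normalization is computed once per 3D dataset (before any cropping), so
#' full-slice and cropped experiments share intensities.
#'
#' @param vol A [labeled_volume()].
#' @return The volume with integer intensities in `{0, ..., 255}`.
#' @export
normalize_volume <- function(vol) {
  stopifnot(inherits(vol, "labeled_volume"))
  mx <- max(vol$intensities)
  if (mx <= 0) stop("cannot normalize an all-zero volume")
  vol$intensities <- round_half_up(vol$intensities / mx * 255)
  vol
}

#' One 2D slice of a study
#'
#' A tumor-containing plane extracted along an orientation: the intensity
#' plane replicated to three identical channels (the input contract of
#' promptable predictors trained on RGB images), the ground-truth plane, and
#' bookkeeping used later for stacking and the area analysis.
#'
#' @param image `nrow x ncol x 3` array with identical channels, integer
#'   intensities in `[0, 255]`.
#' @param gt_mask 2D logical mask with at least one foreground pixel.
#' @param orientation One of `"transverse"`, `"sagittal"`, `"coronal"`.
#' @param slice_index 1-based index along the orientation axis.
#' @param study_id,grade Propagated from the parent volume.
#' @param gt_area_mm2 Foreground pixel count times in-plane pixel area.
#' @param roi_offset Voxel offset of the parent (possibly cropped) grid.
#' @param full_shape Full-grid shape of the parent study.
#' @return An object of class `slice_sample`.
#' @export
slice_sample <- function(image, gt_mask, orientation, slice_index,
                         study_id, grade, gt_area_mm2,
                         roi_offset = c(0L, 0L, 0L),
                         full_shape = NULL) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  if (!any(gt_mask > 0)) stop("slice_sample requires a nonempty gt plane")
  structure(list(image = image,
                 gt_mask = gt_mask > 0,
                 orientation = match.arg(orientation, names(.ORIENTATIONS)),
                 slice_index = as.integer(slice_index),
                 study_id = study_id,
                 grade = grade,
                 gt_area_mm2 = as.numeric(gt_area_mm2),
                 roi_offset = as.integer(roi_offset),
                 full_shape = full_shape),
            class = "slice_sample")
}

#' Extract tumor-containing slices along an orientation
#'
#' Emits one [slice_sample()] per plane along the orientation axis whose
#' ground-truth plane is nonempty, in ascending index order. The same
#' nonempty-core selection rule is applied to all three orientations.
#'
#' @param vol A normalized [labeled_volume()].
#' @param orientation `"transverse"` (default), `"sagittal"`, or `"coronal"`.
#' @return List of `slice_sample` objects.
#' @export
extract_slices <- function(vol, orientation = "transverse") {
  stopifnot(inherits(vol, "labeled_volume"))
  ax <- orientation_axis(orientation)
  pax <- plane_axes(orientation)
  sp <- vol$spacing_mm
  pix_area <- sp[pax[1]] * sp[pax[2]]
  d <- dim(vol$intensities)
  out <- list()
  for (k in seq_len(d[ax])) {
    gt_plane <- slice_plane(vol$gt_mask, ax, k)
    n_fg <- sum(gt_plane)
    if (n_fg == 0) next
    img_plane <- slice_plane(vol$intensities, ax, k)
    img3 <- array(rep(img_plane, 3), c(dim(img_plane), 3))
    out[[length(out) + 1]] <- slice_sample(
      image = img3, gt_mask = gt_plane,
      orientation = orientation, slice_index = k,
      study_id = vol$study_id, grade = vol$grade,
      gt_area_mm2 = n_fg * pix_area,
      roi_offset = vol$roi_offset, full_shape = vol$full_shape)
  }
  out
}

slice_plane <- function(arr, axis, k) {
  switch(axis,
         `1` = arr[k, , , drop = TRUE],
         `2` = arr[, k, , drop = TRUE],
         `3` = arr[, , k, drop = TRUE])
}

#' Fit a cuboid region of interest around the tumor
#'
#' The box is the per-axis min/max extent of the ground-truth mask, extended
#' by `round(margin_mm / spacing)` voxels per axis and clipped to the grid.
#' Indices are 1-based with a half-open `[lower, upper)` convention.
#'
#' @param vol A [labeled_volume()].
#' @param margin_mm Nonnegative margin in mm (default 20, i.e. 2 cm).
#' @return An object of class `roi_box` with fields `lower`, `upper`,
#'   `margin_mm`.
#' @export
fit_roi <- function(vol, margin_mm = 20) {
  stopifnot(inherits(vol, "labeled_volume"), margin_mm >= 0)
  idx <- which(vol$gt_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("gt_mask is empty")
  d <- dim(vol$gt_mask)
  mvox <- round(margin_mm / vol$spacing_mm)
  lower <- pmax(apply(idx, 2, min) - mvox, 1)
  upper <- pmin(apply(idx, 2, max) + mvox + 1, d + 1)
  structure(list(lower = as.integer(lower), upper = as.integer(upper),
                 margin_mm = as.numeric(margin_mm)),
            class = "roi_box")
}

#' Crop a volume to a region of interest
#'
#' Returns the sub-volume covered by `box` and records the offset
#' (`roi_offset`) and the full grid shape so that masks predicted in the
#' cropped frame can be mapped back to the full grid.
#'
#' @param vol A [labeled_volume()].
#' @param box An [fit_roi()] box.
#' @return A [labeled_volume()] on the cropped grid.
#' @export
crop_volume <- function(vol, box) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(box, "roi_box"))
  i <- box$lower[1]:(box$upper[1] - 1)
  j <- box$lower[2]:(box$upper[2] - 1)
  k <- box$lower[3]:(box$upper[3] - 1)
  out <- vol
  out$intensities <- vol$intensities[i, j, k, drop = FALSE]
  out$gt_mask <- vol$gt_mask[i, j, k, drop = FALSE]
  out$roi_offset <- as.integer(vol$roi_offset + box$lower - 1L)
  out$full_shape <- vol$full_shape
  out
}

#' Read an image/label NIfTI pair as a labeled volume
#'
#' @param image_path Path to the intensity NIfTI.
#' @param label_path Path to the co-registered label NIfTI.
#' @param core_classes Optional integer label values forming the target
#'   class (e.g. necrotic core and enhancing tumor); by default any nonzero
#'   label is foreground.
#' @param grade,study_id Metadata to attach.
#' @return A [labeled_volume()]; voxel spacing is taken from the image
#'   header.
#' @export
read_labeled_volume <- function(image_path, label_path, core_classes = NULL,
                                grade = "HGG_like", study_id = NULL) {
  img <- RNifti::readNifti(image_path)
  lab <- RNifti::readNifti(label_path)
  ai <- as.array(img)
  al <- as.array(lab)
  if (!identical(dim(ai), dim(al))) {
    stop("image and label grids differ: ",
         paste(dim(ai), collapse = "x"), " vs ", paste(dim(al), collapse = "x"))
  }
  if (max(abs(RNifti::xform(img) - RNifti::xform(lab))) > 1e-4) {
    stop("image and label affines differ; volumes are not co-registered")
  }
  mask <- if (is.null(core_classes)) al > 0 else
    array(al %in% core_classes, dim(al))
  labeled_volume(ai, mask, RNifti::pixdim(img)[1:3],
                 grade = grade,
                 study_id = if (is.null(study_id))
                   sub("\\.nii(\\.gz)?$", "", basename(image_path)) else study_id)
}

#' Write a labeled volume as an image/label NIfTI pair
#'
#' @param vol A [labeled_volume()].
#' @param image_path,label_path Output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_labeled_volume <- function(vol, image_path, label_path) {
  stopifnot(inherits(vol, "labeled_volume"))
  img <- RNifti::asNifti(vol$intensities)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, image_path)
  lab <- RNifti::asNifti(array(as.integer(vol$gt_mask), dim(vol$gt_mask)))
  RNifti::pixdim(lab) <- vol$spacing_mm
  RNifti::writeNifti(lab, label_path)
  invisible(c(image_path, label_path))
}

#' Export per-slice metadata to CSV
#'
#' @param samples List of [slice_sample()] objects.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_slice_metadata <- function(samples, path) {
  df <- do.call(rbind, lapply(samples, function(s) {
    data.frame(study_id = s$study_id, grade = s$grade,
               orientation = s$orientation, slice_index = s$slice_index,
               gt_area_mm2 = s$gt_area_mm2)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
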