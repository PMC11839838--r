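#' Parameters for a synthetic tumor phantom
#'
#' Describes one synthetic study: a brain-like bright ellipsoid on a dark
#' background, carrying a multi-lobed tumor core whose boundary shell is
#' contrast enhanced and whose interior may be partly necrotic (dimmed).
#' `rim_contrast` is the morphology axis: values near 1 emulate sharply
#' enhancing high-grade lesions, low values emulate diffuse low-contrast
#' low-grade lesions.
#'
#' @param grid_shape Integer vector of 3 voxel counts, each >= 16.
#' @param spacing_mm Positive voxel spacing per axis, in mm.
#' @param n_lobes Number of ellipsoidal lobes (>= 1) forming the tumor core;
#'   1 gives a sphere of radius `tumor_radius_mm`.
#' @param tumor_radius_mm Radius of the primary lobe in mm.
#' @param rim_contrast Enhancing-rim contrast in `[0, 1]`.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise,
#'   in raw intensity units (the brain background level is 80).
#' @param necrotic_fraction Fraction of tumor-core volume (in `[0, 1)`)
#'   rendered as a dim necrotic interior. Necrosis affects intensity only;
#'   the ground-truth tumor core always includes it.
#' @param seed Integer seed; together with the other parameters it fully
#'   determines the phantom.
#' @return An object of class `phantom_params`.
#' @seealso [generate_phantom()]
#' @export
phantom_params <- function(grid_shape = c(64, 64, 64),
                           spacing_mm = c(1, 1, 1),
                           n_lobes = 3,
                           tumor_radius_mm = 10,
                           rim_contrast = 0.8,
                           noise_sd = 6,
                           necrotic_fraction = 0.25,
                           seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 16)) {
    stop("'grid_shape' must be 3 integers, all >= 16")
  }
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop("'spacing_mm' must be 3 positive reals")
  }
  if (n_lobes < 1) stop("'n_lobes' must be >= 1")
  if (tumor_radius_mm <= 0) stop("'tumor_radius_mm' must be positive")
  if (rim_contrast < 0 || rim_contrast > 1) stop("'rim_contrast' must be in [0, 1]")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (necrotic_fraction < 0 || necrotic_fraction >= 1) {
    stop("'necrotic_fraction' must be in [0, 1)")
  }
  structure(list(grid_shape = grid_shape,
                 spacing_mm = as.numeric(spacing_mm),
                 n_lobes = as.integer(n_lobes),
                 tumor_radius_mm = as.numeric(tumor_radius_mm),
                 rim_contrast = as.numeric(rim_contrast),
                 noise_sd = as.numeric(noise_sd),
                 necrotic_fraction = as.numeric(necrotic_fraction),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' Construct a labeled volume
#'
#' Container for one study: a 3D intensity array, the co-registered binary
#' tumor-core mask, voxel spacing, and a grade tag. `roi_offset` and
#' `full_shape` record, for volumes produced by [crop_volume()], where the
#' sub-grid sits inside the original grid so masks can be mapped back.
#'
#' @param intensities 3D array of finite nonnegative intensities.
#' @param gt_mask 3D logical (or 0/1) array of identical shape, nonempty.
#' @param spacing_mm Positive voxel spacing per axis (mm).
#' @param grade `"HGG_like"` or `"LGG_like"`.
#' @param study_id Character study identifier.
#' @param roi_offset Integer voxel offset of this grid inside the full grid
#'   (0 when uncropped).
#' @param full_shape Shape of the full grid this volume belongs to.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(intensities, gt_mask, spacing_mm,
                           grade = c("HGG_like", "LGG_like"),
                           study_id = "study",
                           roi_offset = c(0L, 0L, 0L),
                           full_shape = dim(intensities)) {
  grade <- match.arg(grade)
  if (length(dim(intensities)) != 3) stop("'intensities' must be a 3D array")
  if (!identical(dim(intensities), dim(gt_mask))) {
    stop("'intensities' and 'gt_mask' must have identical shapes")
  }
  if (!all(is.finite(intensities)) || any(intensities < 0)) {
    stop("'intensities' must be finite and nonnegative")
  }
  gt <- gt_mask > 0
  if (!any(gt)) stop("'gt_mask' must contain at least one foreground voxel")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop("'spacing_mm' must be 3 positive reals")
  }
  structure(list(intensities = intensities,
                 gt_mask = gt,
                 spacing_mm = as.numeric(spacing_mm),
                 grade = grade,
                 study_id = as.character(study_id),
                 roi_offset = as.integer(roi_offset),
                 full_shape = as.integer(full_shape)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s [%s] grid %s, spacing %s mm, %d core voxels\n",
              x$study_id, x$grade,
              paste(dim(x$intensities), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              sum(x$gt_mask)))
  invisible(x)
}

# 1-voxel 6-connected erosion of a 3D logical array, iterated `iter` times.
erode3d <- function(mask, iter = 1) {
  m <- mask > 0
  d <- dim(m)
  for (i in seq_len(iter)) {
    out <- m
    shift <- function(ax, by) {
      s <- array(FALSE, d)
      idx_src <- lapply(d, seq_len)
      idx_dst <- idx_src
      n <- d[ax]
      if (by > 0) { idx_dst[[ax]] <- (1 + by):n; idx_src[[ax]] <- 1:(n - by) }
      else        { idx_dst[[ax]] <- 1:(n + by); idx_src[[ax]] <- (1 - by):n }
      s[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      s
    }
    for (ax in 1:3) {
      out <- out & shift(ax, 1) & shift(ax, -1)
    }
    m <- out
  }
  m
}

#' Generate a synthetic labeled tumor volume
#'
#' Builds the ground-truth tumor core as a smooth union of `n_lobes`
#' ellipsoidal lobes: each lobe contributes a radial basis field
#' `exp(-2 * q)` with `q` the squared normalized ellipsoidal distance, and
#' the mask is the superlevel set `sum > exp(-2)`. A single lobe therefore
#' yields exactly the sphere of radius `tumor_radius_mm`; extra lobes (radii
#' 0.3-0.5 of the primary, centers within one radius of the primary center)
#' blend smoothly into an irregular connected core. Intensities are: dark
#' air, a bright brain ellipsoid, a contrast-enhanced rim shell at the mask
#' boundary scaled by `rim_contrast`, a dimmed necrotic interior occupying
#' the deepest `necrotic_fraction` of the core, plus Gaussian noise.
#'
#' @param params A [phantom_params()] object.
#' @param study_id Study identifier stored in the output (does not affect
#'   the generated arrays).
#' @return A [labeled_volume()]; grade is `"HGG_like"` when
#'   `rim_contrast >= 0.5`, `"LGG_like"` otherwise.
#' @export
generate_phantom <- function(params, study_id = sprintf("phantom_%05d", params$seed)) {
  stopifnot(inherits(params, "phantom_params"))
  d <- params$grid_shape
  sp <- params$spacing_mm
  r <- params$tumor_radius_mm

  # maximal reach of any lobe from the primary centre, in mm
  reach_mm <- r * if (params$n_lobes > 1) 1.5 else 1
  margin_vox <- ceiling(reach_mm / sp) + 3
  if (any(2 * margin_vox >= d)) {
    stop("tumor cannot fit inside the grid with the required background margin; ",
         "enlarge 'grid_shape' or shrink 'tumor_radius_mm'")
  }

  with_seed(subseed(params$seed, "phantom"), {
    xs <- (seq_len(d[1]) - 1) * sp[1]
    ys <- (seq_len(d[2]) - 1) * sp[2]
    zs <- (seq_len(d[3]) - 1) * sp[3]

    lo <- (margin_vox - 1) * sp
    hi <- (d - margin_vox) * sp
    centre <- lo + stats::runif(3) * (hi - lo)

    # lobe geometry: primary is a sphere of radius r; extras are smaller
    # anisotropic ellipsoids within one radius of the primary centre
    centres <- matrix(centre, nrow = 1)
    radii <- matrix(r, nrow = 1, ncol = 3)
    if (params$n_lobes > 1) {
      for (j in 2:params$n_lobes) {
        repeat {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3) * r
          break
        }
        centres <- rbind(centres, centre + u)
        radii <- rbind(radii, r * stats::runif(3, 0.3, 0.5))
      }
    }

    field <- array(0, d)
    for (j in seq_len(nrow(centres))) {
      ax <- ((xs - centres[j, 1]) / radii[j, 1])^2
      ay <- ((ys - centres[j, 2]) / radii[j, 2])^2
      az <- ((zs - centres[j, 3]) / radii[j, 3])^2
      q <- array(0, d)
      q <- q + ax                              # recycles along axis 1
      q <- q + rep(ay, each = d[1])            # axis 2
      q <- q + rep(az, each = d[1] * d[2])     # axis 3
      field <- field + exp(-2 * q)
    }
    mask <- field > exp(-2)

    edge <- array(FALSE, d)
    edge[c(1, 2, d[1] - 1, d[1]), , ] <- TRUE
    edge[, c(1, 2, d[2] - 1, d[2]), ] <- TRUE
    edge[, , c(1, 2, d[3] - 1, d[3])] <- TRUE
    if (any(mask & edge)) {
      stop("generated tumor touches the grid boundary margin")
    }

    # brain ellipsoid on dark air
    bc <- (d - 1) * sp / 2
    ba <- pmax((d - 1) * sp * 0.45, reach_mm + 4 * sp) # tumor stays inside
    bx <- ((xs - bc[1]) / ba[1])^2
    by <- ((ys - bc[2]) / ba[2])^2
    bz <- ((zs - bc[3]) / ba[3])^2
    bq <- array(0, d)
    bq <- bq + bx
    bq <- bq + rep(by, each = d[1])
    bq <- bq + rep(bz, each = d[1] * d[2])
    brain <- bq <= 1

    shell <- mask & !erode3d(mask, 2)
    necrotic <- array(FALSE, d)
    if (params$necrotic_fraction > 0) {
      vals <- field[mask]
      thr <- stats::quantile(vals, 1 - params$necrotic_fraction,
                             names = FALSE, type = 7)
      necrotic <- mask & field >= thr & !shell
    }

    img <- array(5, d)
    img[brain] <- 80
    img[mask] <- 95
    img[shell] <- 95 + 120 * params$rim_contrast
    img[necrotic] <- 55
    if (params$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = params$noise_sd)
    }
    img <- pmax(img, 0)

    labeled_volume(array(img, d), mask, sp,
                   grade = if (params$rim_contrast >= 0.5) "HGG_like" else "LGG_like",
                   study_id = study_id)
  })
}

#' Parameters of the mock promptable predictor
#'
#' The mock predictor stands in for a real promptable segmentation model:
#' candidate masks are the slice ground truth degraded by seeded
#' morphological noise whose magnitude shrinks with the number of prompts and
#' with the image's measured tumor-rim contrast.
#'
#' @param corruption_level Base degradation magnitude in pixels (erosion /
#'   dilation radius or translation distance at one prompt and full contrast).
#' @param confidence_calibration In `[0, 1]`: 1 means the reported
#'   confidences rank candidates exactly by true IoU, 0 means they are pure
#'   noise.
#' @param ambiguity_mode `"none"`, or `"whole_object"` to make one candidate
#'   at the single-prompt stage segment the whole bright object (the brain)
#'   instead of the tumor, emulating prompt-ambiguity failures.
#' @param improvement_rate Reduction of the degradation magnitude per
#'   additional prompt.
#' @param seed Integer seed controlling all predictor randomness.
#' @return An object of class `mock_predictor_params`.
#' @export
mock_predictor_params <- function(corruption_level = 3,
                                  confidence_calibration = 1,
                                  ambiguity_mode = c("none", "whole_object"),
                                  improvement_rate = 0.5,
                                  seed = 1) {
  ambiguity_mode <- match.arg(ambiguity_mode)
  stopifnot_scalar(corruption_level, "corruption_level")
  stopifnot_scalar(confidence_calibration, "confidence_calibration")
  stopifnot_scalar(improvement_rate, "improvement_rate")
  if (corruption_level < 0) stop("'corruption_level' must be nonnegative")
  if (confidence_calibration < 0 || confidence_calibration > 1) {
    stop("'confidence_calibration' must be in [0, 1]")
  }
  if (improvement_rate < 0) stop("'improvement_rate' must be nonnegative")
  structure(list(corruption_level = corruption_level,
                 confidence_calibration = confidence_calibration,
                 ambiguity_mode = ambiguity_mode,
                 improvement_rate = improvement_rate,
                 seed = as.integer(seed)),
            class = "mock_predictor_params")
}

#' Ground-truth registry for the mock predictor
#'
#' The promptable-predictor contract is a pure function of (image, prompts),
#' so the mock predictor recovers the ground truth of the slice it is shown
#' through a content-addressed registry: slices are registered by the hash of
#' their pixel data before simulation.
#'
#' @return A list with functions `register(image, gt)` and `lookup(image)`.
#' @export
gt_registry <- function() {
  env <- new.env(parent = emptyenv())
  register <- function(image, gt) {
    key <- as.character(hash_array(if (length(dim(image)) == 3) image[, , 1] else image))
    assign(key, gt > 0, envir = env)
    invisible(key)
  }
  lookup <- function(image) {
    key <- as.character(hash_array(if (length(dim(image)) == 3) image[, , 1] else image))
    if (!exists(key, envir = env, inherits = FALSE)) {
      stop("mock predictor: slice not registered in the ground-truth registry")
    }
    list(gt = get(key, envir = env), key = key)
  }
  list(register = register, lookup = lookup)
}

# contrast estimate from the image itself: mean intensity of the 2-px rim of
# the true mask minus the mean of a background ring just outside it, on the
# 0-255 scale, clipped to [0, 1]
estimate_contrast <- function(img2d, gt) {
  rim <- gt & !morph_disc(gt, 2, "erode")
  ring <- morph_disc(gt, 3, "dilate") & !gt
  if (!any(rim) || !any(ring)) return(0.5)
  min(max((mean(img2d[rim]) - mean(img2d[ring])) / 255, 0), 1)
}

#' Create a mock promptable predictor
#'
#' Returns a predictor satisfying the promptable contract: called with a
#' 3-channel 2D image and an ordered prompt list it yields three candidate
#' binary masks plus three confidence scores. Candidates are the slice ground
#' truth degraded by a per-candidate morphological operation (erode, dilate,
#' or translate, chosen reproducibly per slice) of magnitude
#' `max(0, corruption_level - improvement_rate * (n_prompts - 1))`, scaled up
#' for low-contrast images. Prompts are honored locally: a foreground prompt
#' falling outside a candidate adds the 3-px neighborhood of true tumor
#' around it; a background prompt inside a candidate removes the 3-px
#' neighborhood of non-tumor. Confidences blend the true-IoU rank with
#' uniform noise according to `confidence_calibration`.
#'
#' @param params A [mock_predictor_params()] object.
#' @param gt_lookup Function mapping an image to
#'   `list(gt = <binary matrix>, key = <string>)`; typically the `lookup`
#'   member of a [gt_registry()].
#' @return An object of class `c("mock_predictor", "promptable_predictor")`;
#'   call it via [predict_masks()].
#' @export
make_mock_predictor <- function(params, gt_lookup) {
  stopifnot(inherits(params, "mock_predictor_params"))
  stopifnot(is.function(gt_lookup))
  force(params)
  force(gt_lookup)

  fn <- function(image, prompts) {
    validate_prompts(image, prompts)
    dims <- dim(image)
    img2d <- if (length(dims) == 3) image[, , 1] else image
    info <- gt_lookup(image)
    gt <- info$gt
    if (!identical(dim(gt), dim(img2d))) {
      stop("registered ground truth does not match the image shape")
    }
    n_prompts <- nrow(prompts)
    contrast <- estimate_contrast(img2d, gt)
    base <- max(0, params$corruption_level -
                  params$improvement_rate * (n_prompts - 1))
    # degradation grows convexly as boundary contrast falls: diffuse
    # low-contrast lesions are disproportionally harder to delineate
    magnitude <- base * (1 + 3.5 * (1 - contrast)^2)

    # structural choice per (slice, candidate) is stable across iterations so
    # candidates improve smoothly as prompts accumulate
    ops <- with_seed(subseed(params$seed, info$key, "ops"), {
      list(type = sample(c("erode", "dilate", "shift")),
           angle = stats::runif(3, 0, 2 * pi))
    })
    scale <- c(0.7, 1.0, 1.3)

    masks <- vector("list", 3)
    for (j in 1:3) {
      rj <- round(magnitude * scale[j])
      cand <- with_seed(subseed(params$seed, info$key, j, n_prompts), {
        if (rj <= 0) {
          gt
        } else if (ops$type[j] == "erode") {
          morph_disc(gt, rj, "erode")
        } else if (ops$type[j] == "dilate") {
          morph_disc(gt, rj, "dilate")
        } else {
          shift_mask(gt, round(rj * sin(ops$angle[j])),
                     round(rj * cos(ops$angle[j])))
        }
      })
      if (params$ambiguity_mode == "whole_object" && n_prompts == 1 && j == 3) {
        cand <- img2d > 0.25 * max(img2d)
      }
      # honor prompts locally (influence radius 3 px): a foreground prompt
      # outside the candidate forces its whole neighborhood in, a background
      # prompt inside forces it out -- with the overshoot a real model would
      # show, so few-pixel tumors cannot be repaired exactly
      for (k in seq_len(n_prompts)) {
        r0 <- prompts$row[k]
        c0 <- prompts$col[k]
        if (prompts$label[k] == "foreground" && !cand[r0, c0]) {
          cand <- paint_disc(cand, r0, c0, 3, TRUE)
        } else if (prompts$label[k] == "background" && cand[r0, c0]) {
          cand <- paint_disc(cand, r0, c0, 3, FALSE)
        }
      }
      masks[[j]] <- cand
    }

    ious <- vapply(masks, compute_iou, numeric(1), b = gt)
    noise <- with_seed(subseed(params$seed, info$key, "conf", n_prompts),
                       stats::runif(3))
    conf <- params$confidence_calibration * (rank(ious, ties.method = "average") / 3) +
      (1 - params$confidence_calibration) * noise
    prediction_triple(masks, conf)
  }

  structure(list(fn = fn, params = params, gt_lookup = gt_lookup),
            class = c("mock_predictor", "promptable_predictor"))
}

#' Wrap a plain function as a promptable predictor
#'
#' @param fn Function `(image, prompts) -> prediction_triple`.
#' @return An object of class `promptable_predictor`.
#' @export
as_predictor <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn), class = "promptable_predictor")
}

#' Query a promptable predictor
#'
#' @param predictor A `promptable_predictor` (e.g. from
#'   [make_mock_predictor()] or [as_predictor()]).
#' @param image 2D image replicated to 3 channels (`nrow x ncol x 3` array)
#'   or a plain matrix.
#' @param prompts Data frame with columns `row`, `col`, `label`
#'   (`"foreground"`/`"background"`) and `iteration`; must be nonempty and
#'   inside the image bounds.
#' @return A [prediction_triple()].
#' @export
predict_masks <- function(predictor, image, prompts) {
  stopifnot(inherits(predictor, "promptable_predictor"))
  predictor$fn(image, prompts)
}

#' Register a slice with a predictor that needs ground-truth access
#'
#' Generic hook called by the study driver before simulating a slice; the
#' default is a no-op, the mock predictor registers the slice ground truth in
#' its content-addressed registry.
#'
#' @param predictor A `promptable_predictor`.
#' @param sample A [slice_sample] object.
#' @export
register_sample <- function(predictor, sample) UseMethod("register_sample")

#' @export
register_sample.default <- function(predictor, sample) invisible(NULL)

#' @export
register_sample.mock_predictor <- function(predictor, sample) {
  reg_env <- environment(predictor$gt_lookup)
  if (!is.null(reg_env$register)) {
    reg_env$register(sample$image, sample$gt_mask)
  }
  invisible(NULL)
}

validate_prompts <- function(image, prompts) {
  if (!is.data.frame(prompts) || nrow(prompts) == 0) {
    stop("prompt list must be a nonempty data frame")
  }
  req <- c("row", "col", "label")
  if (!all(req %in% names(prompts))) {
    stop("prompts need columns 'row', 'col', 'label'")
  }
  dims <- dim(image)
  if (any(prompts$row < 1 | prompts$row > dims[1] |
            prompts$col < 1 | prompts$col > dims[2])) {
    stop("prompt outside image bounds")
  }
  if (!all(prompts$label %in% c("foreground", "background"))) {
    stop("prompt labels must be 'foreground' or 'background'")
  }
  invisible(TRUE)
}
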