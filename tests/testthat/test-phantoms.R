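test_that("phantom generation is deterministic and geometrically sound", {
  p <- phantom_params(grid_shape = c(30, 30, 30), n_lobes = 1,
                      tumor_radius_mm = 10, rim_contrast = 1,
                      noise_sd = 0, necrotic_fraction = 0, seed = 11)
  v1 <- generate_phantom(p)
  v2 <- generate_phantom(p)
  expect_identical(v1$intensities, v2$intensities)
  expect_identical(v1$gt_mask, v2$gt_mask)

  # single lobe: one 6-connected component
  px <- which(v1$gt_mask, arr.ind = TRUE)
  g <- igraph::make_empty_graph(nrow(px), directed = FALSE)
  edges <- c()
  for (i in seq_len(nrow(px))) {
    d <- abs(sweep(px, 2, px[i, ]))
    nb <- which(rowSums(d) == 1)
    for (j in nb[nb > i]) edges <- c(edges, i, j)
  }
  g <- igraph::add_edges(g, edges)
  expect_equal(igraph::components(g)$no, 1)

  # voxelized sphere volume close to (4/3) pi r^3
  expect_lt(abs(sum(v1$gt_mask) - 4 / 3 * pi * 10^3), 0.15 * 4 / 3 * pi * 10^3)

  expect_true(all(is.finite(v1$intensities)) && all(v1$intensities >= 0))
})

test_that("impossible phantom geometries are rejected", {
  expect_error(phantom_params(tumor_radius_mm = 0), "positive")
  expect_error(phantom_params(grid_shape = c(12, 32, 32)), ">= 16")
  p <- phantom_params(grid_shape = c(16, 16, 16), tumor_radius_mm = 12,
                      n_lobes = 1, seed = 1)
  expect_error(generate_phantom(p), "cannot fit")
})

test_that("necrosis dims the interior without leaving the core mask", {
  p <- phantom_params(grid_shape = c(32, 32, 32), n_lobes = 1,
                      tumor_radius_mm = 8, rim_contrast = 0.9,
                      noise_sd = 0, necrotic_fraction = 0.3, seed = 4)
  v <- generate_phantom(p)
  nec <- v$intensities == 55
  expect_gt(sum(nec), 0)
  expect_true(all(v$gt_mask[nec]))       # necrosis is part of the core
  expect_equal(v$grade, "HGG_like")
  expect_equal(generate_phantom(phantom_params(grid_shape = c(32, 32, 32),
                                               tumor_radius_mm = 8,
                                               rim_contrast = 0.3,
                                               seed = 4))$grade, "LGG_like")
})

test_that("mock predictor honors its corruption and calibration contracts", {
  vols <- gen_phantoms(1, 0.9, 100)
  sl <- extract_slices(normalize_volume(vols[[1]]))
  s <- sl[[ceiling(length(sl) / 2)]]

  # no corruption: every candidate equals the ground truth
  mk <- mock_with_registry(corruption_level = 0, seed = 1)
  register_sample(mk$pred, s)
  tr <- predict_masks(mk$pred, s$image, place_initial_point(s$gt_mask))
  for (j in 1:3) expect_equal(compute_iou(tr$masks[[j]], s$gt_mask), 1)

  # calibrated confidences rank by true IoU in every call
  for (sd in 1:20) {
    mk <- mock_with_registry(corruption_level = 3,
                             confidence_calibration = 1, seed = sd)
    register_sample(mk$pred, s)
    tr <- predict_masks(mk$pred, s$image, place_initial_point(s$gt_mask))
    ious <- vapply(tr$masks, compute_iou, numeric(1), b = s$gt_mask)
    expect_equal(which.max(tr$confidences), which.max(ious))
  }

  # prompts outside bounds / empty prompt list are rejected
  expect_error(predict_masks(mk$pred, s$image,
                             data.frame(row = 0, col = 1,
                                        label = "foreground", iteration = 1)),
               "bounds")
  expect_error(predict_masks(mk$pred, s$image,
                             data.frame(row = integer(), col = integer(),
                                        label = character(),
                                        iteration = integer())),
               "nonempty")
})

test_that("uncalibrated confidences pick the oracle candidate a third of the time", {
  vols <- gen_phantoms(1, 0.9, 200)
  sl <- extract_slices(normalize_volume(vols[[1]]))
  s <- sl[[ceiling(length(sl) / 2)]]
  p0 <- place_initial_point(s$gt_mask)
  hits <- 0
  used <- 0
  for (sd in 1:500) {
    mk <- mock_with_registry(corruption_level = 3,
                             confidence_calibration = 0, seed = 1000 + sd)
    register_sample(mk$pred, s)
    tr <- predict_masks(mk$pred, s$image, p0)
    ious <- vapply(tr$masks, compute_iou, numeric(1), b = s$gt_mask)
    if (length(unique(ious)) < 3) next
    used <- used + 1
    if (which.max(tr$confidences) == which.max(ious)) hits <- hits + 1
  }
  expect_gt(used, 400)
  # binomial 95% band around 1/3
  band <- 1 / 3 + c(-1, 1) * 1.96 * sqrt(1 / 3 * 2 / 3 / used)
  expect_gt(hits / used, band[1])
  expect_lt(hits / used, band[2])
})

test_that("difficulty responds monotonically to corruption and contrast", {
  n_slices_per_level <- function(vols, corruption) {
    mk <- mock_with_registry(corruption_level = corruption,
                             improvement_rate = 0, seed = 42)
    ious <- c()
    for (v in vols) {
      for (s in extract_slices(normalize_volume(v))) {
        register_sample(mk$pred, s)
        tr <- predict_masks(mk$pred, s$image, place_initial_point(s$gt_mask))
        ious <- c(ious, max(vapply(tr$masks, compute_iou, numeric(1),
                                   b = s$gt_mask)))
      }
    }
    ious
  }
  vols <- gen_phantoms(4, 0.9, 300)
  m <- sapply(c(0, 1, 2, 4), function(cl) mean(n_slices_per_level(vols, cl)))
  expect_gte(length(n_slices_per_level(vols, 0)), 50)
  expect_true(all(diff(m) <= 1e-9))   # non-increasing in corruption

  by_rim <- sapply(c(0.2, 0.5, 0.9), function(rc) {
    mean(n_slices_per_level(gen_phantoms(4, rc, 300), 3))
  })
  expect_true(all(diff(by_rim) >= -1e-9))  # non-decreasing in contrast
})
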