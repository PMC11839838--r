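test_that("IoU follows the pixel-counting definition", {
  a <- matrix(FALSE, 4, 4); a[2:3, 1:2] <- TRUE
  expect_equal(compute_iou(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[2:3, 3:4] <- TRUE
  expect_equal(compute_iou(a, b), 0)
  shifted <- matrix(FALSE, 4, 4); shifted[2:3, 2:3] <- TRUE
  expect_equal(compute_iou(a, shifted), 2 / 6)
  expect_error(compute_iou(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("initial prompt lands on the distance-transform center", {
  sq <- matrix(FALSE, 11, 11); sq[4:8, 4:8] <- TRUE
  p <- place_initial_point(sq)
  expect_equal(c(p$row, p$col), c(6, 6))

  one <- matrix(FALSE, 7, 7); one[3, 5] <- TRUE
  p1 <- place_initial_point(one)
  expect_equal(c(p1$row, p1$col), c(3, 5))
  expect_equal(p1$label, "foreground")

  # concave masks against the all-pairs brute-force oracle
  for (sd in 1:15) {
    m <- random_concave_mask(sd)
    got <- place_initial_point(m)
    want <- bf_argmax(bf_dist_map(m), m)
    expect_equal(c(got$row, got$col), unname(want))
  }
  expect_error(place_initial_point(matrix(FALSE, 5, 5)), "empty")
})

test_that("corrective prompts follow the area rule and the set difference", {
  gt <- matrix(FALSE, 12, 12); gt[3:8, 3:8] <- TRUE       # 36 px
  pred <- matrix(FALSE, 12, 12); pred[5:6, 5:6] <- TRUE   # 4 px
  p <- next_prompt(gt, pred, 2)
  expect_equal(p$label, "foreground")
  expect_true(gt[p$row, p$col] && !pred[p$row, p$col])

  over <- matrix(FALSE, 12, 12); over[2:10, 2:10] <- TRUE # pred superset
  p2 <- next_prompt(gt, over, 2)
  expect_equal(p2$label, "background")
  expect_true(over[p2$row, p2$col] && !gt[p2$row, p2$col])

  # two components: the larger one is selected, at its brute-force center
  gt3 <- matrix(FALSE, 14, 14)
  gt3[2:5, 2:4] <- TRUE               # 12 px component
  gt3[10:12, 11] <- TRUE              # 3 px component
  pred3 <- matrix(FALSE, 14, 14)
  p3 <- next_prompt(gt3, pred3, 2)
  want <- bf_corrective(gt3, pred3)
  expect_equal(list(p3$row, p3$col, p3$label),
               list(want$row, want$col, want$label))
  expect_true(p3$row <= 5)            # inside the 12-px component

  expect_error(next_prompt(gt, gt, 2), "equals")
})

test_that("mask selection strategies follow their argmax definitions", {
  base <- matrix(FALSE, 8, 8)
  gt <- base; gt[3:6, 3:6] <- TRUE
  m_bad <- base; m_bad[1:2, 1:2] <- TRUE
  m_good <- gt
  m_mid <- base; m_mid[3:6, 3:4] <- TRUE
  triple <- prediction_triple(list(m_bad, m_good, m_mid), c(0.9, 0.1, 0.5))

  expect_equal(select_mask(triple, gt, "oracle")$index, 2)
  expect_equal(select_mask(triple, gt, "suggested")$index, 1)
  expect_equal(select_mask(triple, gt, "prev_slice", prev_mask = m_mid)$index, 3)
  expect_error(select_mask(triple, gt, "prev_slice"), "previous")

  same <- prediction_triple(list(gt, gt, gt), c(0.5, 0.5, 0.5))
  for (st in c("oracle", "suggested")) {
    expect_equal(select_mask(same, gt, st)$index, 1)
  }
  expect_equal(select_mask(same, gt, "prev_slice", prev_mask = gt)$index, 1)
})

test_that("a perfect predictor terminates at iteration one with IoU 1", {
  vols <- gen_phantoms(1, 0.9, 400)
  mk <- mock_with_registry(corruption_level = 0, seed = 1)
  for (s in extract_slices(normalize_volume(vols[[1]]))) {
    register_sample(mk$pred, s)
    tr <- simulate_slice(s, mk$pred, "oracle")
    expect_equal(tr$best_iou, 1)
    expect_equal(tr$best_iteration, 1)
    expect_true(tr$terminated_early)
    expect_equal(nrow(tr$prompts), 1)
  }
})

test_that("simulation traces are deterministic and internally consistent", {
  vols <- gen_phantoms(1, 0.8, 401)
  sl <- extract_slices(normalize_volume(vols[[1]]))
  s <- sl[[2]]
  mk <- mock_with_registry(corruption_level = 3, improvement_rate = 0.4,
                           confidence_calibration = 0.5, seed = 77)
  register_sample(mk$pred, s)
  t1 <- simulate_slice(s, mk$pred, "oracle")
  t2 <- simulate_slice(s, mk$pred, "oracle")
  expect_identical(t1$iou, t2$iou)
  expect_identical(t1$prompts, t2$prompts)
  expect_identical(t1$best_mask, t2$best_mask)

  expect_equal(t1$best_iou, max(t1$iou))
  expect_equal(t1$best_iteration, which.max(t1$iou))
  expect_lte(nrow(t1$prompts), 9)
  expect_equal(t1$prompts$iteration, seq_len(nrow(t1$prompts)))
})

test_that("every corrective prompt lies inside its generating set difference", {
  vols <- gen_phantoms(2, 0.7, 402)
  mk <- mock_with_registry(corruption_level = 3, improvement_rate = 0.3,
                           seed = 13)
  n_checked <- 0
  for (v in vols) {
    for (s in extract_slices(normalize_volume(v))) {
      register_sample(mk$pred, s)
      tr <- simulate_slice(s, mk$pred, "oracle")
      # replay: the prompt at iteration k+1 was generated against the mask
      # selected at iteration k
      for (k in seq_len(nrow(tr$prompts) - 1)) {
        triple <- predict_masks(mk$pred, s$image, tr$prompts[1:k, ])
        selected <- select_mask(triple, s$gt_mask, "oracle")$mask
        p <- tr$prompts[k + 1, ]
        if (p$label == "foreground") {
          expect_true(s$gt_mask[p$row, p$col] && !selected[p$row, p$col])
        } else {
          expect_true(selected[p$row, p$col] && !s$gt_mask[p$row, p$col])
        }
        n_checked <- n_checked + 1
      }
      # running best is non-decreasing
      expect_true(all(diff(cummax(tr$iou)) >= 0))
    }
  }
  expect_gt(n_checked, 30)
})

test_that("predictors returning wrong shapes are reported with the candidate", {
  bad <- as_predictor(function(image, prompts) {
    prediction_triple(list(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2),
                           matrix(FALSE, 2, 2)), c(1, 1, 1))
  })
  v <- normalize_volume(tiny_volume())
  s <- extract_slices(v)[[1]]
  expect_error(simulate_slice(s, bad, "oracle"), "candidate 1")
})

test_that("the study driver enumerates arms and aggregates faithfully", {
  vols <- gen_phantoms(2, 0.9, 403)
  mk <- mock_with_registry(corruption_level = 2, improvement_rate = 0.5,
                           confidence_calibration = 1, seed = 3)
  res <- run_study(vols, mk$pred, strategies = c("oracle", "suggested"),
                   orientations = "transverse")
  n_slices <- sum(vapply(vols, function(v)
    sum(apply(v$gt_mask, 3, any)), numeric(1)))
  expect_equal(sum(res$slices$strategy == "oracle"), n_slices)
  expect_equal(sum(res$slices$strategy == "suggested"), n_slices)

  # perfectly calibrated confidences make the two strategies coincide
  o <- res$slices[res$slices$strategy == "oracle", ]
  s <- res$slices[res$slices$strategy == "suggested", ]
  expect_equal(o$best_iou, s$best_iou)

  agg <- res$aggregates
  row <- agg[agg$strategy == "oracle" & agg$grade == "all", ]
  expect_equal(row$mean_best_iou, mean(o$best_iou))
  expect_equal(row$n, n_slices)
})

test_that("previous-slice selection approaches oracle accuracy on phantoms", {
  vols <- gen_phantoms(2, 0.9, 404)
  mk <- mock_with_registry(corruption_level = 2.5, improvement_rate = 0.4,
                           confidence_calibration = 0, seed = 21)
  res <- run_study(vols, mk$pred, strategies = c("oracle", "prev_slice"))
  agg <- res$aggregates[res$aggregates$grade == "all", ]
  m_or <- agg$mean_best_iou[agg$strategy == "oracle"]
  m_pv <- agg$mean_best_iou[agg$strategy == "prev_slice"]
  expect_gt(m_pv, 0.7 * m_or)       # prev-slice stays close to oracle
})
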