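# shared scratch space for results reused across acceptance blocks
.acceptance_cache <- new.env(parent = emptyenv())

# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own primitives (EBImage distance maps,
# the BFS labeller) so they can serve as cross-checks.

# all-pairs Euclidean distance of each foreground pixel to the nearest
# background pixel inside the image (Inf when there is no background)
bf_dist_map <- function(mask) {
  mask <- mask > 0
  out <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    out[fg[k, 1], fg[k, 2]] <- if (nrow(bg) == 0) Inf else
      sqrt(min((bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2))
  }
  out
}

# argmax of a distance map over `within`, ties (within 1e-7) to the
# lexicographically smallest (row, col)
bf_argmax <- function(dm, within) {
  cand <- which(within > 0, arr.ind = TRUE)
  vals <- dm[cand]
  cand <- cand[vals >= max(vals) - 1e-7, , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  c(row = unname(cand[1, 1]), col = unname(cand[1, 2]))
}

# 8-connected components via igraph (independent of the package's BFS)
bf_components8 <- function(mask) {
  mask <- mask > 0
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0) return(lab)
  edges <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (max(abs(px[i, ] - px[j, ])) <= 1) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  lab[px] <- memb
  lab
}

# full brute-force replication of the corrective-prompt contract
bf_corrective <- function(gt, pred) {
  gt <- gt > 0
  pred <- pred > 0
  fg_label <- sum(gt) >= sum(pred)
  diffmask <- if (fg_label) gt & !pred else pred & !gt
  lab <- bf_components8(diffmask)
  sizes <- table(lab[lab > 0])
  biggest <- names(sizes)[sizes == max(sizes)]
  if (length(biggest) > 1) {
    firsts <- t(sapply(biggest, function(b) {
      px <- which(lab == as.integer(b), arr.ind = TRUE)
      px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
      px[1, ]
    }))
    biggest <- biggest[order(firsts[, 1], firsts[, 2])]
  }
  comp <- lab == as.integer(biggest[1])
  p <- bf_argmax(bf_dist_map(comp), comp)
  list(row = unname(p["row"]), col = unname(p["col"]),
       label = if (fg_label) "foreground" else "background")
}

# seeded concave 2D masks (rectangles plus a disc, minus a bite)
random_concave_mask <- function(seed, n = 20) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  for (rep in 1:2) {
    r0 <- sample(2:(n - 6), 1); c0 <- sample(2:(n - 6), 1)
    m[r0:(r0 + sample(3:5, 1)), c0:(c0 + sample(3:5, 1))] <- TRUE
  }
  cc <- c(sample(5:(n - 4), 1), sample(5:(n - 4), 1))
  for (i in 1:n) for (j in 1:n) {
    if ((i - cc[1])^2 + (j - cc[2])^2 <= 9) m[i, j] <- TRUE
  }
  bite <- c(sample(3:(n - 2), 1), sample(3:(n - 2), 1))
  for (i in 1:n) for (j in 1:n) {
    if ((i - bite[1])^2 + (j - bite[2])^2 <= 4) m[i, j] <- FALSE
  }
  if (!any(m) || all(m)) m[2:4, 2:4] <- TRUE
  m
}

# standardized two-sample Wilcoxon rank-sum statistic at cutpoint mu,
# written from the textbook formula (tie-corrected variance via tie counts)
bf_rank_sum_z <- function(x, y, mu) {
  grp1 <- x <= mu
  n1 <- sum(grp1)
  n2 <- sum(!grp1)
  n <- n1 + n2
  r <- rank(y)
  w <- sum(r[grp1])
  e <- n1 * (n + 1) / 2
  ties <- table(y)
  v <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  (w - e) / sqrt(v)
}

# small labeled volume with a hand-placed cuboid tumor
tiny_volume <- function(dim3 = c(24, 24, 24), lo = c(9, 10, 11), hi = c(14, 16, 15)) {
  gt <- array(FALSE, dim3)
  gt[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  img <- array(40, dim3)
  img[gt] <- 200
  labeled_volume(img, gt, c(1, 1, 1), grade = "HGG_like", study_id = "tiny")
}

# generate n phantoms with shared geometry, varying seeds
gen_phantoms <- function(n, rim_contrast, seed_base, grid = 32,
                         radius = 6.5, lobes = 2, noise_sd = 5,
                         prefix = "ph") {
  lapply(seq_len(n), function(i) {
    generate_phantom(
      phantom_params(grid_shape = rep(grid, 3), n_lobes = lobes,
                     tumor_radius_mm = radius, rim_contrast = rim_contrast,
                     noise_sd = noise_sd, necrotic_fraction = 0.2,
                     seed = seed_base + i),
      study_id = sprintf("%s_%03d", prefix, i))
  })
}

# predictor + registry in one step for test convenience
mock_with_registry <- function(...) {
  reg <- gt_registry()
  pred <- make_mock_predictor(mock_predictor_params(...), reg$lookup)
  list(pred = pred, reg = reg)
}

# per-iteration IoU curve padded to k prompts by carrying the last value
# forward (traces that hit the ground truth terminate early)
iou_curve <- function(trace, k = 9) {
  v <- trace$iou
  c(v, rep(v[length(v)], k - length(v)))[1:k]
}
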