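#' Mean and interquartile range of a sample
#'
#' @param values Nonempty numeric vector.
#' @return List with `mean`, `iqr` (25th and 75th percentiles, linear
#'   interpolation between order statistics, i.e. quantile type 7) and `n`.
#' @export
summarize_values <- function(values) {
  if (length(values) == 0) stop("cannot summarize an empty sample")
  list(mean = mean(values),
       iqr = stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7),
       n = length(values))
}

# Standardized two-sample Wilcoxon rank-sum statistics for every candidate
# cut position, vectorised. `r` are the (mid)ranks of y in the order of
# increasing x; position i cuts between x_(i) and x_(i+1).
standardized_cut_stats <- function(r, positions) {
  n <- length(r)
  cs <- cumsum(r)
  n1 <- positions
  n2 <- n - n1
  e <- n1 * (n + 1) / 2
  v <- n1 * n2 / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
  (cs[positions] - e) / sqrt(v)
}

#' Optimal covariate cutpoint by maximally selected rank statistics
#'
#' Scans candidate cutpoints of `x` (distinct values restricted to an inner
#' quantile band), computes at each the standardized two-sample Wilcoxon
#' rank-sum statistic comparing `y` below vs. above the cutpoint, and
#' returns the cutpoint maximizing the absolute standardized statistic. The
#' selection-adjusted p-value is obtained by permutation: the x-y pairing is
#' permuted `n_perm` times and the maximal absolute statistic recomputed,
#' which bounds the family-wise error over all candidate cutpoints.
#'
#' @param x Covariate values (e.g. tumor area in mm^2).
#' @param y Responses (e.g. best IoU per slice), same length, `n >= 10`.
#' @param band Inner quantile band of `x` eligible as cutpoints
#'   (default 10%-90%).
#' @param n_perm Number of permutations for the adjusted p-value.
#' @param seed Integer seed for the permutations.
#' @return An object of class `threshold_result`: `best_cutpoint`,
#'   `max_standardized_statistic` (signed statistic at the best cutpoint),
#'   `adjusted_p`, `candidate_cutpoints`, and `group_means`
#'   (mean of `y` at or below / above the cutpoint).
#' @export
maxstat_threshold <- function(x, y, band = c(0.1, 0.9),
                              n_perm = 1000, seed = 1) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  n <- length(x)
  if (n < 10) stop("need at least 10 observations")
  if (all(y == y[1])) {
    stop("response is constant; no cutpoint statistic is defined")
  }
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  qb <- stats::quantile(x, band, names = FALSE, type = 7)
  # candidate cut positions: last index of each distinct x value that lies in
  # the band and leaves at least 2 observations on each side
  last_of_value <- which(diff(xs) > 0)
  positions <- last_of_value[xs[last_of_value] >= qb[1] &
                               xs[last_of_value] <= qb[2] &
                               last_of_value >= 2 &
                               last_of_value <= n - 2]
  if (length(positions) == 0) {
    stop("no candidate cutpoint leaves at least 2 observations on each side")
  }
  candidates <- xs[positions]

  r <- rank(ys)
  z <- standardized_cut_stats(r, positions)
  best <- which.max(abs(z))
  obs_max <- max(abs(z))

  perm_max <- with_seed(subseed(seed, "maxstat"), {
    vapply(seq_len(n_perm), function(b) {
      max(abs(standardized_cut_stats(sample(r), positions)))
    }, numeric(1))
  })
  adj_p <- (1 + sum(perm_max >= obs_max - 1e-12)) / (n_perm + 1)

  cut <- candidates[best]
  structure(list(best_cutpoint = cut,
                 max_standardized_statistic = z[best],
                 adjusted_p = adj_p,
                 candidate_cutpoints = candidates,
                 group_means = c(below = mean(y[x <= cut]),
                                 above = mean(y[x > cut])),
                 n = n, n_perm = n_perm),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(paste0("<threshold_result> best cutpoint %.6g ",
                     "(|z| = %.3f, adjusted p = %.4g, %d candidates)\n"),
              x$best_cutpoint, abs(x$max_standardized_statistic),
              x$adjusted_p, length(x$candidate_cutpoints)))
  cat(sprintf("  mean response below/above: %.4f / %.4f\n",
              x$group_means["below"], x$group_means["above"]))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank-based correlation with midranks for ties and a two-sided p-value
#' (asymptotic t approximation).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, neither constant.
#' @return List with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("correlation undefined for constant input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Wilcoxon comparison of two experiment arms
#'
#' Paired arms use the Wilcoxon signed-rank test on nonzero differences;
#' unpaired arms the Wilcoxon rank-sum test. Two-sided p-values use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric samples (equal lengths when `paired`).
#' @param paired Logical.
#' @return List with `statistic` and `p`.
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal lengths")
    if (all(a == b)) stop("all paired differences are zero")
    if (sum(a != b) < 5) stop("need at least 5 nonzero paired differences")
  } else if (min(length(a), length(b)) < 5) {
    stop("need at least 5 observations per group")
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
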