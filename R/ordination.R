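#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = 1 - 2 \sum_i \min(x_i, y_i) / \sum_i (x_i + y_i)}, computed
#' between all sample pairs of a relative-abundance matrix.
#'
#' @param x a `community_matrix` (or any non-negative sample x taxon matrix).
#' @return a `dist` object with entries in [0, 1].
#' @export
bray_curtis <- function(x) {
  d <- vegan::vegdist(unclass(x), method = "bray")
  attr(d, "ages") <- attr(x, "ages")
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (via `vegan::metaMDS`/`monoMDS`) with multiple random
#' restarts under a fixed seed. The first axis (NMDS1) is the community state
#' variable used downstream; because NMDS axes have arbitrary sign, NMDS1 is
#' flipped, when ages are available, so its Pearson correlation with sample
#' age is non-negative.
#'
#' @param d a `dist` of dissimilarities (e.g. from [bray_curtis()]).
#' @param k embedding dimension (default 2).
#' @param restarts random restarts (default 20); the best solution is kept.
#' @param seed integer RNG seed; identical seed and input give identical
#'   coordinates.
#' @param ages optional ages for axis orientation; defaults to the `"ages"`
#'   attribute of `d` if present.
#' @return list of class `nmds_state`: `points` (n x k, columns NMDS1..),
#'   `stress`, `converged`, `k`, `seed`.
#' @export
nmds_state <- function(d, k = 2, restarts = 20, seed = 1L, ages = NULL) {
  n <- attr(d, "Size")
  if (n < k + 2) stop_("need at least k + 2 samples")
  ages <- ages %||% attr(d, "ages")
  fit <- with_seed_(seed, vegan::metaMDS(d, k = k, try = restarts, trymax = restarts,
                                         autotransform = FALSE, wascores = FALSE,
                                         trace = 0))
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  if (!is.null(ages) && stats::sd(pts[, 1]) > 0 &&
      stats::cor(pts[, 1], ages) < 0)
    pts[, 1] <- -pts[, 1]
  structure(list(points = pts, stress = fit$stress,
                 converged = isTRUE(fit$converged) || (is.numeric(fit$converged) && fit$converged > 0),
                 k = k, seed = as.integer(seed)),
            class = "nmds_state")
}

#' @export
print.nmds_state <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f, %s\n", x$k, x$stress,
              if (x$converged) "converged" else "no convergent solution (best effort)"))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based two-group (or multi-group) test on a dissimilarity matrix:
#' R = (mean between-group rank - mean within-group rank) / (M/4) with
#' M = n(n-1)/2. R = 1 indicates complete separation, 0 no separation. The
#' permutation p-value uses the (b + 1)/(m + 1) estimator, so the smallest
#' attainable p at 999 permutations is 0.001.
#'
#' @param d a `dist`.
#' @param labels group label per sample; each group needs >= 2 members.
#' @param n_perm number of label permutations (default 999); 0 returns the
#'   statistic alone with `p = NA`.
#' @param seed RNG seed for the permutations.
#' @return list with `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(d, labels, n_perm = 999, seed = 1L) {
  labels <- factor(labels)
  if (any(table(labels) < 2)) stop_("every group needs at least 2 samples")
  if (n_perm == 0)
    return(list(R = anosim_statistic(d, labels), p = NA_real_, n_perm = 0))
  fit <- with_seed_(seed, vegan::anosim(d, labels, permutations = n_perm))
  list(R = unname(fit$statistic), p = unname(fit$signif), n_perm = n_perm)
}

# The bare ANOSIM statistic without permutations (used for null-mean studies).
anosim_statistic <- function(d, labels) {
  labels <- factor(labels)
  n <- attr(d, "Size")
  rd <- rank(as.vector(d))
  within <- as.vector(stats::as.dist(outer(labels, labels, "=="))) > 0
  (mean(rd[!within]) - mean(rd[within])) / (n * (n - 1) / 4)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Pseudo-F from the partition of summed squared dissimilarities between and
#' within groups (`vegan::adonis2`), with a permutation p-value as in
#' [anosim_test()].
#'
#' @inheritParams anosim_test
#' @return list with `F`, `R2`, `p`, `n_perm`.
#' @export
permanova_test <- function(d, labels, n_perm = 999, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2 || any(table(labels) < 2))
    stop_("need >= 2 groups with >= 2 samples each")
  df <- data.frame(grp = labels)
  fit <- with_seed_(seed, vegan::adonis2(d ~ grp, data = df, permutations = n_perm))
  list(F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1], n_perm = n_perm)
}

#' Stratigraphically constrained zonation (CONISS-style)
#'
#' Agglomerative clustering in which only stratigraphically adjacent clusters
#' may merge, choosing at each step the merge with the smallest increase in
#' within-cluster dispersion. Dispersion of a cluster is computed from the
#' squared dissimilarities, \eqn{\sum_{i<j \in C} d_{ij}^2 / |C|}, which for
#' Euclidean distances reduces to the classical incremental sum of squares.
#' The two-state cut is computed exactly, by minimizing total dispersion over
#' all n - 1 contiguous splits.
#'
#' @param d a `dist` over samples in stratigraphic order.
#' @return list of class `zonation`: `merge` (hclust-style merge matrix over
#'   adjacent clusters), `height` (cumulative dispersion at each merge),
#'   `states` (two-state labels, 1 then 2), `boundary` (last sample index of
#'   state 1), `n`.
#' @export
constrained_zonation <- function(d) {
  n <- attr(d, "Size")
  if (n < 4) stop_("need at least 4 samples for zonation")
  dm2 <- as.matrix(d)^2
  # cluster dispersion of the contiguous block i..j
  disp <- function(i, j) {
    if (j <= i) return(0)
    sum(dm2[i:j, i:j]) / (2 * (j - i + 1))
  }
  # exact two-state cut
  costs <- vapply(seq_len(n - 1), function(b) disp(1, b) + disp(b + 1, n), 0)
  boundary <- which.min(costs)
  states <- rep(c(1L, 2L), c(boundary, n - boundary))
  # constrained agglomeration for the merge tree
  blocks <- data.frame(start = seq_len(n), end = seq_len(n), id = -seq_len(n))
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  total <- 0
  for (step in seq_len(n - 1)) {
    inc <- vapply(seq_len(nrow(blocks) - 1), function(i) {
      disp(blocks$start[i], blocks$end[i + 1]) -
        disp(blocks$start[i], blocks$end[i]) -
        disp(blocks$start[i + 1], blocks$end[i + 1])
    }, 0)
    i <- which.min(inc)
    merge[step, ] <- c(blocks$id[i], blocks$id[i + 1])
    total <- total + inc[i]
    height[step] <- total
    blocks$end[i] <- blocks$end[i + 1]
    blocks$id[i] <- step
    blocks <- blocks[-(i + 1), , drop = FALSE]
  }
  structure(list(merge = merge, height = height, states = states,
                 boundary = boundary, n = n),
            class = "zonation")
}

#' @export
print.zonation <- function(x, ...) {
  cat(sprintf("constrained zonation of %d samples: two-state cut after sample %d (%d | %d)\n",
              x$n, x$boundary, x$boundary, x$n - x$boundary))
  invisible(x)
}

#' Cut a constrained zonation tree into k contiguous zones
#'
#' @param z a `zonation` from [constrained_zonation()].
#' @param k number of zones.
#' @return integer zone label per sample, numbered in stratigraphic order;
#'   every zone is a contiguous interval by construction of the tree.
#' @export
cut_zonation <- function(z, k) {
  if (k < 1 || k > z$n) stop_("k out of range")
  h <- structure(list(merge = z$merge, height = cummax(z$height),
                      order = seq_len(z$n),
                      labels = as.character(seq_len(z$n))),
                 class = "hclust")
  lab <- stats::cutree(h, k = k)
  as.integer(factor(lab, levels = unique(lab)))
}

#' Gaussian kernel-density bimodality of a state series
#'
#' Gaussian KDE on a 512-point grid spanning the data range plus three
#' bandwidths on each side (Silverman's rule by default), with modes counted
#' as strict local maxima of the gridded density. Used to test whether the
#' community state axis (NMDS1) is bimodal, the signature of bistability.
#'
#' @param values numeric vector (>= 3 values).
#' @param bandwidth `"silverman"` or a positive number.
#' @return list with `x`, `density`, `bw`, `n_modes`, `modes` (x-locations)
#'   and `degenerate` (TRUE when the input has zero variance).
#' @export
kde_bimodality <- function(values, bandwidth = "silverman") {
  values <- as.numeric(values)
  if (length(values) < 3) stop_("need at least 3 values")
  if (stats::sd(values) == 0) {
    return(list(x = rep(values[1], 512), density = rep(NA_real_, 512),
                bw = NA_real_, n_modes = 1L, modes = values[1],
                degenerate = TRUE))
  }
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(values) else as.numeric(bandwidth)
  den <- stats::density(values, bw = bw, n = 512, cut = 3)
  y <- den$y
  is_mode <- which(y[2:511] > y[1:510] & y[2:511] > y[3:512]) + 1L
  list(x = den$x, density = y, bw = bw, n_modes = length(is_mode),
       modes = den$x[is_mode], degenerate = FALSE)
}
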