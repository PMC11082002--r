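test_that("Bray-Curtis matches the direct formula", {
  cm <- community_matrix(rbind(c(1, 0), c(0.5, 0.5), c(1, 0), c(0, 1)),
                         ages = 1:4)
  rownames(cm) <- paste0("s", 1:4); colnames(cm) <- c("a", "b")
  d <- as.matrix(bray_curtis(cm))
  expect_equal(d[1, 3], 0)            # identical rows
  expect_equal(d[1, 4], 1)            # disjoint support
  expect_equal(d[1, 2], 0.5)          # 1 - 2*min sums / total
  # random compositions against the formula written out
  withr::with_seed(2, {
    x <- matrix(rgamma(5 * 4, 1), 5); x <- x / rowSums(x)
    rownames(x) <- paste0("r", 1:5); colnames(x) <- paste0("t", 1:4)
    d2 <- as.matrix(bray_curtis(community_matrix(x, ages = 1:5)))
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(d2[i, j],
                   1 - 2 * sum(pmin(x[i, ], x[j, ])) / sum(x[i, ] + x[j, ]),
                   tolerance = 1e-12)
    }
  })
})

test_that("NMDS embeds exact configurations, is deterministic, and is oriented", {
  withr::with_seed(8, {
    pts <- matrix(rnorm(20), 10, 2)
  })
  d <- stats::dist(pts)
  attr(d, "Size") <- 10L
  nm <- suppressWarnings(nmds_state(d, k = 2, restarts = 10, seed = 5))
  expect_lt(nm$stress, 0.01)                       # embeddable exactly
  expect_true(all(abs(colMeans(nm$points)) < 1e-9))  # centered
  nm2 <- suppressWarnings(nmds_state(d, k = 2, restarts = 10, seed = 5))
  expect_identical(nm$points, nm2$points)          # determinism
  # 4 points on a line, k = 1: rank order of the coordinate is preserved
  line <- matrix(c(0, 1, 3, 7), dimnames = list(paste0("s", 1:4), NULL))
  dl <- stats::dist(line)
  nl <- suppressWarnings(nmds_state(dl, k = 1, restarts = 10, seed = 2, ages = 1:4))
  expect_equal(order(nl$points[, 1]), 1:4)
  # orientation: NMDS1 correlates non-negatively with age when ages given
  sc <- transition_scenario(seed = 9)
  db <- bray_curtis(select_modeled_taxa(to_relative(sc$table)))
  nb <- suppressWarnings(nmds_state(db, seed = 3))
  expect_gte(stats::cor(nb$points[, 1], sample_ages(sc$table)), 0)
})

test_that("ANOSIM attains its bounds and the permutation p floor", {
  x <- two_cluster_matrix()
  d <- stats::dist(x)
  g <- rep(c("a", "b"), each = 5)
  res <- anosim_test(d, g, n_perm = 999, seed = 1)
  expect_equal(res$R, 1)                  # complete separation
  expect_equal(res$R, anosim_R_oracle(d, g))
  # p floor (0+1)/(999+1): needs groups large enough that no permutation
  # reproduces the separating partition by chance
  x2 <- two_cluster_matrix(n_per = 10)
  res2 <- anosim_test(stats::dist(x2), rep(c("a", "b"), each = 10),
                      n_perm = 999, seed = 1)
  expect_equal(res2$p, 0.001)
  # mean R over random labelings of an unstructured cloud is ~0
  withr::with_seed(21, {
    cloud <- matrix(rnorm(40), 20, 2)
    dc <- stats::dist(cloud)
    Rs <- replicate(400, {
      lab <- sample(rep(1:2, each = 10))
      anosim_R_oracle(dc, lab)
    })
  })
  expect_lt(abs(mean(Rs)), 0.02)
  expect_true(all(Rs >= -1 & Rs <= 1))
  expect_error(anosim_test(d, c("a", rep("b", 9))), "at least 2")
})

test_that("PERMANOVA separates clusters and is scale invariant", {
  x <- two_cluster_matrix(n_per = 10)
  d <- stats::dist(x)
  g <- rep(c("a", "b"), each = 10)
  res <- permanova_test(d, g, n_perm = 999, seed = 1)
  expect_equal(res$p, 0.001)
  expect_gt(res$F, 100)
  # doubling all distances leaves pseudo-F unchanged
  res2 <- permanova_test(d * 2, g, n_perm = 99, seed = 1)
  expect_equal(res2$F, res$F, tolerance = 1e-10)
  # labels shuffled on an unstructured cloud: pseudo-F near 1 on average
  withr::with_seed(3, {
    cloud <- stats::dist(matrix(rnorm(60), 30, 2))
    Fs <- replicate(100, {
      g0 <- sample(rep(1:2, each = 15))
      permanova_test(cloud, g0, n_perm = 1, seed = 1)$F
    })
  })
  expect_lt(abs(mean(Fs) - 1), 0.5)
})

test_that("constrained zonation cuts at the block boundary and stays contiguous", {
  # two internally identical blocks
  m <- rbind(matrix(rep(c(0.9, 0.1), each = 6), 6),
             matrix(rep(c(0.1, 0.9), each = 5), 5))
  rownames(m) <- paste0("s", 1:11); colnames(m) <- c("a", "b")
  d <- bray_curtis(community_matrix(m, ages = 1:11))
  z <- constrained_zonation(d)
  expect_equal(z$boundary, 6)
  expect_equal(z$states, rep(c(1L, 2L), c(6, 5)))
  # all merge costs zero when all samples are identical
  same <- matrix(rep(c(0.5, 0.5), each = 6), 6,
                 dimnames = list(paste0("s", 1:6), c("a", "b")))
  z0 <- constrained_zonation(bray_curtis(community_matrix(same, ages = 1:6)))
  expect_true(all(z0$height == 0))
  # contiguity: every cut at every k gives contiguous zones
  withr::with_seed(13, {
    x <- matrix(rgamma(15 * 3, 1), 15); x <- x / rowSums(x)
    rownames(x) <- paste0("s", 1:15); colnames(x) <- paste0("t", 1:3)
  })
  zr <- constrained_zonation(bray_curtis(community_matrix(x, ages = 1:15)))
  for (k in 2:8) {
    lab <- cut_zonation(zr, k)
    expect_equal(lab, cummax(lab))           # non-decreasing = contiguous
    expect_equal(length(unique(lab)), k)
  }
  expect_error(constrained_zonation(stats::dist(matrix(0, 3, 2))), "at least 4")
})

test_that("two-state cut equals the exhaustive minimal-dispersion split", {
  # brute-force oracle over all contiguous splits, for noisy two-regime data
  withr::with_seed(17, {
    for (rep in 1:8) {
      n1 <- sample(4:10, 1); n2 <- sample(4:10, 1)
      base <- rbind(matrix(rep(c(0.8, 0.15, 0.05), each = n1), n1),
                    matrix(rep(c(0.1, 0.2, 0.7), each = n2), n2))
      noise <- matrix(rgamma(length(base), 40), nrow(base))
      x <- base * noise; x <- x / rowSums(x)
      rownames(x) <- paste0("s", seq_len(nrow(x))); colnames(x) <- paste0("t", 1:3)
      d <- bray_curtis(community_matrix(x, ages = seq_len(nrow(x))))
      z <- constrained_zonation(d)
      dm2 <- as.matrix(d)^2
      n <- nrow(x)
      disp <- function(i, j) sum(dm2[i:j, i:j]) / (2 * (j - i + 1))
      costs <- vapply(1:(n - 1), function(b) disp(1, b) + disp(b + 1, n), 0)
      expect_equal(z$boundary, which.min(costs))
    }
  })
})

test_that("Gaussian KDE counts modes and integrates to one", {
  # single repeated value -> degenerate, one mode
  k0 <- kde_bimodality(rep(3, 10))
  expect_true(k0$degenerate)
  expect_equal(k0$n_modes, 1L)
  expect_equal(k0$modes, 3)
  # two clusters at +-5 -> two modes
  withr::with_seed(4, v <- c(rnorm(50, -5, 0.5), rnorm(50, 5, 0.5)))
  k2 <- kde_bimodality(v)
  expect_equal(k2$n_modes, 2L)
  expect_true(any(abs(k2$modes + 5) < 1) && any(abs(k2$modes - 5) < 1))
  # density integrates to ~1 on the grid
  dx <- diff(k2$x[1:2])
  expect_lt(abs(sum(k2$density) * dx - 1), 0.01)
  expect_error(kde_bimodality(c(1, 2)), "at least 3")
})
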