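test_that("Morisita-Horn matches hand-evaluated and boundary cases", {
  # identical composition -> 0; disjoint -> 1
  expect_equal(morisita_horn(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(morisita_horn(c(1, 0), c(0, 1)), 1)
  # hand evaluation: numerator 2 * 0.25, denominator 0.5 + 0.5
  expect_equal(morisita_horn(c(0.5, 0.5, 0), c(0.5, 0, 0.5)), 0.5)
  expect_error(morisita_horn(c(1, 0), c(1, 0, 0)), "length")
  expect_error(morisita_horn(c(0, 0), c(1, 0)), "degenerate")
})

test_that("Morisita-Horn agrees with the naive formula on random vectors", {
  set.seed(101)
  for (i in 1:300) {
    s <- sample(2:41, 1)
    x <- random_proportions(s); y <- random_proportions(s)
    expect_equal(morisita_horn(x, y), min(1, max(0, mh_naive(x, y))),
                 tolerance = 1e-12)
    # symmetry and count-duplication invariance
    expect_equal(morisita_horn(x, y), morisita_horn(y, x))
    expect_equal(morisita_horn(7 * x, y), morisita_horn(x, y))
  }
})

test_that("Morisita-Horn agrees with an independent library implementation", {
  skip_if_not_installed("vegan")
  set.seed(55)
  for (i in 1:50) {
    x <- random_proportions(30); y <- random_proportions(30)
    v <- as.numeric(vegan::vegdist(rbind(x, y), method = "horn"))
    expect_equal(morisita_horn(x, y), v, tolerance = 1e-12)
  }
})

test_that("pairwise matrix matches the double-loop oracle", {
  set.seed(11)
  m <- matrix(rexp(10 * 8), 10, 8)
  d <- pairwise_matrix(m)
  expect_equal(dim(d), c(10, 10))
  expect_equal(diag(d), rep(0, 10), ignore_attr = TRUE)
  expect_equal(d, t(d))
  for (i in 1:10) for (j in 1:10) {
    if (i != j) expect_equal(d[i, j], morisita_horn(m[i, ], m[j, ]),
                             tolerance = 1e-12)
  }
  # identical samples give an (numerically) all-zero matrix
  same <- matrix(rep(c(1, 2, 3), each = 3), 3, 3)
  expect_lt(max(abs(pairwise_matrix(same))), 1e-12)
  expect_error(pairwise_matrix(m[1, , drop = FALSE]), "2 samples")
})

test_that("PCA of the dissimilarity matrix honours rank and variance ordering", {
  # one-dimensional gradient: a two-species seesaw. Its distance rows are
  # a curved (quadratic) image of the gradient, so the variance splits
  # into a dominant gradient axis and a small arch axis.
  p <- seq(0.45, 0.55, length.out = 8)
  x <- toy_table(cbind(a = p, b = 1 - p), ages = 1:8)
  d <- pairwise_matrix(x)
  pc <- pca_on_dissimilarity(d, k = 2)
  expect_gt(pc$explained[1], 0.8)
  expect_gt(sum(pc$explained[1:2]), 0.999)
  # PC1 scores are monotone along the gradient
  expect_true(all(diff(pc$scores[, 1]) > 0) || all(diff(pc$scores[, 1]) < 0))
  # k beyond the matrix rank is truncated with a warning
  set.seed(8)
  d3 <- pairwise_matrix(matrix(rexp(9), 3, 3))
  expect_warning(pc3 <- pca_on_dissimilarity(d3, k = 3), "rank")
  expect_lte(ncol(pc3$scores), 2)
  # fractions are non-increasing and sum to <= 1
  set.seed(3)
  d2 <- pairwise_matrix(matrix(rexp(20 * 10), 20, 10))
  pc2 <- pca_on_dissimilarity(d2, k = 3)
  expect_true(all(diff(pc2$all_fractions) <= 1e-12))
  expect_lte(sum(pc2$all_fractions), 1 + 1e-9)
  # degenerate: identical samples -> zero scores and variance
  d0 <- matrix(0, 4, 4)
  pc0 <- pca_on_dissimilarity(d0, k = 3)
  expect_true(all(pc0$scores == 0))
  expect_equal(pc0$explained, rep(0, 3))
  expect_error(pca_on_dissimilarity(d2, k = 0), "at least 1")
})

test_that("PCA reconstruction from all axes reproduces the centred matrix", {
  set.seed(9)
  d <- pairwise_matrix(matrix(rexp(12 * 7), 12, 7))
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  rec <- pc$x %*% t(pc$rotation)
  centred <- scale(d, center = TRUE, scale = FALSE)
  expect_equal(rec, centred, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("RGB mapping rescales per axis with PC1->blue, PC2->red, PC3->green", {
  sc <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 2, 4))
  rgb <- scores_to_rgb(sc)
  expect_equal(colnames(rgb), c("r", "g", "b"))
  # sample at the minimum of all axes -> black
  expect_equal(unname(rgb[1, ]), c(0, 0, 0))
  # sample at max of PC1 only -> pure blue
  expect_equal(unname(rgb[2, ]), c(0, 0, 1))
  # equal scores give identical colours
  sc2 <- rbind(c(1, 2, 3), c(1, 2, 3), c(4, 0, 1))
  rgb2 <- scores_to_rgb(sc2)
  expect_equal(rgb2[1, ], rgb2[2, ])
  expect_warning(scores_to_rgb(cbind(1:3, 1, 1:3)), "constant axis")
  expect_error(scores_to_rgb(cbind(1:3, 1:3)), "3 axes")
})

test_that("Hovmoller gridding bins left-closed and conserves counts", {
  g <- grid_hovmoller(c(0.2, 0.4), ages = c(0.5, 0.9),
                      latitudes = c(41, 40.1))
  expect_equal(nrow(g), 1)
  expect_equal(g$time_bin, 0)
  expect_equal(g$lat_bin, 40)
  expect_equal(g$value, 0.3)
  expect_equal(g$n, 2L)
  # single sample keeps its own value
  g1 <- grid_hovmoller(7, 3.2, 10)
  expect_equal(g1$value, 7)
  # counts conserve the number of samples
  set.seed(2)
  n <- 200
  g2 <- grid_hovmoller(runif(n), runif(n, 0, 24), runif(n, 0, 65))
  expect_equal(sum(g2$n), n)
  expect_error(grid_hovmoller(1, -0.5, 10), "extent")
})
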