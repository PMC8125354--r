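test_that("KL divergence of a sample with itself is zero and is never negative", {
  set.seed(1)
  x <- matrix(rnorm(200), ncol = 2)
  expect_equal(histogram_kl(x, x), 0)
  for (s in 1:20) {
    set.seed(s)
    a <- matrix(rnorm(120, sd = runif(1, 0.5, 2)), ncol = 2)
    b <- matrix(rnorm(140, mean = runif(1, -1, 1)), ncol = 2)
    expect_gte(histogram_kl(a, b), 0)
  }
})

test_that("discrete KL matches the two-bin closed form", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(round(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)), 4), 0.1438)
})

test_that("disjoint-support samples give a large but finite divergence", {
  a <- matrix(rnorm(100), ncol = 1)
  b <- matrix(rnorm(100, mean = 50), ncol = 1)
  v <- histogram_kl(a, b, bins = 10)
  expect_true(is.finite(v))
  expect_gt(v, 1)
  # bounded by -log of the smoothing mass share
  expect_lt(v, -log(1e-5 / (1 + 10 * 1e-5)))
})

test_that("PCA projection satisfies the eigenbasis contracts", {
  set.seed(4)
  x2 <- matrix(rnorm(60), ncol = 2)
  p2 <- pca2_project(x2)
  expect_equal(sum(p2$var_explained), 1, tolerance = 1e-9)
  # rank-1 input: all variance on the first component
  r1 <- outer(rnorm(30), c(1, 2, 3))
  p1 <- pca2_project(r1)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-9)
  expect_equal(p1$var_explained[2], 0, tolerance = 1e-9)
  # orthonormal loadings
  x5 <- matrix(rnorm(250), ncol = 5)
  p5 <- pca2_project(x5)
  expect_equal(crossprod(p5$rotation), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pca2_project(matrix(1, 10, 3)), "rank 0")
})

test_that("identical train and test samples give unit weights on 49 bins", {
  set.seed(6)
  pts <- matrix(rnorm(400), ncol = 2)
  g <- weight_ratio_grid(pts, pts)
  expect_equal(g$n_bins, 7L)
  expect_length(g$ratio, 49L)
  occ <- g$train_density > 0
  expect_true(all(abs(g$ratio[occ] - 1) < 1e-12))
  expect_equal(sum(g$train_density), 1, tolerance = 1e-9)
  expect_equal(sum(g$test_density), 1, tolerance = 1e-9)
})

test_that("bins with train mass but no test mass sit at exactly -5", {
  train <- cbind(c(rep(0, 10), rep(10, 10)), c(rep(0, 10), rep(10, 10)))
  test <- cbind(rep(0.1, 8), rep(0.1, 8))   # never visits the (10, 10) corner
  g <- weight_ratio_grid(train, test)
  corner <- g$train_density > 0 & g$test_density == 0
  expect_true(any(corner))
  expect_true(all(g$log_ratio[corner] == -5))
})

test_that("unsupported bins carry the sentinel and weights conserve mass", {
  train <- matrix(runif(60), ncol = 2)
  test <- rbind(matrix(runif(40), ncol = 2), c(5, 5))  # mass outside train support
  g <- weight_ratio_grid(train, test)
  expect_true(any(g$unsupported))
  expect_true(all(is.na(g$ratio[g$unsupported])))
  # when test support is inside train support, sum w * p_train = 1
  set.seed(7)
  tr <- matrix(rnorm(2000), ncol = 2)
  te <- tr[sample(1000, 300), ]
  g2 <- weight_ratio_grid(tr, te)
  supp <- !is.na(g2$ratio)
  expect_equal(sum(g2$ratio[supp] * g2$train_density[supp]), 1,
               tolerance = 1e-9)
  expect_error(weight_ratio_grid(cbind(1, 1:5), cbind(1, 1:5)), "degenerate")
})

test_that("log-ratio deltas label equal, lower and higher bins", {
  set.seed(8)
  pts <- matrix(rnorm(300), ncol = 2)
  g <- weight_ratio_grid(pts, pts)
  d0 <- log_ratio_delta(g, g, tau = 0.5)
  expect_true(all(d0$delta[!is.na(d0$delta)] == 0))
  expect_true(all(d0$labels[!is.na(d0$labels)] == "="))
  # plant a single-bin difference of 2 log10 units
  g2 <- g
  bin <- which(!is.na(g$log_ratio))[1]
  g2$log_ratio[bin] <- g2$log_ratio[bin] + 2
  d2 <- log_ratio_delta(g2, g, tau = 0.5)
  expect_equal(d2$n_pos, 1L)
  expect_equal(d2$n_neg, 0L)
  bad <- weight_ratio_grid(pts + 100, pts + 100)
  expect_error(log_ratio_delta(g, bad), "geometry")
})

test_that("proper-vs-improper grids differ more than improper replicates", {
  agree <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    ds <- generate_feature_dataset(clustered_config(s))
    proj <- pca2_project(ds$features)$scores
    grid_of <- function(fold) weight_ratio_grid(proj[fold$train, , drop = FALSE],
                                                proj[fold$eval, , drop = FALSE])
    gp <- grid_of(lopo_partition(ds)$folds[[1]])
    gi1 <- grid_of(improper_shuffled_kfold(ds, 12, seed = s)$folds[[1]])
    gi2 <- grid_of(improper_shuffled_kfold(ds, 12, seed = s + 1000L)$folds[[1]])
    n_eq_cross <- log_ratio_delta(gp, gi1)$n_equal
    n_eq_rep <- log_ratio_delta(gi2, gi1)$n_equal
    if (n_eq_cross < n_eq_rep) agree <- agree + 1L
  }
  expect_gt(agree, n_seeds / 2)
})

test_that("the 2-D embedding is seeded, finite and separates distant blobs", {
  set.seed(9)
  blobs <- rbind(matrix(rnorm(300, mean = 0, sd = 1), ncol = 2),
                 matrix(rnorm(300, mean = 100, sd = 1), ncol = 2))
  who <- rep(c("A", "B"), each = 150)
  e1 <- embed_2d(blobs, perplexity = 20, seed = 11)
  e2 <- embed_2d(blobs, perplexity = 20, seed = 11)
  expect_identical(e1$coords, e2$coords)
  expect_equal(dim(e1$coords), c(300L, 2L))
  expect_true(all(is.finite(e1$coords)))
  expect_equal(participant_purity(e1$coords, who, k = 10), 1.0)
  expect_error(embed_2d(blobs[1:20, ], perplexity = 20), "perplexity too large")
})

test_that("participant purity is 1 for far clusters and chance-level for mixed data", {
  # P far-apart tight groups
  grp <- rbind(matrix(0.01 * rnorm(40), ncol = 2),
               matrix(0.01 * rnorm(40) + 50, ncol = 2),
               matrix(0.01 * rnorm(40) - 50, ncol = 2))
  who <- rep(c("A", "B", "C"), each = 20)
  expect_equal(participant_purity(grp, who, k = 5), 1.0)

  # everyone from one distribution: purity within 3 sd of the permutation level
  set.seed(10)
  x <- matrix(rnorm(400), ncol = 2)
  ids <- rep(sprintf("P%d", 1:4), each = 50)
  observed <- participant_purity(x, ids, k = 10)
  perm <- replicate(60, participant_purity(x, sample(ids), k = 10))
  expect_lte(abs(observed - mean(perm)), 3 * sd(perm) + 1e-9)
  expect_error(participant_purity(x, ids, k = 200), "smaller")
})
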