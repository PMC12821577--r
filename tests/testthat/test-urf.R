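test_that("marginal permutation preserves columns exactly", {
  withr::local_seed(1)
  X <- matrix(rnorm(50), 10)
  P <- synth_null(X, seed = 2)
  for (j in 1:5) expect_equal(sort(P[, j]), sort(X[, j]))
  expect_equal(colMeans(P), colMeans(X))
  expect_equal(apply(P, 2, sd), apply(X, 2, sd))
  # single column is a permutation of itself
  p1 <- synth_null(X[, 1, drop = FALSE], seed = 3)
  expect_equal(sort(p1[, 1]), sort(X[, 1]))
})

test_that("permutation destroys correlation between columns", {
  withr::local_seed(4)
  z <- rnorm(40)
  X <- cbind(z, z)   # perfectly correlated pair
  cors <- vapply(1:100, function(s) cor(synth_null(X, seed = s))[1, 2],
                 numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
  expect_lt(max(abs(cors)), 0.8)
})

test_that("URF dissimilarities satisfy the metric-like contract", {
  withr::local_seed(5)
  X <- matrix(rnorm(20 * 8), 20)
  X[1:10, 1:4] <- X[1:10, 1:4] + 3
  X[11, ] <- X[10, ]   # duplicated sample
  D <- urf_dissimilarity(X, n_iterations = 3, n_trees = 200, min_leaf = 4,
                         seed = 6)
  M <- D$values
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_true(all(M >= 0 & M <= 1))
  # duplicates are each other's nearest neighbour
  expect_equal(unname(which.min(replace(M[11, ], 11, Inf))), 10L)
  # seed contract
  D2 <- urf_dissimilarity(X, n_iterations = 3, n_trees = 200, min_leaf = 4,
                          seed = 6)
  expect_identical(M, D2$values)
  expect_error(urf_dissimilarity(X[1, , drop = FALSE]), "2 samples")
})

test_that("planted clusters are closer within than between", {
  ok <- vapply(1:5, function(s) {
    withr::local_seed(s)
    X <- matrix(rnorm(30 * 10), 30)
    X[1:15, 1:5] <- X[1:15, 1:5] + 2.5
    D <- urf_dissimilarity(X, n_iterations = 3, n_trees = 200, min_leaf = 4,
                           seed = 100 + s)$values
    g <- rep(1:2, each = 15)
    within <- mean(D[outer(g, g, "==") & upper.tri(D)])
    between <- mean(D[outer(g, g, "!=") & upper.tri(D)])
    within < between
  }, logical(1))
  expect_true(all(ok))
})

test_that("more iterations stabilize the dissimilarity estimate", {
  withr::local_seed(7)
  X <- matrix(rnorm(16 * 6), 16)
  spread <- function(iters) {
    reps <- sapply(1:6, function(s) {
      urf_dissimilarity(X, n_iterations = iters, n_trees = 60, min_leaf = 4,
                        seed = 200 + s)$values[upper.tri(diag(16))]
    })
    mean(apply(reps, 1, sd))
  }
  expect_lt(spread(8), spread(1))
})

test_that("PCoA reproduces Euclidean configurations", {
  # points on a line: one axis, 100% explained
  x <- c(0, 1, 3, 7)
  D <- as.matrix(dist(x))
  p <- pcoa(D, k = 3)
  expect_equal(p$explained_pct[1], 100, tolerance = 1e-8)
  expect_equal(as.matrix(dist(p$coordinates[, 1])), D,
               tolerance = 1e-8, ignore_attr = TRUE)
  # three equidistant points: two equal eigenvalues, 50/50
  D3 <- matrix(1, 3, 3) - diag(3)
  p3 <- pcoa(D3, k = 2)
  expect_equal(p3$explained_pct, c(50, 50), tolerance = 1e-8)
  # general Euclidean clouds up to 10 points reconstruct to 1e-8
  for (s in 1:5) {
    withr::local_seed(s)
    n <- sample(4:10, 1)
    Y <- matrix(rnorm(n * 3), n)
    D <- as.matrix(dist(Y))
    pe <- pcoa(D, k = n - 1)
    expect_equal(as.matrix(dist(pe$coordinates)), D,
                 tolerance = 1e-8, ignore_attr = TRUE)
    # cross-check against classical scaling in base R
    cm <- stats::cmdscale(D, k = 3, eig = TRUE)
    expect_equal(abs(pe$coordinates[, 1:3]), abs(cm$points),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(pcoa(D3, k = 3), "smaller")
})

test_that("explained percentages are non-increasing and bounded", {
  withr::local_seed(11)
  X <- matrix(rnorm(12 * 5), 12)
  D <- urf_dissimilarity(X, n_iterations = 2, n_trees = 100, min_leaf = 4,
                         seed = 12)
  p <- pcoa(D, k = 5)
  expect_true(all(diff(p$explained_pct) <= 1e-9))
  expect_lte(sum(p$explained_pct), 100 + 1e-9)
  # embedding distances correlate with the input dissimilarities
  rho <- cor(as.numeric(as.matrix(dist(p$coordinates))[upper.tri(diag(12))]),
             D$values[upper.tri(diag(12))], method = "spearman")
  expect_gt(rho, 0)
})

test_that("confounder screen detects structure matching the embedding", {
  withr::local_seed(13)
  X <- matrix(rnorm(24 * 6), 24)
  X[1:12, ] <- X[1:12, ] + 3
  D <- urinmr:::as_dissimilarity(as.matrix(dist(X)) / max(dist(X)))
  covs <- data.frame(cluster = rep(c("a", "b"), each = 12),
                     noise = rnorm(24))
  scr <- confounder_screen(D, covs, n_perm = 99, seed = 1)
  expect_equal(scr$p_value[1], 1 / 100)
  expect_gt(scr$p_value[2], 0.05)
  expect_error(confounder_screen(D, data.frame(k = rep(1, 24))), "constant")
})

test_that("screen statistics are invariant to sample order", {
  withr::local_seed(14)
  X <- matrix(rnorm(18 * 4), 18)
  D <- urinmr:::as_dissimilarity(as.matrix(dist(X)))
  covs <- data.frame(g = rep(c("a", "b", "c"), 6), age = rnorm(18))
  s1 <- confounder_screen(D, covs, n_perm = 0)
  pm <- sample(18)
  Dp <- urinmr:::as_dissimilarity(D$values[pm, pm])
  s2 <- confounder_screen(Dp, covs[pm, ], n_perm = 0)
  expect_equal(s2$statistic, s1$statistic, tolerance = 1e-10)
})

test_that("pseudo-F agrees with an independent PERMANOVA implementation", {
  withr::local_seed(15)
  X <- matrix(rnorm(20 * 5), 20)
  D <- as.matrix(dist(X))
  covs <- data.frame(g = factor(rep(c("a", "b"), each = 10)),
                     bmi = rnorm(20, 25, 3))
  scr <- confounder_screen(urinmr:::as_dissimilarity(D), covs, n_perm = 0)
  for (i in 1:2) {
    ad <- vegan::adonis2(stats::as.dist(D) ~ covs[[i]], permutations = 0)
    expect_equal(scr$statistic[i], ad$F[1], tolerance = 1e-8)
  }
})
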