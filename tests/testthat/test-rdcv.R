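test_that("compiled engine matches the plain-R reference", {
  withr::local_seed(1)
  n1 <- 14; n0 <- 16; p <- 8
  X <- matrix(rnorm((n1 + n0) * p), n1 + n0)
  y01 <- c(rep(1L, n1), rep(0L, n0))
  X[y01 == 1, 1:2] <- X[y01 == 1, 1:2] + 1
  X <- scale(X)
  y <- factor(ifelse(y01 == 1, "worker", "resident"),
              levels = c("worker", "resident"))
  folds <- urinmr:::with_seed(5, urinmr:::build_folds(y01, 4, 3, 3))
  eng <- urinmr:::rdcv_engine_cpp(X, y01, folds$outer, folds$inner, 4, 1e-8)
  ref <- ref_rdcv(X, y, folds$outer, folds$inner, 4)
  expect_equal(eng$pred, ref$pred)
  expect_equal(unname(eng$chosen_A), ref$chosen)
  # weights agree up to numerical noise
  expect_equal(eng$weights_fold, ref$weights_fold, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("every sample is predicted exactly once per repetition", {
  withr::local_seed(2)
  X <- matrix(rnorm(40 * 6), 40)
  y <- factor(rep(c("w", "r"), 20), levels = c("w", "r"))
  r <- rdcv(X, y, rdcv_config(n_outer_folds = 4, n_inner_folds = 3,
                              n_repetitions = 5, max_components = 3,
                              seed = 3))
  expect_true(all(r$predictions %in% c(0L, 1L)))
  expect_equal(dim(r$predictions), c(40L, 5L))
})

test_that("separable data yields perfect outer-loop metrics", {
  d <- separable_data(n1 = 20, n0 = 20)
  r <- rdcv(d$X, d$y, rdcv_config(n_outer_folds = 5, n_inner_folds = 4,
                                  n_repetitions = 4, max_components = 3,
                                  seed = 4))
  expect_equal(unname(r$summary$mean), rep(100, 4))
  expect_equal(unname(r$summary$sd), rep(0, 4))
  expect_true(all(sample_stability(r) == "always_correct"))
})

test_that("null data stays at chance regardless of model capacity", {
  accs <- vapply(1:3, function(s) {
    withr::local_seed(s)
    X <- scale(matrix(rnorm(60 * 30), 60))
    y <- factor(rep(c("w", "r"), each = 30), levels = c("w", "r"))
    r <- rdcv(X, y, rdcv_config(n_outer_folds = 5, n_inner_folds = 4,
                                n_repetitions = 4, max_components = 10,
                                seed = 10 + s))
    mean(r$metrics$accuracy)
  }, numeric(1))
  expect_gt(mean(accs), 40)
  expect_lt(mean(accs), 60)
})

test_that("rdcv is reproducible from its seed", {
  withr::local_seed(6)
  X <- matrix(rnorm(36 * 5), 36)
  y <- factor(rep(c("w", "r"), 18), levels = c("w", "r"))
  cfg <- rdcv_config(n_outer_folds = 3, n_inner_folds = 3,
                     n_repetitions = 3, max_components = 3, seed = 99)
  expect_identical(rdcv(X, y, cfg)$predictions, rdcv(X, y, cfg)$predictions)
})

test_that("auto-scaling makes results invariant to column rescaling", {
  withr::local_seed(7)
  X <- matrix(rlnorm(40 * 6), 40)
  edges <- cbind(seq(9, by = -0.1, length.out = 6),
                 seq(8.9, by = -0.1, length.out = 6))
  y <- factor(rep(c("w", "r"), 20), levels = c("w", "r"))
  cfg <- rdcv_config(n_outer_folds = 4, n_inner_folds = 3,
                     n_repetitions = 3, max_components = 3, seed = 8)
  z1 <- log_autoscale(binned_matrix(X, edges))$values
  z2 <- log_autoscale(binned_matrix(sweep(X, 2, c(2, 5, 0.1, 1, 10, 3), `*`),
                                    edges))$values
  expect_equal(z1, z2, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(rdcv(z1, y, cfg)$metrics, rdcv(z2, y, cfg)$metrics)
})

test_that("permutation p-values are valid and detect planted effects", {
  withr::local_seed(9)
  n <- 44
  y <- factor(rep(c("w", "r"), each = n / 2), levels = c("w", "r"))
  X <- matrix(rnorm(n * 10), n)
  X[y == "w", 1:4] <- X[y == "w", 1:4] + 1.5
  cfg <- rdcv_config(n_outer_folds = 4, n_inner_folds = 3,
                     n_repetitions = 2, max_components = 3,
                     n_permutations = 49, perm_repetitions = 1, seed = 10)
  pt <- permutation_test(scale(X), y, cfg)
  expect_true(all(pt$p_values > 0 & pt$p_values <= 1))
  expect_true(all(pt$p_values <= 0.05))
  expect_equal(nrow(pt$null), 49)
})

test_that("sign-unstable or zero-straddling variables are never selected", {
  fake <- structure(list(
    weights_rep = rbind(c(1, 1, 0.5), c(-1, 1, 0.5), c(1, 1, 0.5)),
    weights_fold = rbind(c(1, 1, 0.5), c(-1, 1, 0.5), c(1, 1, 0.5)),
    sign_pos = c(2, 3, 3), sign_neg = c(1, 0, 0),
    variables = c("v1", "v2", "v3"),
    y = factor(c("w", "r"), levels = c("w", "r")),
    config = rdcv_config(n_repetitions = 3)), class = "rdcv_result")
  sel <- select_variables(fake, alpha = 0.05)
  expect_false(sel$significant[1])   # sign flip
  expect_true(sel$significant[2])    # stable, CI degenerate at 1
  expect_true(sel$significant[3])
  expect_equal(sel$group[2], "w")
  neg <- fake
  neg$weights_fold <- -neg$weights_fold
  neg$sign_pos <- c(1, 0, 0); neg$sign_neg <- c(2, 3, 3)
  expect_equal(select_variables(neg)$group[2], "r")
})

test_that("per-sample stability flags systematically misclassified samples", {
  d <- separable_data(n1 = 20, n0 = 20)
  y_bad <- d$y
  y_bad[1] <- "resident"   # mislabel one separable-class sample
  r <- rdcv(d$X, y_bad, rdcv_config(n_outer_folds = 4, n_inner_folds = 3,
                                    n_repetitions = 4, max_components = 2,
                                    seed = 11))
  st <- sample_stability(r)
  expect_equal(as.character(st[1]), "always_wrong")
  expect_true(all(st[-1] == "always_correct"))
  expect_equal(length(st), 40)
  expect_false(anyNA(st))
})
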