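#' Synthetic-class copy by marginal permutation
#'
#' Builds the contrast class for unsupervised random forests: each
#' column is independently permuted across samples, preserving every
#' marginal distribution exactly while destroying the covariance
#' structure.
#'
#' @param x a [binned_matrix] or plain matrix.
#' @param seed optional seed.
#' @return An object of the same type with permuted columns.
#' @export
synth_null <- function(x, seed = NULL) {
  X <- if (inherits(x, "binned_matrix")) x$values else as.matrix(x)
  if (nrow(X) < 2) stopf("need at least 2 samples")
  with_seed(seed, {
    P <- apply(X, 2, sample)
  })
  if (inherits(x, "binned_matrix")) {
    out <- x
    rownames(P) <- rownames(X)
    out$values <- P
    out
  } else P
}

#' Unsupervised random-forest dissimilarity
#'
#' Trains, over `n_iterations` iterations, a random forest to separate
#' the real samples (class 1) from a fresh marginal-permutation copy
#' (class 2, see [synth_null()]). The proximity of two real samples is
#' the fraction of trees in which they share a terminal node;
#' dissimilarity is `1 - proximity` averaged over iterations (or its
#' square root with `variant = "sqrt"`).
#'
#' @param x a [binned_matrix] or matrix (samples x variables).
#' @param n_iterations synthetic-class redraws (each grows a forest).
#' @param n_trees trees per forest.
#' @param min_leaf minimum terminal-node size.
#' @param mtry variables tried per split; default `sqrt(p)`.
#' @param variant `"one_minus"` (default) for `1 - proximity`,
#'   `"sqrt"` for `sqrt(1 - proximity)`.
#' @param oob_only if `TRUE`, proximities are computed from out-of-bag
#'   trees only.
#' @param seed seed controlling both the synthetic copies and the
#'   forests.
#' @return A `dissimilarity_matrix`: list with `values` (n x n symmetric
#'   matrix, zero diagonal, entries in `[0, 1]`) and `sample_ids`.
#' @export
urf_dissimilarity <- function(x, n_iterations = 50, n_trees = 1500,
                              min_leaf = 8, mtry = NULL,
                              variant = c("one_minus", "sqrt"),
                              oob_only = FALSE, seed = NULL) {
  variant <- match.arg(variant)
  X <- if (inherits(x, "binned_matrix")) x$values else as.matrix(x)
  ids <- if (inherits(x, "binned_matrix")) x$sample_ids else
    rownames(X) %||% sprintf("S%03d", seq_len(nrow(X)))
  n <- nrow(X)
  if (n < 2) stopf("need at least 2 samples")
  stopifnot(n_iterations >= 1, n_trees >= 1, min_leaf >= 1)
  mtry <- mtry %||% max(1, floor(sqrt(ncol(X))))
  with_seed(seed, {
    prox <- matrix(0, n, n)
    for (it in seq_len(n_iterations)) {
      Xs <- apply(X, 2, sample)
      XX <- rbind(X, Xs)
      colnames(XX) <- sprintf("V%d", seq_len(ncol(XX)))
      y <- factor(rep(c("real", "synthetic"), each = n))
      rf <- randomForest::randomForest(x = XX, y = y, ntree = n_trees,
                                       mtry = mtry, nodesize = min_leaf,
                                       proximity = TRUE,
                                       oob.prox = oob_only)
      prox <- prox + rf$proximity[seq_len(n), seq_len(n)]
    }
    prox <- prox / n_iterations
  })
  d <- 1 - prox
  if (variant == "sqrt") d <- sqrt(pmax(d, 0))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[d < 0] <- 0; d[d > 1] <- 1
  dimnames(d) <- list(ids, ids)
  structure(list(values = d, sample_ids = ids),
            class = "dissimilarity_matrix")
}

#' @exportS3Method base::print
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d samples, mean off-diagonal %.3f\n",
              nrow(x$values),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

as_dissimilarity <- function(D) {
  if (inherits(D, "dissimilarity_matrix")) return(D)
  D <- as.matrix(D)
  structure(list(values = D,
                 sample_ids = rownames(D) %||% sprintf("S%03d", seq_len(nrow(D)))),
            class = "dissimilarity_matrix")
}

#' Principal coordinates analysis
#'
#' Classical (Torgerson) scaling of a dissimilarity matrix: the squared
#' dissimilarities are double-centered (`-1/2 J D^2 J`), the Gram matrix
#' eigendecomposed, and the top `k` coordinates with positive
#' eigenvalues returned. Explained percentages are relative to the sum
#' of positive eigenvalues. Axis signs follow the convention that the
#' largest-magnitude coordinate of each axis is positive.
#'
#' @param D a `dissimilarity_matrix` (or symmetric matrix).
#' @param k number of coordinates to keep (`k < n`).
#' @return A list of class `pcoa_result`: `coordinates` (n x k),
#'   `explained_pct`, `eigenvalues`.
#' @export
pcoa <- function(D, k = 2) {
  D <- as_dissimilarity(D)
  n <- nrow(D$values)
  if (k >= n) stopf("k must be smaller than the number of samples")
  A <- -0.5 * D$values^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-12 * max(abs(e$values)))
  k_eff <- min(k, length(pos))
  if (k_eff == 0) stopf("no positive eigenvalues; dissimilarities degenerate")
  vals <- e$values[pos][seq_len(k_eff)]
  vecs <- e$vectors[, pos, drop = FALSE][, seq_len(k_eff), drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(vals), `*`)
  for (j in seq_len(k_eff)) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- D$sample_ids
  colnames(coords) <- sprintf("PCo%d", seq_len(k_eff))
  structure(list(coordinates = coords,
                 explained_pct = 100 * vals / sum(e$values[pos]),
                 eigenvalues = vals),
            class = "pcoa_result")
}

#' Permutation screen for confounders on a dissimilarity matrix
#'
#' For each covariate, partitions the total dissimilarity-based variance
#' into a model and a residual part (distance-based redundancy
#' decomposition: pseudo-F from the trace of the projected
#' Gower-centered matrix) and assesses significance by permuting sample
#' labels. Categorical and continuous covariates are handled uniformly
#' through the model matrix; for a single categorical covariate the
#' statistic is the usual one-way PERMANOVA pseudo-F.
#'
#' @param D a `dissimilarity_matrix`.
#' @param covariates data.frame of covariates (rows in sample order).
#' @param n_perm number of label permutations.
#' @param seed optional seed.
#' @return data.frame with one row per covariate: `statistic`
#'   (pseudo-F), `df`, `p_value`.
#' @export
confounder_screen <- function(D, covariates, n_perm = 999, seed = NULL) {
  D <- as_dissimilarity(D)
  covariates <- as.data.frame(covariates)
  n <- nrow(D$values)
  if (nrow(covariates) != n) stopf("covariates must cover every sample")
  if (anyNA(covariates)) stopf("covariates must be complete")
  A <- -0.5 * D$values^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  sst <- sum(diag(G))
  res <- lapply(names(covariates), function(v) {
    x <- covariates[[v]]
    if (length(unique(x)) < 2) stopf("constant covariate '%s'", v)
    M <- stats::model.matrix(~x)
    H <- M %*% solve(crossprod(M), t(M))
    df1 <- ncol(M) - 1
    df2 <- n - ncol(M)
    fstat <- function(Gm) {
      ssm <- sum(H * Gm)          # tr(H G) since H symmetric
      ((ssm) / df1) / ((sum(diag(Gm)) - ssm) / df2)
    }
    f0 <- fstat(G)
    exceed <- with_seed(if (is.null(seed)) NULL else
      child_seed(seed, match(v, names(covariates))), {
        sum(vapply(seq_len(n_perm), function(b) {
          pm <- sample.int(n)
          fstat(G[pm, pm]) >= f0
        }, logical(1)))
      })
    data.frame(covariate = v, statistic = f0, df = df1,
               p_value = (1 + exceed) / (1 + n_perm))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
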