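#' NIPALS partial least squares (single response)
#'
#' Standard NIPALS PLS1: for each component the weight vector is the
#' normalized covariance `X'y`, scores are `X w`, and `X` is deflated by
#' the rank-one score/loading product. The rotation `R = W (P'W)^-1`
#' maps (centered) variables directly to scores, `T = X R`.
#'
#' @param X column-centered predictor matrix.
#' @param y centered response vector (class indicator for
#'   discrimination).
#' @param A number of components requested; the fit stops early if `X`
#'   deflates to numerical zero.
#' @return List with `W` (weights), `P` (loadings), `T` (scores), `R`
#'   (rotation), `q` (response loadings), `A` (components fitted).
#' @export
fit_pls <- function(X, y, A) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (all(abs(X) < .Machine$double.eps)) stopf("zero-variance X")
  n <- nrow(X); p <- ncol(X)
  A <- min(A, p, n - 1)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xd <- X
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xd, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t * t)
    if (tt < 1e-12) break
    pv <- crossprod(Xd, t) / tt
    q[a] <- sum(y * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t
    a_eff <- a
  }
  if (a_eff == 0L) stopf("no PLS component could be extracted")
  W <- W[, seq_len(a_eff), drop = FALSE]
  P <- P[, seq_len(a_eff), drop = FALSE]
  Tm <- Tm[, seq_len(a_eff), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  rownames(W) <- rownames(P) <- rownames(R) <- colnames(X)
  list(W = W, P = P, T = Tm, R = R, q = q[seq_len(a_eff)], A = a_eff)
}

#' PLS-LDA discriminant model
#'
#' Reduces the predictors to `A` PLS score dimensions (class indicator
#' as the PLS response) and fits linear discriminant analysis on the
#' scores; the first canonical variate is the LDA discriminant
#' direction in score space. Back-projection through the PLS rotation
#' yields one weight per original variable (`cv1_weights`), whose sign
#' indicates the class in which the variable is elevated (positive =
#' first factor level). Class priors are the training frequencies.
#'
#' @param X predictor matrix (samples x variables); centered internally.
#' @param y two-level factor; the FIRST level is the positive class.
#' @param A number of PLS components.
#' @param ridge relative ridge added to the within-class scatter
#'   diagonal to guard against singularity.
#' @return An object of class `plslda_model`.
#' @export
fit_plslda <- function(X, y, A = 2, ridge = 1e-8) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stopf("y must have exactly two classes")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  y01 <- as.integer(y == levels(y)[1])
  yc <- y01 - mean(y01)
  pls <- fit_pls(Xc, yc, A)
  Tm <- pls$T
  i1 <- y01 == 1; i0 <- !i1
  m1 <- colMeans(Tm[i1, , drop = FALSE])
  m0 <- colMeans(Tm[i0, , drop = FALSE])
  S <- (crossprod(sweep(Tm[i1, , drop = FALSE], 2, m1)) +
          crossprod(sweep(Tm[i0, , drop = FALSE], 2, m0))) / (nrow(Tm) - 2)
  diag(S) <- diag(S) + ridge * mean(diag(S)) + 1e-300
  a_dir <- solve(S, m1 - m0)
  cutoff <- 0.5 * sum(a_dir * (m1 + m0)) - log(sum(i1) / sum(i0))
  w <- drop(pls$R %*% a_dir)
  w <- w / sqrt(sum(w^2))
  structure(list(pls = pls, lda_direction = a_dir, cutoff = cutoff,
                 cv1_weights = w, center = mu, levels = levels(y),
                 A = pls$A),
            class = "plslda_model")
}

#' @exportS3Method base::print
print.plslda_model <- function(x, ...) {
  cat(sprintf("<plslda_model> %d components, %d variables, classes %s/%s\n",
              x$A, length(x$cv1_weights), x$levels[1], x$levels[2]))
  invisible(x)
}

#' Predict classes from a PLS-LDA model
#'
#' @param object a `plslda_model`.
#' @param newdata matrix with the training variables.
#' @param type `"class"` (default) or `"score"` (the discriminant score
#'   minus the decision cutoff; positive predicts the first level).
#' @param ... unused.
#' @export
predict.plslda_model <- function(object, newdata, type = c("class", "score"),
                                 ...) {
  type <- match.arg(type)
  Tn <- sweep(as.matrix(newdata), 2, object$center) %*% object$pls$R
  s <- drop(Tn %*% object$lda_direction) - object$cutoff
  if (type == "score") return(s)
  factor(ifelse(s > 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}
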