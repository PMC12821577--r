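#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution differences: every sample is divided by
#' the median of its bin-wise quotients against a reference profile
#' (default: the median spectrum over samples). For samples that are
#' exact scalar multiples of one profile this recovers the scale factors
#' exactly (up to one global constant).
#'
#' @param bm a [binned_matrix].
#' @param reference `"median"` (default), `"mean"`, or the index of a
#'   sample to use as the reference profile.
#' @param min_reference smallest reference value for a bin to take part
#'   in the quotients (guards against divisions by ~0).
#' @return The normalized [binned_matrix]; the estimated per-sample
#'   dilution factors (the quotient medians) are attached as element
#'   `dilution_factors`.
#' @export
normalize_quotient <- function(bm, reference = "median",
                               min_reference = .Machine$double.eps) {
  stopifnot(inherits(bm, "binned_matrix"))
  X <- bm$values
  if (any(rowSums(abs(X)) == 0)) stopf("all-zero sample cannot be normalized")
  ref <- switch(as.character(reference[1]),
                median = apply(X, 2, median),
                mean = colMeans(X),
                X[as.integer(reference), ])
  use <- which(ref > min_reference)
  if (!length(use)) stopf("reference profile has no positive bins")
  q <- sweep(X[, use, drop = FALSE], 2, ref[use], `/`)
  f <- apply(q, 1, median)
  if (any(f <= 0)) stopf("non-positive quotient median; check input signs")
  out <- bm
  out$values <- X / f
  out$dilution_factors <- f
  out
}

#' Log-transform and auto-scale a binned matrix
#'
#' Element-wise natural log after adding a small offset (by default half
#' the smallest positive value of each column, which admits zero bins
#' and keeps the transform equivariant to rescaling a column), then
#' per-column centering to mean 0 and scaling to variance 1
#' (auto-scaling), the usual preparation before multivariate modelling.
#'
#' @param bm a [binned_matrix].
#' @param offset scalar added to every entry before the log; `NULL`
#'   (default) selects half the smallest positive entry per column.
#' @param constant_cols what to do with zero-variance columns: `"drop"`
#'   (default), `"zero"` (keep as all-zero columns) or `"error"`.
#' @return The transformed [binned_matrix]; column means/SDs used are
#'   attached as `scaling`.
#' @export
log_autoscale <- function(bm, offset = NULL,
                          constant_cols = c("drop", "zero", "error")) {
  stopifnot(inherits(bm, "binned_matrix"))
  constant_cols <- match.arg(constant_cols)
  X <- bm$values
  if (is.null(offset)) {
    offset <- apply(X, 2, function(v) {
      if (all(v > 0)) 0 else if (any(v > 0)) min(v[v > 0]) / 2 else 1
    })
    Xo <- sweep(X, 2, offset, `+`)
  } else {
    Xo <- X + offset
  }
  if (any(Xo <= 0)) stopf("non-positive entries after offset")
  L <- log(Xo)
  mu <- colMeans(L)
  s <- apply(L, 2, sd)
  const <- s < .Machine$double.eps^0.5
  if (any(const)) {
    if (constant_cols == "error") stopf("constant column(s) cannot be auto-scaled")
    if (constant_cols == "drop") {
      bm <- bm[, !const]
      L <- L[, !const, drop = FALSE]
      mu <- mu[!const]; s <- s[!const]
    } else {
      s[const] <- 1  # centering already maps the column to exact zeros
    }
  }
  out <- bm
  out$values <- sweep(sweep(L, 2, mu), 2, s, `/`)
  out$scaling <- list(offset = offset, center = mu, scale = s)
  out
}
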