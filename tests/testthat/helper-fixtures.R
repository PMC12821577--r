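# Shared fixtures and independent oracle implementations.

# -- tiny panels -------------------------------------------------------

one_singlet_panel <- function(center = 5, conc = 2, width = 0.02) {
  metabolite_panel(
    meta = data.frame(name = "probe", abbreviation = "prb", group_sign = 0,
                      base_concentration = conc, effect_size = 0),
    peaks = data.frame(metabolite = "probe", center_ppm = center,
                       multiplicity = 1, j_hz = 0, width_ppm = width,
                       relative_area = 1))
}

two_singlet_panel <- function(centers = c(3, 7), width = 0.05) {
  metabolite_panel(
    meta = data.frame(name = c("a", "b"), abbreviation = c("a", "b"),
                      group_sign = 0, base_concentration = c(2, 3),
                      effect_size = 0),
    peaks = data.frame(metabolite = c("a", "b"), center_ppm = centers,
                       multiplicity = 1, j_hz = 0, width_ppm = width,
                       relative_area = 1))
}

# Two well-separated Gaussian classes (for separable-limit checks).
separable_data <- function(n1 = 21, n0 = 21, p = 10, gap = 8, seed = 1) {
  withr::local_seed(seed)
  X <- matrix(rnorm((n1 + n0) * p), n1 + n0)
  X[seq_len(n1), 1] <- X[seq_len(n1), 1] + gap
  y <- factor(rep(c("worker", "resident"), c(n1, n0)),
              levels = c("worker", "resident"))
  list(X = X, y = y)
}

# -- independent AI-binning oracle -------------------------------------
# Literal, unoptimized re-implementation used only to cross-check the
# vectorized version: brute force over every candidate split.

oracle_bin_value <- function(I, r) {
  mx <- apply(I, 2, max)
  sum(((mx - I[1, ]) * (mx - I[nrow(I), ]))^r)
}

oracle_splits <- function(I, r, sigma, noise_factor = 2) {
  lambda <- function(m) noise_factor * sum((sigma^2 * 2 * log(m))^r)
  splits <- integer(0)
  rec <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 4) return(invisible())
    cand <- (lo + 1):(hi - 2)
    v1 <- vapply(cand, function(k) oracle_bin_value(I[lo:k, , drop = FALSE], r), 0)
    v2 <- vapply(cand, function(k) oracle_bin_value(I[(k + 1):hi, , drop = FALSE], r), 0)
    best <- which.max(v1 + v2)
    vp <- oracle_bin_value(I[lo:hi, , drop = FALSE], r)
    k <- cand[best]
    if ((v1 + v2)[best] > vp &&
        v1[best] > lambda(k - lo + 1) && v2[best] > lambda(hi - k)) {
      splits[[length(splits) + 1]] <<- k
      rec(lo, k); rec(k + 1, hi)
    }
    invisible()
  }
  rec(1, nrow(I))
  sort(splits)
}

# Splits chosen by the package, recovered from the returned bin edges.
splits_from_edges <- function(bm, ppm) {
  if (nrow(bm$bin_edges) < 2) return(integer(0))
  cuts <- unname(bm$bin_edges[-1, "hi"])
  vapply(cuts, function(cc) max(which(ppm > cc)), 0L)
}

# -- R reference for the rdCV engine -----------------------------------
# Mirrors the compiled engine using the exported fit_plslda/predict
# path, consuming the same fold layout.

ref_choose_A <- function(errs, n_val_avg) {
  m <- colMeans(errs)
  se <- apply(errs, 2, sd) / sqrt(nrow(errs))
  se <- pmax(se, 0.5 / n_val_avg)
  best <- which.min(m)
  min(which(m <= m[best] + se[best]))
}

ref_rdcv <- function(X, y, outer, inner, Amax, ridge = 1e-8) {
  y <- droplevels(as.factor(y))
  y01 <- as.integer(y == levels(y)[1])
  n <- nrow(X)
  reps <- ncol(outer)
  kout <- max(outer)
  kin <- max(inner)
  pred <- matrix(-1L, n, reps)
  Wfold <- matrix(0, reps * kout, ncol(X))
  chosen <- matrix(0L, kout, reps)
  for (r in seq_len(reps)) {
    for (k in seq_len(kout)) {
      te <- which(outer[, r] == k)
      tr <- which(outer[, r] != k)
      errs <- matrix(NA_real_, kin, Amax)
      nval <- 0
      for (j in seq_len(kin)) {
        itr <- tr[inner[tr, k, r] != j]
        ival <- tr[inner[tr, k, r] == j]
        fit <- fit_plslda(X[itr, , drop = FALSE], y[itr], A = Amax,
                          ridge = ridge)
        for (a in seq_len(fit$A)) {
          fa <- fit_plslda(X[itr, , drop = FALSE], y[itr], A = a,
                           ridge = ridge)
          pr <- predict(fa, X[ival, , drop = FALSE])
          errs[j, a] <- mean(pr != y[ival])
        }
        nval <- nval + length(ival)
      }
      A_eff <- max(which(colSums(is.na(errs)) == 0))
      Ak <- ref_choose_A(errs[, seq_len(A_eff), drop = FALSE], nval / kin)
      chosen[k, r] <- Ak
      fit <- fit_plslda(X[tr, , drop = FALSE], y[tr], A = Ak, ridge = ridge)
      pred[te, r] <- as.integer(predict(fit, X[te, , drop = FALSE]) ==
                                  levels(y)[1])
      w <- fit$cv1_weights
      Wfold[(r - 1) * kout + k, ] <- w
    }
  }
  list(pred = pred, weights_fold = Wfold, chosen = chosen)
}
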