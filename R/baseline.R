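#' Baseline correction by asymmetric least squares
#'
#' Estimates a smooth baseline that tracks the lower envelope of each
#' spectrum and subtracts it. The estimate minimizes a weighted least
#' squares criterion with a second-difference roughness penalty
#' (smoothness `lambda`); the weights are iteratively reweighted so
#' points above the baseline (peaks) get weight `p` and points below get
#' `1 - p`. This is a reproducible substitute for proprietary baseline
#' procedures aimed at removing solvent and digitization humps.
#'
#' @param spectra an [nmr_spectra] set (or a single spectrum).
#' @param lambda smoothness penalty; larger gives a stiffer baseline.
#' @param p asymmetry in (0, 1); small values force the baseline under
#'   the peaks.
#' @param maxit number of reweighting iterations.
#' @return An [nmr_spectra] with the baseline removed; the fitted
#'   baselines are attached as the `baseline` element.
#' @export
correct_baseline <- function(spectra, lambda = 1e7, p = 0.001, maxit = 10) {
  stopifnot(inherits(spectra, "nmr_spectra"))
  if (lambda <= 0) stopf("smoothness lambda must be positive")
  if (p <= 0 || p >= 1) stopf("asymmetry p must be in (0, 1)")
  m <- length(spectra$ppm)
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  base <- spectra$intensity
  for (i in seq_len(nrow(base))) {
    y <- spectra$intensity[i, ]
    w <- rep(1, m)
    z <- y
    for (it in seq_len(maxit)) {
      Wm <- Matrix::Diagonal(x = w)
      z <- as.numeric(Matrix::solve(Wm + DtD, w * y))
      wn <- ifelse(y > z, p, 1 - p)
      if (all(wn == w)) break
      w <- wn
    }
    base[i, ] <- z
  }
  out <- nmr_spectra(spectra$ppm, spectra$intensity - base,
                     spectra$sample_ids)
  out$baseline <- base
  out$excluded_regions <- spectra$excluded_regions
  out
}
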