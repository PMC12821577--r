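#' Process a free-induction decay into a spectrum
#'
#' Standard 1D processing chain: exponential apodization with
#' line-broadening `lb_hz` (default 0.3 Hz), zero-filling to the next
#' power of two, Fourier transform, and automatic zero/first-order phase
#' correction by entropy minimization of the real part. The real part of
#' the phased spectrum is returned.
#'
#' @param fid complex time-domain vector (length >= 2).
#' @param sw_hz spectral width (sampling rate) in Hz.
#' @param lb_hz exponential line broadening in Hz.
#' @param sf_mhz spectrometer proton frequency, used to express the axis
#'   in ppm.
#' @param ref_ppm ppm value assigned to the centre of the spectral
#'   window.
#' @param phase if `FALSE`, skip automatic phasing (useful when the FID
#'   is known to be in absorption phase already).
#' @return An [nmr_spectra] with a single spectrum on a descending ppm
#'   axis.
#' @export
process_fid <- function(fid, sw_hz, lb_hz = 0.3, sf_mhz = 600,
                        ref_ppm = 4.7, phase = TRUE) {
  if (length(fid) < 2) stopf("FID must have length >= 2")
  if (!all(is.finite(Re(fid))) || !all(is.finite(Im(fid)))) {
    stopf("non-finite FID")
  }
  n <- length(fid)
  t <- (seq_len(n) - 1) / sw_hz
  fid <- fid * exp(-pi * lb_hz * t)
  nfft <- 2^ceiling(log2(n))
  fid <- c(fid, complex(real = rep(0, nfft - n)))
  spec <- fft(fid)
  # reorder so frequency runs from -sw/2 to +sw/2
  spec <- c(spec[(nfft / 2 + 1):nfft], spec[1:(nfft / 2)])
  freq <- seq(-sw_hz / 2, sw_hz / 2, length.out = nfft + 1)[-(nfft + 1)]
  if (phase && any(Mod(spec) > 0)) {
    spec <- autophase(spec)
  }
  ppm <- ref_ppm + freq / sf_mhz
  nmr_spectra(ppm, Re(spec), sample_ids = "fid")
}

# Zero/first-order phasing by minimizing the entropy of the first
# derivative of the real part, with a penalty on negative intensity
# (Chen-style criterion). Phases in radians; first order is linear
# across the spectrum.
autophase <- function(spec) {
  n <- length(spec)
  x <- seq(-0.5, 0.5, length.out = n)
  obj <- function(phi) {
    re <- Re(spec * exp(1i * (phi[1] + phi[2] * x)))
    d <- abs(diff(re))
    s <- sum(d)
    if (s == 0) return(0)
    p <- d / s
    h <- -sum(p[p > 0] * log(p[p > 0]))
    neg <- re[re < 0]
    h + 1000 * sum(neg^2) / sum(re^2)
  }
  # coarse zero-order grid, then joint refinement
  grid <- seq(-pi, pi, length.out = 25)
  phi0 <- grid[which.min(vapply(grid, function(g) obj(c(g, 0)), 0))]
  fit <- optim(c(phi0, 0), obj, method = "Nelder-Mead",
               control = list(maxit = 400))
  spec * exp(1i * (fit$par[1] + fit$par[2] * x))
}
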