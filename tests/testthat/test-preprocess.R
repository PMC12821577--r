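# FID processing, baseline correction, alignment.

test_that("the FT of a damped complex exponential is a single peak", {
  sw <- 1000
  t <- (0:1023) / sw
  f0 <- 120
  fid <- exp(2i * pi * f0 * t - t / 0.5)
  sp <- process_fid(fid, sw_hz = sw, lb_hz = 0, sf_mhz = 600, phase = FALSE)
  pk_ppm <- sp$ppm[which.max(sp$intensity[1, ])]
  expect_lt(abs((pk_ppm - 4.7) * 600 - f0), sw / 1024)
  expect_gt(max(sp$intensity[1, ]), 10 * stats::median(abs(sp$intensity[1, ])))
})

test_that("0.3 Hz line broadening widens the peak by about 0.3 Hz", {
  sw <- 500
  t <- (0:8191) / sw
  fid <- exp(2i * pi * 60 * t - t / 1.0)   # natural FWHM = 1/(pi*T2) Hz
  fwhm <- function(lb) {
    sp <- process_fid(fid, sw_hz = sw, lb_hz = lb, sf_mhz = 600,
                      phase = FALSE)
    y <- sp$intensity[1, ]
    hz <- sort((sp$ppm - 4.7) * 600)
    y <- rev(y)                       # ascending frequency
    half <- max(y) / 2
    above <- which(y >= half)
    lo <- min(above); hi <- max(above)
    # linear interpolation of the half-height crossings
    left <- hz[lo - 1] + (half - y[lo - 1]) / (y[lo] - y[lo - 1]) *
      (hz[lo] - hz[lo - 1])
    right <- hz[hi] + (half - y[hi]) / (y[hi + 1] - y[hi]) *
      (hz[hi + 1] - hz[hi])
    right - left
  }
  expect_lt(abs(fwhm(0.3) - fwhm(0) - 0.3), 0.05)
})

test_that("a zero FID transforms to a zero spectrum", {
  sp <- process_fid(complex(real = rep(0, 64)), sw_hz = 100)
  expect_true(all(sp$intensity == 0))
  expect_error(process_fid(complex(real = c(NA, 1)), sw_hz = 100),
               "non-finite")
})

test_that("baseline correction is invariant to constant offsets", {
  ppm <- seq(10, 0, length.out = 1024)
  peak <- 50 * dcauchy(ppm, 5, 0.01) * 0.01 * pi
  sp0 <- nmr_spectra(ppm, peak)
  sp1 <- nmr_spectra(ppm, peak + 20)
  c0 <- correct_baseline(sp0)
  c1 <- correct_baseline(sp1)
  expect_lt(max(abs(c1$intensity - c0$intensity)), 0.01 * 20)
  expect_true(all(correct_baseline(nmr_spectra(ppm, rep(0, 1024)))$intensity == 0))
  expect_error(correct_baseline(sp0, lambda = -1), "positive")
})

test_that("slow humps are removed while peak heights survive", {
  ppm <- seq(10, 0, length.out = 2048)
  hump <- 30 * sin(seq(0, pi, length.out = 2048))
  heights <- c(80, 120, 60)
  centers <- c(2.5, 5.0, 7.5)
  peaks <- rowSums(sapply(seq_along(centers), function(i) {
    heights[i] * exp(-((ppm - centers[i]) / 0.02)^2 / 2)
  }))
  corr <- correct_baseline(nmr_spectra(ppm, peaks + hump))
  for (i in seq_along(centers)) {
    got <- max(corr$intensity[1, abs(ppm - centers[i]) < 0.05])
    expect_equal(got, heights[i], tolerance = 0.05)
  }
})

test_that("aligning identical spectra does nothing", {
  ppm <- seq(10, 0, length.out = 1024)
  y <- 100 / (1 + ((ppm - 5) / 0.02)^2) + 10 / (1 + ((ppm - 2) / 0.02)^2)
  sp <- nmr_spectra(ppm, rbind(y, y, y))
  al <- align_spectra(sp, n_segments = 8)
  expect_true(all(al$shifts == 0))
  expect_equal(al$intensity, sp$intensity)
})

test_that("a known within-segment shift is recovered exactly", {
  ppm <- seq(10, 0, length.out = 1024)
  y <- 100 / (1 + ((ppm - 5) / 0.03)^2)
  for (k in c(2L, 5L)) {
    ys <- urinmr:::shift_fill(y, k)
    sp <- nmr_spectra(ppm, rbind(y, ys))
    al <- align_spectra(sp, reference = 1, n_segments = 4,
                        max_shift_ppm = 0.1)
    seg <- which.max(apply(abs(al$shifts), 2, max))
    expect_equal(al$shifts[2, seg], -k)
    # exact recovery up to edge-filled segment borders
    expect_lt(max(abs(al$intensity[2, ] - y)), 0.05)
  }
})

test_that("alignment tightens jittered peak positions across a cohort", {
  d <- cohort_design(n_workers = 6, n_residents = 6,
                     panel = two_singlet_panel(width = 0.03),
                     shift_jitter_sd_ppm = 0.02, noise_sd = 0.05,
                     baseline_amplitude = 0, axis = c(0, 10, 2048), seed = 8)
  co <- simulate_cohort(d)
  peak_sd <- function(sp) {
    pos <- apply(sp$intensity, 1, function(y) {
      idx <- abs(sp$ppm - 3) < 0.3
      sp$ppm[idx][which.max(y[idx])]
    })
    sd(pos)
  }
  al <- align_spectra(co$spectra, n_segments = 10, max_shift_ppm = 0.08)
  expect_lt(peak_sd(al), peak_sd(co$spectra))
})

test_that("alignment rejects segments shorter than the shift window", {
  ppm <- seq(10, 0, length.out = 128)
  sp <- nmr_spectra(ppm, rbind(rnorm(128), rnorm(128)))
  expect_error(align_spectra(sp, n_segments = 30, max_shift_ppm = 1),
               "segment shorter")
})
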