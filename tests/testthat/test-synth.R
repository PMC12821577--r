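test_that("a noiseless singlet peaks at its chemical shift", {
  d <- cohort_design(n_workers = 2, n_residents = 2,
                     panel = one_singlet_panel(center = 5),
                     dilution_log_sd = 0, inter_subject_log_sd = 0,
                     shift_jitter_sd_ppm = 0, noise_sd = 0,
                     baseline_amplitude = 0, axis = c(0, 10, 1024), seed = 1)
  co <- simulate_cohort(d)
  for (i in 1:4) {
    pk <- co$spectra$ppm[which.max(co$spectra$intensity[i, ])]
    expect_lt(abs(pk - 5), 10 / 1024)  # within one pixel
  }
})

test_that("asymmetric panels land on the correct side of the axis", {
  # two singlets of different size: the taller one must appear at ITS
  # shift, not at the mirrored position
  d <- cohort_design(n_workers = 2, n_residents = 2,
                     panel = two_singlet_panel(centers = c(3, 7)),
                     dilution_log_sd = 0, inter_subject_log_sd = 0,
                     shift_jitter_sd_ppm = 0, noise_sd = 0,
                     baseline_amplitude = 0, axis = c(0, 10, 1024), seed = 1)
  co <- simulate_cohort(d)
  at <- function(p) co$spectra$intensity[1, which.min(abs(co$spectra$ppm - p))]
  expect_gt(at(7), at(3))          # concentration 3 vs 2
  expect_gt(at(3), 100 * at(5))    # and nothing at the mirror-free midpoint
})

test_that("identical designs and seeds give bit-identical cohorts", {
  d <- cohort_design(n_workers = 3, n_residents = 3, axis = c(-0.2, 10, 512),
                     seed = 11)
  c1 <- simulate_cohort(d)
  c2 <- simulate_cohort(d)
  expect_identical(c1$spectra$intensity, c2$spectra$intensity)
  expect_identical(c1$truth, c2$truth)
  d2 <- cohort_design(n_workers = 3, n_residents = 3, axis = c(-0.2, 10, 512),
                      seed = 12)
  expect_false(identical(simulate_cohort(d2)$spectra$intensity,
                         c1$spectra$intensity))
})

test_that("noiseless spectra conserve the planted total area", {
  d <- cohort_design(n_workers = 3, n_residents = 3,
                     panel = default_panel(),
                     shift_jitter_sd_ppm = 0.002, noise_sd = 0,
                     baseline_amplitude = 0, axis = c(-0.2, 10, 2048),
                     seed = 4)
  co <- simulate_cohort(d)
  dx <- abs(diff(co$spectra$ppm[1:2]))
  areas <- tapply(urinmr:::panel_lines(d$panel)$area,
                  urinmr:::panel_lines(d$panel)$metabolite, sum)
  areas <- areas[colnames(co$truth$concentrations)]
  for (i in seq_len(6)) {
    planted <- sum(areas * co$truth$concentrations[i, ]) *
      co$truth$dilution[i]
    expect_equal(sum(co$spectra$intensity[i, ]) * dx, planted,
                 tolerance = 1e-6)
  }
})

test_that("covariates reproduce the cohort's demographic contrasts", {
  ok_age <- ok_smoke <- logical(100)
  for (s in 1:100) {
    d <- cohort_design(panel = one_singlet_panel(), seed = s)
    cv <- urinmr:::with_seed(d$seed, urinmr:::simulate_covariates(d))
    w <- seq_len(64); r <- 65:142
    ok_age[s] <- mean(cv$age[r]) > mean(cv$age[w])
    ok_smoke[s] <- mean(cv$smoker[w]) > mean(cv$smoker[r])
  }
  expect_true(all(ok_age))
  expect_true(all(ok_smoke))
})

test_that("a planted log-fold change of 1 is detected with high power", {
  # Monte-Carlo power of a two-sample t-test on the integrated peak area
  # of a single discriminant metabolite, 40 vs 40 subjects
  panel <- one_singlet_panel(center = 5)
  panel$meta$group_sign <- 1
  panel$meta$effect_size <- 1
  rejected <- vapply(1:200, function(s) {
    d <- cohort_design(n_workers = 40, n_residents = 40, panel = panel,
                       axis = c(0, 10, 512), seed = 1000 + s)
    bm <- cohort_to_binned(d, bin_width_ppm = 10)   # one bin = whole axis
    area <- bm$values[, 1] / bm$dilution
    t.test(area[bm$labels == "worker"], area[bm$labels == "resident"])$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.9)
})

test_that("binned fast path is exact for a single metabolite", {
  d <- cohort_design(n_workers = 2, n_residents = 2,
                     panel = one_singlet_panel(center = 5, conc = 2),
                     axis = c(0, 10, 512), seed = 2)
  bm <- cohort_to_binned(d, bin_width_ppm = 10)
  expect_equal(ncol(bm$values), 1)
  # column equals concentration x dilution exactly
  d0 <- cohort_design(n_workers = 2, n_residents = 2,
                      panel = one_singlet_panel(center = 5, conc = 2),
                      dilution_log_sd = 0.3, inter_subject_log_sd = 0,
                      axis = c(0, 10, 512), seed = 3)
  b0 <- cohort_to_binned(d0, bin_width_ppm = 10)
  expect_equal(unname(b0$values[, 1]), 2 * b0$dilution, tolerance = 1e-12)
  expect_error(cohort_to_binned(d0, bin_width_ppm = 11), "exceeds")
})

test_that("bin ground truth is aligned with the bin edges", {
  d <- cohort_design(panel = two_singlet_panel(centers = c(3, 7)), seed = 6)
  bm <- cohort_to_binned(d, bin_width_ppm = 0.1)
  ctr <- rowMeans(bm$bin_edges)
  i3 <- which.min(abs(ctr - 3))
  i7 <- which.min(abs(ctr - 7))
  expect_match(bm$truth$metabolites[i3], "^a$")
  expect_match(bm$truth$metabolites[i7], "^b$")
  # the singlet bins dominate their columns
  expect_gt(mean(bm$values[, i3]), 10 * median(bm$values[, -c(i3, i7)]))
})

test_that("null panels give equal group means in expectation", {
  d <- cohort_design(panel = null_panel(5), seed = 9)
  bm <- cohort_to_binned(d, bin_width_ppm = 0.05)
  sel <- !is.na(bm$truth$planted_sign)
  p <- apply(bm$values[, sel, drop = FALSE], 2, function(v) {
    t.test(log(v[bm$labels == "worker"]), log(v[bm$labels == "resident"]))$p.value
  })
  expect_gt(min(p), 1e-4)   # no column shows a strong spurious difference
})

test_that("cohorts round-trip through plain-text files", {
  d <- cohort_design(n_workers = 3, n_residents = 3, axis = c(-0.2, 10, 256),
                     seed = 21)
  co <- simulate_cohort(d)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$spectra$intensity, co$spectra$intensity,
               tolerance = 1e-12)
  expect_equal(back$labels, co$labels)
  expect_equal(back$truth$dilution, co$truth$dilution, tolerance = 1e-12)
})
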