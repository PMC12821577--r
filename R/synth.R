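#' Cohort design for urine-NMR simulation
#'
#' Collects every parameter of the synthetic-cohort generator. Defaults
#' reproduce the structure of a typical occupational-exposure study: 64
#' exposed workers versus 78 residents, a 27-metabolite discriminant
#' panel, log-normal urinary dilution, small chemical-shift jitter,
#' smooth baseline drift and additive Gaussian noise.
#'
#' @param n_workers,n_residents group sizes (each >= 2).
#' @param panel a [metabolite_panel]; default [default_panel()].
#' @param dilution_log_sd SD of per-sample log dilution factors; urine
#'   concentration varies strongly between voids, the default 0.4 gives
#'   roughly a 2.2-fold interquartile dilution range.
#' @param inter_subject_log_sd SD of per-subject log concentration around
#'   the group mean (biological variability).
#' @param shift_jitter_sd_ppm SD of the per-sample, per-multiplet
#'   chemical-shift jitter (pH/ionic-strength effects).
#' @param noise_sd SD of additive Gaussian noise per point.
#' @param baseline_amplitude scale of the smooth random baseline drift.
#' @param axis `c(ppm_min, ppm_max, n_points)` of the digitized axis
#'   (`n_points >= 256`).
#' @param covariate_model per-group covariate distributions, see
#'   [default_covariate_model()].
#' @param confounded if `TRUE`, smoking also shifts three microbial
#'   co-metabolites (hippurate, p-cresol sulfate, phenylacetylglycine) by
#'   +0.3 log units, providing a negative control for the confounder
#'   screen. Default `FALSE`: covariates have no causal link to spectra.
#' @param seed integer seed making the cohort reproducible.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_workers = 64, n_residents = 78,
                          panel = default_panel(),
                          dilution_log_sd = 0.4,
                          inter_subject_log_sd = 0.4,
                          shift_jitter_sd_ppm = 0.0025,
                          noise_sd = 1,
                          baseline_amplitude = 15,
                          axis = c(-0.2, 10, 4096),
                          covariate_model = default_covariate_model(),
                          confounded = FALSE,
                          seed = NULL) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (n_workers < 2 || n_residents < 2) stopf("group sizes must be >= 2")
  if (axis[3] < 256) stopf("n_points must be >= 256")
  if (min(dilution_log_sd, inter_subject_log_sd, shift_jitter_sd_ppm,
          noise_sd, baseline_amplitude) < 0) {
    stopf("all dispersion parameters must be >= 0")
  }
  lines <- panel_lines(panel)
  if (any(lines$center_ppm < axis[1] | lines$center_ppm > axis[2])) {
    stopf("panel peaks fall outside the ppm axis")
  }
  structure(list(n_workers = n_workers, n_residents = n_residents,
                 panel = panel, dilution_log_sd = dilution_log_sd,
                 inter_subject_log_sd = inter_subject_log_sd,
                 shift_jitter_sd_ppm = shift_jitter_sd_ppm,
                 noise_sd = noise_sd,
                 baseline_amplitude = baseline_amplitude,
                 axis = axis, covariate_model = covariate_model,
                 confounded = confounded, seed = seed),
            class = "cohort_design")
}

#' Default per-group covariate model
#'
#' Age is normal, sex/smoking/alcohol are Bernoulli, BMI is normal
#' truncated to the observed range; the parameters mirror the enrolled
#' worker/resident cohorts (workers younger and smoking more, residents
#' older; sex, alcohol and BMI nearly homogeneous).
#'
#' @return A named list with one parameter list per group.
#' @export
default_covariate_model <- function() {
  list(
    worker = list(age_mean = 47, age_sd = 8, p_male = 38 / 64,
                  p_smoker = 24 / 64, p_alcohol = 44 / 64,
                  bmi_mean = 24.4, bmi_sd = 2.6, bmi_range = c(18.4, 31.2)),
    resident = list(age_mean = 57, age_sd = 10, p_male = 41 / 78,
                    p_smoker = 7 / 78, p_alcohol = 58 / 78,
                    bmi_mean = 25.0, bmi_sd = 3.4, bmi_range = c(18.4, 39.4))
  )
}

rtruncnorm1 <- function(n, mean, sd, range) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < range[1] | x[bad] > range[2]]
  }
  x
}

simulate_covariates <- function(design) {
  cm <- design$covariate_model
  one <- function(n, p) {
    data.frame(age = rnorm(n, p$age_mean, p$age_sd),
               sex = ifelse(rbinom(n, 1, p$p_male) == 1, "M", "F"),
               smoker = rbinom(n, 1, p$p_smoker) == 1,
               alcohol = rbinom(n, 1, p$p_alcohol) == 1,
               bmi = rtruncnorm1(n, p$bmi_mean, p$bmi_sd, p$bmi_range))
  }
  rbind(one(design$n_workers, cm$worker), one(design$n_residents, cm$resident))
}

# Fraction of a unit-area Lorentzian (HWHM gamma, center c) in [a, b].
lorentz_frac <- function(a, b, c, gamma) {
  (atan((b - c) / gamma) - atan((a - c) / gamma)) / pi
}

# Distribute the unit area of one line over contiguous intervals given by
# `breaks` (ascending), renormalized so the whole axis carries exactly 1.
line_bin_fractions <- function(breaks, center, gamma) {
  cdf <- atan((breaks - center) / gamma)
  f <- diff(cdf)
  f / (cdf[length(cdf)] - cdf[1])
}

#' Simulate a two-group urine-NMR cohort
#'
#' Draws per-subject metabolite concentrations (log-normal around group
#' means separated by each metabolite's effect size), per-sample dilution
#' factors, chemical-shift jitter, smooth baseline drift and additive
#' noise, and renders each spectrum as a sum of pixel-integrated
#' Lorentzian multiplets. Pixel integration conserves the planted total
#' area exactly: the Riemann sum of a noiseless spectrum equals the sum
#' of `area x concentration x dilution` over all lines.
#'
#' @param design a [cohort_design].
#' @return A list of class `nmr_cohort` with elements `spectra`
#'   ([nmr_spectra]), `labels` (factor, `worker`/`resident`),
#'   `covariates` (data.frame) and `truth` (list: `dilution`,
#'   `concentrations`, `design`).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    n <- design$n_workers + design$n_residents
    labels <- factor(rep(c("worker", "resident"),
                         c(design$n_workers, design$n_residents)),
                     levels = c("worker", "resident"))
    covs <- simulate_covariates(design)
    meta <- design$panel$meta
    gdir <- ifelse(labels == "worker", 0.5, -0.5)
    logc <- matrix(rnorm(n * nrow(meta), 0, design$inter_subject_log_sd), n)
    logc <- sweep(logc, 2, log(meta$base_concentration), `+`) +
      outer(gdir, meta$group_sign * meta$effect_size)
    if (design$confounded) {
      conf <- meta$name %in% c("Hippurate", "p-Cresol sulfate",
                               "Phenylacetylglycine")
      logc[covs$smoker, conf] <- logc[covs$smoker, conf] + 0.3
    }
    conc <- exp(logc)
    colnames(conc) <- meta$name
    dil <- exp(rnorm(n, 0, design$dilution_log_sd))

    np <- design$axis[3]
    breaks <- seq(design$axis[1], design$axis[2], length.out = np + 1)
    dx <- diff(breaks[1:2])
    centers <- (breaks[-1] + breaks[-(np + 1)]) / 2
    lines <- panel_lines(design$panel)
    # jitter is drawn per sample per multiplet peak row, shared by the
    # lines of one multiplet
    pk <- design$panel$peaks
    pk_of_line <- rep(seq_len(nrow(pk)), times = pmax(1L, pk$multiplicity))
    met_idx <- match(lines$metabolite, meta$name)
    intens <- matrix(0, n, np)
    half_window <- max(0.25, 500 * max(lines$width_ppm) / 2)
    for (i in seq_len(n)) {
      jit <- rnorm(nrow(pk), 0, design$shift_jitter_sd_ppm)
      spec <- numeric(np)
      for (l in seq_len(nrow(lines))) {
        c0 <- lines$center_ppm[l] + jit[pk_of_line[l]]
        gamma <- lines$width_ppm[l] / 2
        lo <- max(1L, findInterval(c0 - half_window, breaks))
        hi <- min(np, findInterval(c0 + half_window, breaks) + 1L)
        fr <- line_bin_fractions(breaks[lo:(hi + 1)], c0, gamma)
        amp <- lines$area[l] * conc[i, met_idx[l]] * dil[i]
        spec[lo:hi] <- spec[lo:hi] + amp * fr / dx
      }
      if (design$baseline_amplitude > 0) {
        u <- seq(0, 1, length.out = np)
        spec <- spec + design$baseline_amplitude *
          (rnorm(1, 0, 0.5) * sin(2 * pi * (runif(1, 0.5, 1.5) * u + runif(1))) +
             rnorm(1, 0, 0.5) * u + rnorm(1, 0, 0.5))
      }
      if (design$noise_sd > 0) spec <- spec + rnorm(np, 0, design$noise_sd)
      intens[i, ] <- spec
    }
    spectra <- nmr_spectra(centers, intens)  # constructor flips to descending
    structure(list(spectra = spectra, labels = labels, covariates = covs,
                   truth = list(dilution = dil, concentrations = conc,
                                design = design)),
              class = "nmr_cohort")
  })
}

#' @exportS3Method base::print
print.nmr_cohort <- function(x, ...) {
  cat(sprintf("<nmr_cohort> %d workers + %d residents, %d points\n",
              sum(x$labels == "worker"), sum(x$labels == "resident"),
              length(x$spectra$ppm)))
  invisible(x)
}

#' Noise-free uniformly binned matrix straight from a design
#'
#' Fast path for statistical testing: skips spectrum rendering and
#' preprocessing, and integrates each metabolite's Lorentzian lines
#' analytically over a uniform bin grid. Bin values are exact
#' `concentration x dilution` contributions (no jitter, baseline or
#' noise). Every bin is annotated with its ground truth: the planted
#' group sign of the metabolites contributing to it.
#'
#' @param design a [cohort_design].
#' @param bin_width_ppm uniform bin width; must not exceed the axis span.
#' @param truth_threshold minimum share of a bin's expected signal for a
#'   metabolite to count as a contributor when assigning ground truth.
#' @param drop_empty drop bins with no signal at all (default `TRUE`).
#' @param min_signal_frac detection floor: drop bins whose expected
#'   signal is below this fraction of the strongest bin's. The default 0
#'   keeps every bin; a small positive value (e.g. 0.01) mimics real
#'   spectra, where far-from-peak bins contain only noise and Lorentzian
#'   tails are not measurable.
#' @return A [binned_matrix]; its `truth` element is a data.frame with
#'   one row per bin: `planted_sign` (+1, -1, 0, or NA for bins mixing
#'   signs) and `metabolites` (comma-separated contributors).
#' @export
cohort_to_binned <- function(design, bin_width_ppm = 0.02,
                             truth_threshold = 0.01, drop_empty = TRUE,
                             min_signal_frac = 0) {
  stopifnot(inherits(design, "cohort_design"))
  span <- design$axis[2] - design$axis[1]
  if (bin_width_ppm > span) stopf("bin width exceeds the axis span")
  with_seed(design$seed, {
    n <- design$n_workers + design$n_residents
    labels <- factor(rep(c("worker", "resident"),
                         c(design$n_workers, design$n_residents)),
                     levels = c("worker", "resident"))
    covs <- simulate_covariates(design)
    meta <- design$panel$meta
    gdir <- ifelse(labels == "worker", 0.5, -0.5)
    logc <- matrix(rnorm(n * nrow(meta), 0, design$inter_subject_log_sd), n)
    logc <- sweep(logc, 2, log(meta$base_concentration), `+`) +
      outer(gdir, meta$group_sign * meta$effect_size)
    conc <- exp(logc)
    dil <- exp(rnorm(n, 0, design$dilution_log_sd))

    breaks <- seq(design$axis[1], design$axis[2], by = bin_width_ppm)
    if (breaks[length(breaks)] < design$axis[2]) {
      breaks <- c(breaks, design$axis[2])
    }
    nb <- length(breaks) - 1
    lines <- panel_lines(design$panel)
    met_idx <- match(lines$metabolite, meta$name)
    # unit contribution of each metabolite to each bin (per unit concentration)
    U <- matrix(0, nb, nrow(meta))
    for (l in seq_len(nrow(lines))) {
      fr <- line_bin_fractions(breaks, lines$center_ppm[l],
                               lines$width_ppm[l] / 2)
      U[, met_idx[l]] <- U[, met_idx[l]] + lines$area[l] * fr
    }
    values <- (conc %*% t(U)) * dil
    expected <- meta$base_concentration * t(U)      # metabolites x bins
    share <- sweep(t(expected), 1, pmax(colSums(expected), .Machine$double.eps),
                   `/`)                              # bins x metabolites
    truth <- data.frame(planted_sign = NA_real_,
                        metabolites = character(nb),
                        expected_signal = colSums(expected))
    for (b in seq_len(nb)) {
      contrib <- which(share[b, ] >= truth_threshold)
      if (!length(contrib) || sum(expected[contrib, b]) == 0) {
        truth$planted_sign[b] <- NA
        truth$metabolites[b] <- ""
        next
      }
      sgns <- unique(meta$group_sign[contrib])
      truth$planted_sign[b] <- if (length(sgns) == 1) sgns else NA  # NA = mixed
      truth$metabolites[b] <- paste(meta$name[contrib], collapse = ",")
    }
    # binned_matrix orders bins by descending ppm; reorder the truth
    # table the same way before attaching it
    ord <- order(breaks[-1], decreasing = TRUE)
    bm <- binned_matrix(values,
                        bin_edges = cbind(hi = breaks[-1], lo = breaks[-(nb + 1)]),
                        sample_ids = sprintf("S%03d", seq_len(n)))
    truth <- truth[ord, , drop = FALSE]
    rownames(truth) <- NULL
    keep <- if (drop_empty) colSums(bm$values) > 0 else rep(TRUE, nb)
    if (min_signal_frac > 0) {
      keep <- keep & truth$expected_signal >=
        min_signal_frac * max(truth$expected_signal)
    }
    bm <- bm[, keep]
    bm$truth <- truth[keep, , drop = FALSE]
    bm$labels <- labels
    bm$covariates <- covs
    bm$dilution <- dil
    bm
  })
}

#' Write / read a cohort to a directory of plain-text files
#'
#' Spectra go to `spectra.tsv` (ppm + one column per sample), labels and
#' covariates to `samples.csv`, ground truth to `truth.json`.
#'
#' @param cohort an `nmr_cohort` from [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns
#'   an `nmr_cohort` (design in truth is not round-tripped).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra_tsv(cohort$spectra, file.path(dir, "spectra.tsv"))
  samples <- cbind(sample_id = cohort$spectra$sample_ids,
                   label = as.character(cohort$labels), cohort$covariates)
  utils::write.csv(samples, file.path(dir, "samples.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(dilution = cohort$truth$dilution,
         concentrations = as.data.frame(cohort$truth$concentrations)),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  spectra <- read_spectra_tsv(file.path(dir, "spectra.tsv"))
  samples <- utils::read.csv(file.path(dir, "samples.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(spectra = spectra,
                 labels = factor(samples$label,
                                 levels = c("worker", "resident")),
                 covariates = samples[, setdiff(names(samples),
                                                c("sample_id", "label"))],
                 truth = list(dilution = truth$dilution,
                              concentrations = as.matrix(truth$concentrations))),
            class = "nmr_cohort")
}
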