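#' Metabolite panel for cohort simulation
#'
#' A panel describes the metabolites that make up a simulated urine
#' spectrum: for each metabolite a set of Lorentzian multiplets
#' (chemical shift, multiplicity, J coupling, linewidth, relative area),
#' a base concentration, the group in which it is elevated
#' (`group_sign`: +1 exposed/workers, -1 residents, 0 non-discriminant)
#' and a log-fold-change effect size between groups.
#'
#' @param meta data.frame with columns `name`, `abbreviation`,
#'   `group_sign`, `base_concentration`, `effect_size`.
#' @param peaks data.frame with columns `metabolite`, `center_ppm`,
#'   `multiplicity`, `j_hz`, `width_ppm`, `relative_area`.
#' @param spectrometer_mhz proton frequency used to convert J couplings
#'   from Hz to ppm.
#' @return An object of class `metabolite_panel`.
#' @export
metabolite_panel <- function(meta, peaks, spectrometer_mhz = 600) {
  meta <- as.data.frame(meta)
  peaks <- as.data.frame(peaks)
  need_m <- c("name", "group_sign", "base_concentration", "effect_size")
  need_p <- c("metabolite", "center_ppm", "multiplicity", "j_hz",
              "width_ppm", "relative_area")
  if (!all(need_m %in% names(meta))) stopf("panel meta lacks required columns")
  if (!all(need_p %in% names(peaks))) stopf("panel peaks lack required columns")
  if (!all(peaks$metabolite %in% meta$name)) {
    stopf("peaks reference unknown metabolites")
  }
  if (any(peaks$width_ppm <= 0)) stopf("peak widths must be > 0")
  if (any(peaks$relative_area <= 0)) stopf("relative areas must be > 0")
  if (any(meta$base_concentration <= 0)) stopf("base concentrations must be > 0")
  if (!all(meta$group_sign %in% c(-1, 0, 1))) stopf("group_sign must be -1, 0 or +1")
  # a null effect means a non-discriminant metabolite, whatever the sign says
  meta$group_sign[meta$effect_size == 0] <- 0
  meta$effect_size[meta$group_sign == 0] <- 0
  structure(list(meta = meta, peaks = peaks,
                 spectrometer_mhz = spectrometer_mhz),
            class = "metabolite_panel")
}

#' @exportS3Method base::print
print.metabolite_panel <- function(x, ...) {
  cat(sprintf(paste0("<metabolite_panel> %d metabolites (%d worker-assoc.,",
                     " %d resident-assoc., %d null), %d peaks\n"),
              nrow(x$meta), sum(x$meta$group_sign == 1),
              sum(x$meta$group_sign == -1), sum(x$meta$group_sign == 0),
              nrow(x$peaks)))
  invisible(x)
}

#' Default 27-metabolite discriminant panel
#'
#' Loads the panel shipped with the package: 27 urinary metabolites with
#' a group association (9 elevated in the exposed/worker group, 18 in
#' the resident group) typical of an occupational-exposure urinary
#' fingerprinting study; chemical shifts and multiplicities are
#' plausible literature values stored in an editable YAML file
#' (`system.file("extdata", "metabolite_panel.yaml", package = "urinmr")`).
#'
#' @param effect_size log-fold-change applied to every discriminant
#'   metabolite (with its `group_sign`). `0` turns the panel into a null
#'   panel (all signs forced to 0).
#' @param config optional path to an alternative YAML panel description.
#' @return A [metabolite_panel].
#' @export
default_panel <- function(effect_size = 0.35, config = NULL) {
  config <- config %||% system.file("extdata", "metabolite_panel.yaml",
                                    package = "urinmr")
  y <- yaml::read_yaml(config)
  meta <- do.call(rbind, lapply(y$metabolites, function(m) {
    data.frame(name = m$name,
               abbreviation = m$abbreviation %||% m$name,
               group_sign = m$group_sign,
               base_concentration = m$base_concentration,
               effect_size = abs(effect_size))
  }))
  peaks <- do.call(rbind, lapply(y$metabolites, function(m) {
    do.call(rbind, lapply(m$peaks, function(p) {
      data.frame(metabolite = m$name, center_ppm = p$center_ppm,
                 multiplicity = p$multiplicity, j_hz = p$j_hz,
                 width_ppm = p$width_ppm, relative_area = p$relative_area)
    }))
  }))
  metabolite_panel(meta, peaks, spectrometer_mhz = y$spectrometer_mhz %||% 600)
}

#' Panel of non-discriminant filler metabolites
#'
#' Generates `n` synthetic singlet metabolites with `group_sign = 0`,
#' evenly spread over `region`, used to plant known null variables when
#' testing variable selection. Names are `null_01`, `null_02`, ...
#'
#' @param n number of null metabolites.
#' @param region length-2 ppm interval over which the singlets are spread.
#' @param base_concentration concentration of each null metabolite.
#' @param width_ppm Lorentzian full width at half maximum.
#' @return A [metabolite_panel] with `n` entries.
#' @export
null_panel <- function(n, region = c(5.0, 6.6), base_concentration = 1,
                       width_ppm = 0.002) {
  centers <- seq(min(region), max(region), length.out = n)
  names <- sprintf("null_%02d", seq_len(n))
  meta <- data.frame(name = names, abbreviation = names, group_sign = 0,
                     base_concentration = base_concentration, effect_size = 0)
  peaks <- data.frame(metabolite = names, center_ppm = centers,
                      multiplicity = 1, j_hz = 0, width_ppm = width_ppm,
                      relative_area = 1)
  metabolite_panel(meta, peaks)
}

#' Concatenate metabolite panels
#'
#' @param ... [metabolite_panel] objects with distinct metabolite names.
#' @return A combined [metabolite_panel].
#' @export
combine_panels <- function(...) {
  ps <- list(...)
  meta <- do.call(rbind, lapply(ps, `[[`, "meta"))
  if (anyDuplicated(meta$name)) stopf("duplicate metabolite names across panels")
  metabolite_panel(meta, do.call(rbind, lapply(ps, `[[`, "peaks")),
                   spectrometer_mhz = ps[[1]]$spectrometer_mhz)
}

# Expand every multiplet of the panel into individual Lorentzian lines.
# Returns a data.frame: metabolite, center_ppm, width_ppm, area (relative
# within the metabolite; binomial weights across multiplet lines sum to 1
# so the multiplet keeps its total relative_area).
panel_lines <- function(panel) {
  sf <- panel$spectrometer_mhz
  out <- lapply(seq_len(nrow(panel$peaks)), function(i) {
    p <- panel$peaks[i, ]
    m <- max(1L, as.integer(p$multiplicity))
    wts <- choose(m - 1, 0:(m - 1)) / 2^(m - 1)
    offs <- ((0:(m - 1)) - (m - 1) / 2) * p$j_hz / sf
    data.frame(metabolite = p$metabolite,
               center_ppm = p$center_ppm + offs,
               width_ppm = p$width_ppm,
               area = p$relative_area * wts)
  })
  do.call(rbind, out)
}
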