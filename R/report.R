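#' Summarize significant variables as a metabolite table
#'
#' Maps each significant bin to a metabolite name through an annotation
#' of ppm ranges and tabulates, per metabolite, the weight sign and the
#' associated group — the usual end-product table of a discriminant
#' metabolomics analysis. Bins not covered by the annotation are
#' reported as `"unknown"`.
#'
#' @param selection a `variable_selection` from [select_variables()].
#' @param bin_edges two-column matrix of (hi, lo) ppm edges matching the
#'   selection rows; taken from `attr(selection, "bin_edges")` if absent.
#' @param annotation data.frame with columns `metabolite`, `ppm_hi`,
#'   `ppm_lo` (a bin is annotated when its centre falls in the range),
#'   or `NULL` for no annotation. See [panel_annotation()].
#' @return Data.frame with columns `metabolite`, `weight_sign`
#'   (`"+"`/`"-"`), `group`.
#' @export
make_metabolite_table <- function(selection, bin_edges = NULL,
                                  annotation = NULL) {
  stopifnot(inherits(selection, "variable_selection"))
  sel <- selection[selection$significant, , drop = FALSE]
  if (!nrow(sel)) {
    return(data.frame(metabolite = character(), weight_sign = character(),
                      group = character()))
  }
  idx <- which(selection$significant)
  name <- rep("unknown", length(idx))
  if (!is.null(annotation) && !is.null(bin_edges)) {
    ctr <- rowMeans(bin_edges[idx, , drop = FALSE])
    for (i in seq_along(idx)) {
      hit <- which(annotation$ppm_hi >= ctr[i] & annotation$ppm_lo <= ctr[i])
      if (length(hit)) name[i] <- annotation$metabolite[hit[1]]
    }
  } else {
    name <- sel$variable
  }
  out <- data.frame(metabolite = name,
                    weight_sign = ifelse(sel$mean_weight > 0, "+", "-"),
                    group = as.character(sel$group))
  # one row per metabolite; keep the sign of the strongest bin
  ord <- order(-abs(sel$mean_weight))
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out$metabolite) | out$metabolite == "unknown", ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ppm-range annotation derived from a metabolite panel
#'
#' Builds the bin-to-metabolite annotation used by
#' [make_metabolite_table()] from the known line positions of a
#' simulation panel.
#'
#' @param panel a [metabolite_panel].
#' @param tol_ppm half-width added around every line.
#' @return Data.frame with `metabolite`, `ppm_hi`, `ppm_lo`.
#' @export
panel_annotation <- function(panel, tol_ppm = 0.02) {
  lines <- panel_lines(panel)
  data.frame(metabolite = lines$metabolite,
             ppm_hi = lines$center_ppm + tol_ppm,
             ppm_lo = lines$center_ppm - tol_ppm)
}

#' Export score-plot data as tidy CSV files
#'
#' Writes plot-ready coordinate tables: the PCoA embedding (with
#' explained-variance axis labels and group/covariate columns) and the
#' PLS-LDA discriminant scores with per-sample stability categories.
#'
#' @param dir output directory.
#' @param pcoa_result a `pcoa_result`, or `NULL`.
#' @param discriminant_scores numeric vector of PLS-LDA scores, or
#'   `NULL`.
#' @param labels group labels.
#' @param stability factor from [sample_stability()], optional.
#' @param covariates optional covariate data.frame bound to both files.
#' @return Invisibly, the paths written.
#' @export
export_scoreplots <- function(dir, pcoa_result = NULL,
                              discriminant_scores = NULL, labels = NULL,
                              stability = NULL, covariates = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(pcoa_result)) {
    df <- as.data.frame(pcoa_result$coordinates)
    names(df) <- sprintf("%s_%.1fpct", names(df), pcoa_result$explained_pct)
    if (!is.null(labels)) df$group <- as.character(labels)
    if (!is.null(covariates)) df <- cbind(df, covariates)
    p <- file.path(dir, "pcoa_scores.csv")
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(discriminant_scores)) {
    df <- data.frame(score = discriminant_scores)
    if (!is.null(labels)) df$group <- as.character(labels)
    if (!is.null(stability)) df$stability <- as.character(stability)
    if (!is.null(covariates)) df <- cbind(df, covariates)
    p <- file.path(dir, "plslda_scores.csv")
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Provenance snapshot of an analysis run
#'
#' Collects the configuration, seeds and per-stage parameters of a run
#' so every reported number is traceable; reports regenerated from the
#' same snapshot are byte-identical (the timestamp lives only in the
#' snapshot itself, never in derived report files).
#'
#' @param ... named per-stage parameter lists.
#' @param seed master seed of the run.
#' @return List of class `run_provenance`.
#' @export
run_provenance <- function(..., seed = NULL) {
  structure(list(package_version = as.character(utils::packageVersion("urinmr")),
                 r_version = R.version.string,
                 timestamp = format(Sys.time(), tz = "UTC"),
                 seed = seed,
                 stages = list(...)),
            class = "run_provenance")
}

#' @exportS3Method base::print
print.run_provenance <- function(x, ...) {
  cat(sprintf("<run_provenance> urinmr %s, seed %s, %d stage(s)\n",
              x$package_version, x$seed %||% "none", length(x$stages)))
  invisible(x)
}

#' Write a provenance snapshot as JSON
#'
#' @param prov a `run_provenance`.
#' @param path output file.
#' @export
write_provenance <- function(prov, path) {
  jsonlite::write_json(unclass(prov), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: simulate (or read) a cohort, preprocess spectra
#' (baseline correction, alignment, adaptive binning, exclusion of
#' water/reference regions, quotient normalization, log +
#' auto-scaling), compute the URF dissimilarity with PCoA and the
#' confounder screen, validate a PLS-LDA model by repeated double
#' cross-validation with a permutation test, and select sign-stable
#' discriminant variables. All stage outputs and a provenance snapshot
#' are written to `out_dir` as plain text.
#'
#' @param config named list (or path to a YAML file) overriding any of
#'   the stage parameter defaults; see the `pipeline_defaults()` for the
#'   recognised fields.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return List with every stage result.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  design <- cohort_design(
    n_workers = cfg$n_workers, n_residents = cfg$n_residents,
    panel = default_panel(effect_size = cfg$effect_size),
    dilution_log_sd = cfg$dilution_log_sd,
    inter_subject_log_sd = cfg$inter_subject_log_sd,
    shift_jitter_sd_ppm = cfg$shift_jitter_sd_ppm,
    noise_sd = cfg$noise_sd, baseline_amplitude = cfg$baseline_amplitude,
    axis = unlist(cfg$axis), seed = cfg$seed)
  cohort <- simulate_cohort(design)

  spec <- correct_baseline(cohort$spectra, lambda = cfg$baseline_lambda,
                           p = cfg$baseline_asymmetry)
  spec <- align_spectra(spec, max_shift_ppm = cfg$max_shift_ppm,
                        n_segments = cfg$n_segments)
  bm <- ai_binning(spec, r = cfg$binning_r,
                   noise_region = unlist(cfg$noise_region))
  bm <- exclude_regions(bm, cfg$excluded_regions %||%
                          default_excluded_regions())
  bm$values[bm$values < 0] <- 0
  bm <- normalize_quotient(bm)
  bmz <- log_autoscale(bm)

  urf_seed <- child_seed(cfg$seed, 1)
  D <- urf_dissimilarity(bmz, n_iterations = cfg$urf_iterations,
                         n_trees = cfg$urf_trees,
                         min_leaf = cfg$urf_min_leaf, seed = urf_seed)
  emb <- pcoa(D, k = 4)
  screen <- confounder_screen(D, cohort$covariates,
                              n_perm = cfg$confounder_permutations,
                              seed = child_seed(cfg$seed, 2))

  rcfg <- rdcv_config(n_outer_folds = cfg$n_outer_folds,
                      n_inner_folds = cfg$n_inner_folds,
                      n_repetitions = cfg$n_repetitions,
                      max_components = cfg$max_components,
                      n_permutations = cfg$n_permutations,
                      perm_repetitions = cfg$perm_repetitions,
                      seed = child_seed(cfg$seed, 3))
  fit <- rdcv(bmz$values, cohort$labels, rcfg)
  perm <- permutation_test(bmz$values, cohort$labels, rcfg)
  sel <- select_variables(fit)
  stab <- sample_stability(fit)
  final <- fit_plslda(bmz$values, cohort$labels,
                      A = round(mean(fit$chosen_components[fit$chosen_components > 0])))
  tab <- make_metabolite_table(sel, bin_edges = bmz$bin_edges,
                               annotation = panel_annotation(design$panel))
  prov <- run_provenance(config = cfg, seed = cfg$seed)

  res <- list(cohort = cohort, binned = bmz, dissimilarity = D, pcoa = emb,
              confounders = screen, rdcv = fit, permutation = perm,
              selection = sel, stability = stab,
              metabolite_table = tab, provenance = prov)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_binned_csv(bmz, file.path(out_dir, "binned.csv"),
                     provenance = cfg)
    utils::write.csv(fit$summary, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(sel, file.path(out_dir, "variable_selection.csv"),
                     row.names = FALSE)
    utils::write.csv(tab, file.path(out_dir, "metabolite_table.csv"),
                     row.names = FALSE)
    utils::write.csv(screen, file.path(out_dir, "confounder_screen.csv"),
                     row.names = FALSE)
    export_scoreplots(out_dir, pcoa_result = emb,
                      discriminant_scores = predict(final, bmz$values,
                                                    type = "score"),
                      labels = cohort$labels, stability = stab)
    write_provenance(prov, file.path(out_dir, "provenance.json"))
  }
  res
}

#' @rdname run_pipeline
#' @export
pipeline_defaults <- function() {
  list(n_workers = 64, n_residents = 78, effect_size = 0.35,
       dilution_log_sd = 0.4, inter_subject_log_sd = 0.4,
       shift_jitter_sd_ppm = 0.0025, noise_sd = 1, baseline_amplitude = 15,
       axis = c(-0.2, 10, 4096), baseline_lambda = 1e7,
       baseline_asymmetry = 0.001, max_shift_ppm = 0.02, n_segments = 40,
       binning_r = 0.5, noise_region = c(9.5, 10),
       excluded_regions = NULL,
       urf_iterations = 50, urf_trees = 1500, urf_min_leaf = 8,
       confounder_permutations = 999,
       n_outer_folds = 7, n_inner_folds = 6, n_repetitions = 50,
       max_components = 10, n_permutations = 1000, perm_repetitions = 5,
       seed = 1)
}
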