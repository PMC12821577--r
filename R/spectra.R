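#' Spectrum set container
#'
#' A set of 1D NMR spectra sharing a common chemical-shift axis. The axis
#' is stored in descending ppm order (the plotting convention for NMR);
#' intensities are held as a samples-by-points matrix so that whole-set
#' operations (alignment, binning, group means) are vectorized.
#'
#' @param ppm numeric chemical-shift axis; reordered to descending if
#'   needed.
#' @param intensity numeric matrix, one row per sample, `length(ppm)`
#'   columns. A single spectrum may be given as a vector.
#' @param sample_ids character vector of sample identifiers.
#' @return An object of class `nmr_spectra`: a list with elements `ppm`,
#'   `intensity` and `sample_ids`.
#' @export
nmr_spectra <- function(ppm, intensity, sample_ids = NULL) {
  if (is.vector(intensity)) intensity <- matrix(intensity, nrow = 1)
  intensity <- as.matrix(intensity)
  ppm <- as.numeric(ppm)
  if (length(ppm) != ncol(intensity)) {
    stopf("length(ppm) [%d] != ncol(intensity) [%d]", length(ppm), ncol(intensity))
  }
  if (anyNA(ppm) || is.unsorted(rev(ppm)) && is.unsorted(ppm)) {
    stopf("ppm axis must be monotone")
  }
  if (!all(is.finite(intensity))) stopf("intensities must be finite")
  if (ppm[1] < ppm[length(ppm)]) {   # ascending input: flip to NMR convention
    ppm <- rev(ppm)
    intensity <- intensity[, rev(seq_along(ppm)), drop = FALSE]
  }
  sample_ids <- sample_ids %||% rownames(intensity) %||%
    sprintf("S%03d", seq_len(nrow(intensity)))
  rownames(intensity) <- sample_ids
  structure(list(ppm = ppm, intensity = intensity,
                 sample_ids = as.character(sample_ids)),
            class = "nmr_spectra")
}

#' @exportS3Method base::print
print.nmr_spectra <- function(x, ...) {
  cat(sprintf("<nmr_spectra> %d spectra, %d points, %.3f..%.3f ppm\n",
              nrow(x$intensity), length(x$ppm),
              min(x$ppm), max(x$ppm)))
  invisible(x)
}

n_spectra <- function(x) nrow(x$intensity)

#' Per-group mean spectra
#'
#' Point-wise arithmetic mean of the spectra in each group, a standard
#' way of displaying a representative profile per cohort arm.
#'
#' @param spectra an [nmr_spectra] set.
#' @param groups vector of group labels, one per sample. Defaults to a
#'   single group.
#' @return An [nmr_spectra] object with one row per group, sample ids set
#'   to the group labels.
#' @export
mean_spectrum <- function(spectra, groups = NULL) {
  stopifnot(inherits(spectra, "nmr_spectra"))
  groups <- groups %||% rep("all", n_spectra(spectra))
  if (length(groups) != n_spectra(spectra)) {
    stopf("groups must have one label per spectrum")
  }
  levs <- unique(as.character(groups))
  means <- t(vapply(levs, function(g) {
    idx <- which(groups == g)
    if (!length(idx)) stopf("empty group '%s'", g)
    colMeans(spectra$intensity[idx, , drop = FALSE])
  }, numeric(length(spectra$ppm))))
  nmr_spectra(spectra$ppm, means, sample_ids = levs)
}

#' Remove chemical-shift regions from spectra or a binned matrix
#'
#' Drops the points (for spectra) or the bins (for a binned matrix) that
#' intersect the given ppm intervals, recording them as excluded. The
#' usual application is removal of the residual water resonance and of
#' the chemical-shift reference singlet before statistical analysis.
#'
#' @param x an [nmr_spectra] or [binned_matrix] object.
#' @param regions numeric matrix or list of length-2 vectors of ppm
#'   intervals (order within a pair is irrelevant). The defaults cover
#'   residual water (4.7-4.9 ppm) and the TSP reference (-0.05-0.05 ppm).
#' @param allow_empty if `FALSE` (default), an error is raised when the
#'   exclusion would remove every point or bin.
#' @return An object of the same class with the regions removed; the
#'   intervals are accumulated in the `excluded_regions` element.
#' @export
exclude_regions <- function(x, regions = default_excluded_regions(),
                            allow_empty = FALSE) {
  UseMethod("exclude_regions")
}

#' @export
#' @rdname exclude_regions
default_excluded_regions <- function() {
  list(water = c(4.7, 4.9), reference = c(-0.05, 0.05))
}

as_region_matrix <- function(regions) {
  if (is.null(regions) || !length(regions)) {
    return(matrix(numeric(0), ncol = 2))
  }
  if (is.list(regions)) regions <- do.call(rbind, regions)
  regions <- matrix(as.numeric(regions), ncol = 2)
  t(apply(regions, 1, sort))
}

in_any_region <- function(ppm, regions) {
  hit <- rep(FALSE, length(ppm))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (ppm >= regions[i, 1] & ppm <= regions[i, 2])
  }
  hit
}

#' @export
exclude_regions.nmr_spectra <- function(x, regions = default_excluded_regions(),
                                        allow_empty = FALSE) {
  regions <- as_region_matrix(regions)
  if (!nrow(regions)) return(x)
  drop <- in_any_region(x$ppm, regions)
  if (all(drop) && !allow_empty) stopf("exclusion regions cover the whole axis")
  out <- nmr_spectra(x$ppm[!drop], x$intensity[, !drop, drop = FALSE],
                     x$sample_ids)
  out$excluded_regions <- rbind(x$excluded_regions, regions)
  out
}

#' Write / read a spectrum set as TSV
#'
#' The on-disk format is a plain TSV whose first column is the ppm axis
#' and remaining columns are one intensity trace per sample (column names
#' are the sample ids).
#'
#' @param spectra an [nmr_spectra] set.
#' @param path file path.
#' @return `write_spectra_tsv` returns `path` invisibly;
#'   `read_spectra_tsv` returns an [nmr_spectra].
#' @export
write_spectra_tsv <- function(spectra, path) {
  stopifnot(inherits(spectra, "nmr_spectra"))
  df <- data.frame(ppm = spectra$ppm, t(spectra$intensity),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_tsv
#' @export
read_spectra_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  nmr_spectra(df[[1]], t(as.matrix(df[, -1, drop = FALSE])),
              sample_ids = colnames(df)[-1])
}
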