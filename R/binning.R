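#' Binned spectral matrix
#'
#' Samples-by-bins matrix of integrated spectral intensities together
#' with the ppm edges of each bin. Bins are ordered along the descending
#' ppm axis and labelled by their `(hi, lo)` edges, half-open on the low
#' side.
#'
#' @param values numeric matrix, samples x bins.
#' @param bin_edges two-column matrix `(hi, lo)` of ppm edges, one row
#'   per bin.
#' @param sample_ids character sample identifiers.
#' @param excluded_regions optional matrix of ppm intervals removed from
#'   the axis.
#' @return An object of class `binned_matrix`.
#' @export
binned_matrix <- function(values, bin_edges, sample_ids = NULL,
                          excluded_regions = NULL) {
  values <- as.matrix(values)
  bin_edges <- matrix(as.numeric(as.matrix(bin_edges)), ncol = 2,
                      dimnames = list(NULL, c("hi", "lo")))
  bin_edges <- t(apply(bin_edges, 1, function(e) sort(e, decreasing = TRUE)))
  colnames(bin_edges) <- c("hi", "lo")
  if (nrow(bin_edges) != ncol(values)) {
    stopf("one bin edge pair per column required")
  }
  ord <- order(bin_edges[, "hi"], decreasing = TRUE)
  bin_edges <- bin_edges[ord, , drop = FALSE]
  values <- values[, ord, drop = FALSE]
  if (nrow(bin_edges) > 1 &&
      any(bin_edges[-1, "hi"] > bin_edges[-nrow(bin_edges), "lo"] + 1e-9)) {
    stopf("bins overlap")
  }
  sample_ids <- sample_ids %||% rownames(values) %||%
    sprintf("S%03d", seq_len(nrow(values)))
  rownames(values) <- sample_ids
  colnames(values) <- sprintf("%.4f_%.4f", bin_edges[, "hi"], bin_edges[, "lo"])
  structure(list(values = values, bin_edges = bin_edges,
                 sample_ids = as.character(sample_ids),
                 excluded_regions = excluded_regions),
            class = "binned_matrix")
}

#' @exportS3Method base::print
print.binned_matrix <- function(x, ...) {
  cat(sprintf("<binned_matrix> %d samples x %d bins (%.3f..%.3f ppm)\n",
              nrow(x$values), ncol(x$values),
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' @export
`[.binned_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  out <- x
  out$values <- x$values[i, j, drop = FALSE]
  out$bin_edges <- x$bin_edges[j, , drop = FALSE]
  out$sample_ids <- x$sample_ids[i]
  for (f in intersect(c("labels", "covariates", "dilution"), names(x))) {
    out[[f]] <- if (is.data.frame(x[[f]])) x[[f]][i, , drop = FALSE] else x[[f]][i]
  }
  if (!is.null(x$truth)) out$truth <- x$truth[j, , drop = FALSE]
  out
}

#' @export
dim.binned_matrix <- function(x) dim(x$values)

# Bin value index: for one bin, sum over samples of
# ((max - I_start)(max - I_end))^r. `I` is points x samples.
bin_value_index <- function(I, r) {
  mx <- apply(I, 2, max)
  sum(((mx - I[1, ]) * (mx - I[nrow(I), ]))^r)
}

# Best split of the points in columns `lo:hi` (indices into the point
# axis). Returns list(split, v1, v2, vsum) where `split` is the last
# point index of the left sub-bin, or NULL when the bin cannot be split.
# Vectorized over candidates via cumulative maxima.
best_split <- function(I, r) {
  m <- nrow(I)
  if (m < 4) return(NULL)
  # prefix/suffix running maxima per sample
  pre <- apply(I, 2, cummax)
  suf <- apply(I[m:1, , drop = FALSE], 2, cummax)[m:1, , drop = FALSE]
  first <- matrix(I[1, ], m, ncol(I), byrow = TRUE)
  last <- matrix(I[m, ], m, ncol(I), byrow = TRUE)
  # candidate split after point k (left = 1..k, right = k+1..m), k = 2..m-2
  ks <- 2:(m - 2)
  v1 <- rowSums(((pre - first) * (pre - I))^r)[ks]
  # right bin k+1..m: max is suf[k+1,], start intensity I[k+1,]
  v2 <- rowSums(((suf - I) * (suf - last))^r)[ks + 1]
  vsum <- v1 + v2
  best <- which.max(vsum)
  list(split = ks[best], v1 = v1[best], v2 = v2[best], vsum = vsum[best])
}

#' Adaptive intelligent binning
#'
#' Data-driven bin boundaries by recursive bisection. Every candidate
#' split of a bin is scored with the bin value index (the magnitude of
#' end-to-maximum intensity differences raised to the resolution
#' exponent `r`, summed over samples); the best split is accepted only
#' when (i) the summed value of the two sub-bins exceeds the parent
#' bin's value and (ii) both sub-bins individually exceed a noise
#' threshold estimated from a signal-free region. Accepted splits are
#' refined recursively, so the final bins track multiplets instead of a
#' fixed grid. Bin integrals are trapezoidal areas per sample.
#'
#' @param spectra an aligned [nmr_spectra] set.
#' @param r resolution exponent in (0, 1]; 0.5 is the usual choice.
#' @param noise_region length-2 ppm interval containing no signal,
#'   used to calibrate the noise threshold.
#' @param noise_factor safety multiplier on the noise-region bin value.
#' @return A [binned_matrix] of trapezoidal bin areas.
#' @export
ai_binning <- function(spectra, r = 0.5, noise_region = c(9.5, 10),
                       noise_factor = 2) {
  stopifnot(inherits(spectra, "nmr_spectra"))
  if (!n_spectra(spectra)) stopf("empty spectra set")
  ppm <- spectra$ppm                       # descending
  noise_region <- sort(noise_region)
  in_noise <- ppm >= noise_region[1] & ppm <= noise_region[2]
  if (sum(in_noise) < 4) stopf("noise_region outside axis or too narrow")
  I <- t(spectra$intensity)                # points x samples, descending ppm
  # noise threshold: expected bin value of an m-point pure-noise bin
  # (extreme-value scaling of the running maximum), times a safety factor
  sigma <- apply(I[in_noise, , drop = FALSE], 2, sd)
  v_noise <- function(m) noise_factor * sum((sigma^2 * 2 * log(m))^r)

  m <- nrow(I)
  splits <- integer(0)
  recurse <- function(lo, hi) {
    bs <- best_split(I[lo:hi, , drop = FALSE], r)
    if (is.null(bs)) return(invisible())
    vp <- bin_value_index(I[lo:hi, , drop = FALSE], r)
    m1 <- bs$split; m2 <- (hi - lo + 1) - bs$split
    if (bs$vsum > vp && bs$v1 > v_noise(m1) && bs$v2 > v_noise(m2)) {
      cut <- lo + bs$split - 1
      splits[[length(splits) + 1]] <<- cut
      recurse(lo, cut)
      recurse(cut + 1, hi)
    }
    invisible()
  }
  recurse(1, m)
  bounds <- sort(unique(c(0, splits, m)))   # point index of last point per bin
  nb <- length(bounds) - 1
  values <- matrix(0, ncol(I), nb)
  edges <- matrix(0, nb, 2)
  for (b in seq_len(nb)) {
    idx <- (bounds[b] + 1):bounds[b + 1]
    seg <- I[idx, , drop = FALSE]
    if (length(idx) > 1) {
      w <- abs(diff(ppm[idx]))
      values[, b] <- colSums((seg[-1, , drop = FALSE] +
                                seg[-nrow(seg), , drop = FALSE]) / 2 * w)
    }
  }
  # boundaries at midpoints between adjacent points, so the bins
  # partition the retained axis exactly
  cuts <- c(ppm[1],
            if (nb > 1) (ppm[bounds[2:nb]] + ppm[bounds[2:nb] + 1]) / 2,
            ppm[m])
  edges <- cbind(cuts[-(nb + 1)], cuts[-1])
  binned_matrix(values, edges, sample_ids = spectra$sample_ids,
                excluded_regions = spectra$excluded_regions)
}

#' @export
exclude_regions.binned_matrix <- function(x, regions = default_excluded_regions(),
                                          allow_empty = FALSE) {
  regions <- as_region_matrix(regions)
  if (!nrow(regions)) return(x)
  drop <- rep(FALSE, ncol(x$values))
  for (i in seq_len(nrow(regions))) {
    drop <- drop | (x$bin_edges[, "hi"] > regions[i, 1] &
                      x$bin_edges[, "lo"] < regions[i, 2])
  }
  if (all(drop) && !allow_empty) stopf("exclusion regions cover every bin")
  out <- x[, !drop]
  out$excluded_regions <- rbind(x$excluded_regions, regions)
  out
}

#' Write / read a binned matrix as CSV plus a JSON sidecar
#'
#' The CSV holds the samples-by-bins values (first column `sample_id`);
#' the sidecar `<path>.json` stores bin edges, excluded regions and any
#' provenance parameters supplied.
#'
#' @param bm a [binned_matrix].
#' @param path CSV file path.
#' @param provenance optional named list of processing parameters to log.
#' @export
write_binned_csv <- function(bm, path, provenance = NULL) {
  stopifnot(inherits(bm, "binned_matrix"))
  df <- data.frame(sample_id = bm$sample_ids, bm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(bin_edges = unname(as.matrix(bm$bin_edges)),
               excluded_regions = bm$excluded_regions,
               provenance = provenance)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_binned_csv
#' @export
read_binned_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  binned_matrix(as.matrix(df[, -1, drop = FALSE]),
                bin_edges = side$bin_edges, sample_ids = df[[1]],
                excluded_regions = side$excluded_regions)
}

#' Read an externally supplied binned-intensity table
#'
#' Accepts a samples-by-bins CSV or TSV in the common supplementary-data
#' layout: first column sample identifiers, remaining column names
#' carrying the bin position in ppm (e.g. `7.8350` or `7.8350_7.8100`).
#' When column names are single positions, nominal edges are derived
#' from midpoints between neighbours.
#'
#' @param path CSV/TSV file.
#' @param sep field separator; guessed from the extension by default.
#' @return A [binned_matrix].
#' @export
read_binned_table <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  nm <- colnames(vals)
  if (all(grepl("_", nm))) {
    edges <- do.call(rbind, lapply(strsplit(nm, "_"), as.numeric))
  } else {
    pos <- suppressWarnings(as.numeric(gsub("[^0-9.eE+-]", "", nm)))
    if (anyNA(pos)) stopf("cannot parse bin positions from column names")
    ord <- order(pos, decreasing = TRUE)
    pos <- pos[ord]; vals <- vals[, ord, drop = FALSE]
    mid <- (pos[-1] + pos[-length(pos)]) / 2
    d1 <- if (length(pos) > 1) pos[1] + (pos[1] - mid[1]) else pos[1] + 0.01
    dn <- if (length(pos) > 1) pos[length(pos)] -
      (mid[length(mid)] - pos[length(pos)]) else pos[1] - 0.01
    edges <- cbind(c(d1, mid), c(mid, dn))
  }
  binned_matrix(vals, edges, sample_ids = ids)
}
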