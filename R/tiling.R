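# Site-level filtering / PCA matrix construction and aggregation of CpG
# counts into fixed-width non-overlapping windows.

#' Build the common-site methylation matrix
#'
#' Retains exactly the CpG sites covered at `min_coverage` or more reads in
#' every sample and returns their methylation proportions as a sites x
#' samples matrix. This is the input for sample-level PCA.
#'
#' @param per_sample_records Named list, one CpG record table
#'   (see [read_bismark_coverage()]) per sample.
#' @param min_coverage Minimum per-sample read coverage for a site to be
#'   retained (default 10).
#' @return A list of class `meth_matrix`: `sites` (data.table chrom/pos),
#'   `samples` (character), `rates` (numeric matrix, sites x samples).
#' @export
filter_common_sites <- function(per_sample_records, min_coverage = 10L) {
  stopifnot(min_coverage >= 1L)
  if (length(per_sample_records) == 0L) stop("no samples supplied")
  samples <- names(per_sample_records)
  if (is.null(samples) || any(samples == "")) {
    stop("per_sample_records must be a named list")
  }
  long <- data.table::rbindlist(per_sample_records, idcol = "sample_id")
  long <- long[long$n_meth + long$n_unmeth >= min_coverage]
  key <- paste(long$chrom, long$pos, sep = ":")
  tab <- table(key)
  common <- names(tab)[tab == length(samples)]
  if (length(common) == 0L) {
    warning("no site passes the coverage filter in every sample")
    return(structure(list(sites = data.table::data.table(chrom = character(),
                                                         pos = integer()),
                          samples = samples,
                          rates = matrix(numeric(), 0L, length(samples),
                                         dimnames = list(NULL, samples))),
                     class = "meth_matrix"))
  }
  long <- long[key %in% common]
  long$rate <- long$n_meth / (long$n_meth + long$n_unmeth)
  wide <- data.table::dcast(long, chrom + pos ~ sample_id,
                            value.var = "rate")
  data.table::setorderv(wide, c("chrom", "pos"))
  rates <- as.matrix(wide[, samples, with = FALSE])
  structure(list(sites = wide[, c("chrom", "pos")], samples = samples,
                 rates = rates),
            class = "meth_matrix")
}

#' Principal component analysis of samples
#'
#' PCA on the common-site methylation matrix with samples as observations and
#' sites as variables. Sites are centered but not scaled: proportions share a
#' common scale, and unit-variance scaling would inflate near-constant sites.
#'
#' @param matrix A `meth_matrix` from [filter_common_sites()].
#' @param n_components Number of components to return (default 2).
#' @return List with `scores` (samples x components matrix) and
#'   `explained_variance` (fractions, non-increasing).
#' @export
pca_samples <- function(matrix, n_components = 2L) {
  rates <- matrix$rates
  if (ncol(rates) < 2L || nrow(rates) < 2L) {
    stop("PCA needs at least 2 samples and 2 sites")
  }
  x <- t(rates)  # samples as rows
  if (all(apply(x, 2L, stats::var) < .Machine$double.eps)) {
    stop("degenerate input: zero-variance methylation matrix")
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  ev <- fit$sdev^2
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       explained_variance = (ev / sum(ev))[seq_len(k)])
}

#' Aggregate CpG counts into non-overlapping windows
#'
#' Tiles each chromosome into `window_size`-bp windows anchored at coordinate
#' 0 and pools methylated/unmethylated counts over the CpGs each window
#' contains, per sample. A CpG at 1-based position p falls in window index
#' `floor((p - 1) / window_size)`. A window is retained only if every sample
#' has at least `min_window_coverage` summed reads and at least `min_cpgs`
#' covered CpGs in it.
#'
#' @param per_sample_records Named list of CpG record tables.
#' @param window_size Window width in bp (default 1000).
#' @param min_window_coverage Minimum summed coverage per sample per window
#'   (default 10).
#' @param min_cpgs Minimum covered CpGs per sample per window (default 3).
#' @return A list of class `window_counts`: `windows` (data.table with chrom,
#'   start, end in 0-based half-open coordinates), `samples`, and integer
#'   matrices `n_meth`, `n_unmeth`, `n_cpgs` (windows x samples).
#' @export
tile_and_aggregate <- function(per_sample_records, window_size = 1000L,
                               min_window_coverage = 10L, min_cpgs = 3L) {
  stopifnot(window_size >= 1L)
  if (length(per_sample_records) == 0L) stop("no samples supplied")
  samples <- names(per_sample_records)
  long <- data.table::rbindlist(per_sample_records, idcol = "sample_id")
  long$win <- (long$pos - 1L) %/% as.integer(window_size)
  n_meth <- n_unmeth <- NULL  # NSE guard
  agg <- long[, list(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth),
                     n_cpgs = sum(n_meth + n_unmeth > 0L)),
              by = c("chrom", "win", "sample_id")]
  wm <- data.table::dcast(agg, chrom + win ~ sample_id,
                          value.var = c("n_meth", "n_unmeth", "n_cpgs"),
                          fill = 0L)
  data.table::setorderv(wm, c("chrom", "win"))
  m_meth <- as.matrix(wm[, paste0("n_meth_", samples), with = FALSE])
  m_unmeth <- as.matrix(wm[, paste0("n_unmeth_", samples), with = FALSE])
  m_cpgs <- as.matrix(wm[, paste0("n_cpgs_", samples), with = FALSE])
  colnames(m_meth) <- colnames(m_unmeth) <- colnames(m_cpgs) <- samples
  keep <- rowSums((m_meth + m_unmeth >= min_window_coverage) &
                    (m_cpgs >= min_cpgs)) == length(samples)
  windows <- data.table::data.table(
    chrom = wm$chrom[keep],
    start = wm$win[keep] * as.integer(window_size),
    end = (wm$win[keep] + 1L) * as.integer(window_size))
  structure(list(windows = windows, samples = samples,
                 n_meth = m_meth[keep, , drop = FALSE],
                 n_unmeth = m_unmeth[keep, , drop = FALSE],
                 n_cpgs = m_cpgs[keep, , drop = FALSE]),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat("window_counts: ", nrow(x$windows), " windows x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("meth_matrix: ", nrow(x$rates), " sites x ", length(x$samples),
      " samples\n", sep = "")
  invisible(x)
}
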