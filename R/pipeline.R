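# Orchestration: run the per-tissue differential-methylation analysis and
# the cross-tissue comparison from a single configuration, writing every
# reported number to a TSV artifact under one run directory.

#' Build a run configuration
#'
#' @param coverage_dir Directory holding `<sample_id>.cov` Bismark coverage
#'   files.
#' @param metadata Path to the sample metadata TSV.
#' @param annotation Path to the gene annotation (GTF), or NULL to skip
#'   feature annotation.
#' @param out_dir Output directory for result artifacts.
#' @param window_size,min_site_coverage,min_window_coverage,min_cpgs Tiling
#'   parameters (see [tile_and_aggregate()] and [filter_common_sites()]).
#' @param q_max,min_abs_diff DMR thresholds (see [call_dmrs()]).
#' @param correction `"slim"` or `"bh"`.
#' @param covariates Metadata columns to adjust for (default `"run"`).
#' @param promoter_bp Promoter width for annotation (default 3000).
#' @param perm_reps,seed Permutation-test parameters.
#' @param ct_table Optional path to a qPCR Ct table.
#' @param reference_gene qPCR normalizer gene (default `"GAPDH"`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(coverage_dir, metadata, annotation = NULL,
                       out_dir = "dmrshare_run", window_size = 1000L,
                       min_site_coverage = 10L, min_window_coverage = 10L,
                       min_cpgs = 3L, q_max = 0.05, min_abs_diff = 10,
                       correction = c("slim", "bh"), covariates = "run",
                       promoter_bp = 3000L, perm_reps = 1000L, seed = 1L,
                       ct_table = NULL, reference_gene = "GAPDH") {
  correction <- match.arg(correction)
  cfg <- as.list(environment())
  for (p in c("coverage_dir", "metadata")) {
    if (!file.exists(cfg[[p]])) stop(p, " does not exist: ", cfg[[p]])
  }
  if (!is.null(annotation) && !file.exists(annotation)) {
    stop("annotation does not exist: ", annotation)
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (p in c("coverage_dir", "metadata", "annotation", "ct_table",
              "out_dir")) {
    if (!is.null(raw[[p]]) && !grepl("^/", raw[[p]])) {
      raw[[p]] <- file.path(base, raw[[p]])
    }
  }
  do.call(run_config, raw)
}

#' Per-tissue differential-methylation analysis
#'
#' Reads the tissue's coverage files, builds the 10x common-site matrix and
#' sample PCA, aggregates counts into windows, tests every window, applies
#' the DMR thresholds, and (when an annotation is configured) annotates the
#' passing DMRs. All tables are written under `out_dir/<tissue>/`.
#'
#' @param config A [run_config()].
#' @param tissue Tissue name present in the metadata.
#' @return List: `calls`, `annotated` (passing DMRs with features), `pca`,
#'   `n_windows_tested`, `n_pass`, `meta`.
#' @export
run_tissue_analysis <- function(config, tissue) {
  stopifnot(inherits(config, "run_config"))
  meta <- read_sample_metadata(config$metadata)
  keep_tissue <- tissue  # avoid data.table scoping onto the tissue column
  meta <- meta[meta$tissue == keep_tissue, ]
  if (nrow(meta) == 0L) stop("no samples for tissue '", tissue, "'")
  for (g in c("young", "old")) {
    if (sum(meta$age_group == g) < 2L) {
      stop("need at least 2 '", g, "' samples in tissue '", tissue, "'")
    }
  }
  tdir <- file.path(config$out_dir, tissue)
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  log_info("tissue=%s samples=%d window_size=%d q_max=%g min_abs_diff=%g",
           tissue, nrow(meta), config$window_size, config$q_max,
           config$min_abs_diff)
  records <- lapply(meta$sample_id, function(s) {
    f <- file.path(config$coverage_dir, paste0(s, ".cov"))
    if (!file.exists(f)) stop("coverage file missing for sample ", s)
    read_bismark_coverage(f)
  })
  names(records) <- meta$sample_id

  mm <- filter_common_sites(records, config$min_site_coverage)
  pca <- if (nrow(mm$rates) >= 2L) pca_samples(mm, 2L) else NULL
  if (!is.null(pca)) {
    data.table::fwrite(
      data.table::data.table(sample_id = rownames(pca$scores),
                             pca$scores),
      file.path(tdir, "pca_scores.tsv"), sep = "\t")
  }

  wc <- tile_and_aggregate(records, config$window_size,
                           config$min_window_coverage, config$min_cpgs)
  res <- test_windows(wc, meta, covariates = config$covariates,
                      correction = config$correction)
  calls <- call_dmrs(res, config$q_max, config$min_abs_diff)
  data.table::fwrite(calls, file.path(tdir, "window_tests.tsv"),
                     sep = "\t")
  pass <- calls[calls$pass == TRUE]
  write_dmr_bed(pass, file.path(tdir, "dmrs.bed"))
  annotated <- NULL
  if (!is.null(config$annotation)) {
    genes <- read_gene_annotation(config$annotation, "gtf")
    idx <- build_feature_index(genes, config$promoter_bp)
    annotated <- annotate_dmrs(pass, idx)
    data.table::fwrite(annotated, file.path(tdir, "dmrs_annotated.tsv"),
                       sep = "\t")
  }
  log_info("tissue=%s tested=%d pass=%d", tissue, nrow(calls), nrow(pass))
  list(calls = calls, annotated = annotated, pca = pca,
       n_windows_tested = nrow(calls), n_pass = nrow(pass), meta = meta)
}

#' Cross-tissue shared-DMR analysis
#'
#' Matches passing DMRs of two per-tissue results by window and direction,
#' runs the permutation significance test (selected-region counts and
#' hyper/hypo splits taken from the observed calls; universe = union of both
#' tissues' tested window grids), and lists the shared DMRs located in
#' promoters with their genes.
#'
#' @param config A [run_config()].
#' @param res_a,res_b Results of [run_tissue_analysis()] for the two tissues.
#' @return List: `shared` (`shared_dmr_set`), `perm` (`permutation_null`),
#'   `promoter_shared` (data.table of promoter-located shared DMRs with
#'   gene ids), `universe_size`.
#' @export
run_cross_tissue <- function(config, res_a, res_b) {
  stopifnot(inherits(config, "run_config"))
  ca <- res_a$calls; cb <- res_b$calls
  key_a <- paste(ca$chrom, ca$start); key_b <- paste(cb$chrom, cb$start)
  universe <- length(union(key_a, key_b))
  shared <- find_shared_dmrs(ca, cb)
  pa <- ca[ca$pass == TRUE]; pb <- cb[cb$pass == TRUE]
  perm <- permutation_test(
    universe_size = universe,
    n_a = nrow(pa), n_b = nrow(pb),
    split_a = c(sum(pa$direction == "hyper"), sum(pa$direction == "hypo")),
    split_b = c(sum(pb$direction == "hyper"), sum(pb$direction == "hypo")),
    observed = shared$n_shared_total,
    reps = config$perm_reps, seed = config$seed)
  promoter_shared <- NULL
  if (!is.null(config$annotation)) {
    genes <- read_gene_annotation(config$annotation, "gtf")
    idx <- build_feature_index(genes, config$promoter_bp)
    ann <- annotate_dmrs(shared$shared, idx)
    promoter_shared <- ann[grepl("promoter", ann$features), ]
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(shared$shared,
                     file.path(config$out_dir, "shared_dmrs.tsv"),
                     sep = "\t")
  data.table::fwrite(
    data.table::data.table(rep = seq_along(perm$null_counts),
                           null_count = perm$null_counts),
    file.path(config$out_dir, "permutation_null.tsv"), sep = "\t")
  if (!is.null(promoter_shared)) {
    data.table::fwrite(promoter_shared,
                       file.path(config$out_dir,
                                 "promoter_shared_dmrs.tsv"), sep = "\t")
  }
  log_info("shared=%d (hyper=%d hypo=%d) perm_p=%g universe=%d",
           shared$n_shared_total, shared$n_shared_hyper,
           shared$n_shared_hypo, perm$p_value, universe)
  list(shared = shared, perm = perm, promoter_shared = promoter_shared,
       universe_size = universe)
}

#' qPCR expression analysis for every target gene in a Ct table
#'
#' @param config A [run_config()] with `ct_table` set.
#' @return `data.table`: gene, mean fold change in the old group, t, df,
#'   two-tailed p.
#' @export
run_expression <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$ct_table)) stop("config has no ct_table")
  ct <- read_ct_table(config$ct_table)
  targets <- setdiff(unique(ct$gene), config$reference_gene)
  rows <- lapply(targets, function(g) {
    dd <- delta_delta_ct(ct, g, config$reference_gene)
    tt <- group_ttest(ct, g, config$reference_gene)
    old_fold <- dd$group_summary$mean_fold[dd$group_summary$group == "old"]
    data.table::data.table(gene = g, mean_fold_old = old_fold,
                           t = tt$t, df = tt$df, p_value = tt$p_value)
  })
  out <- data.table::rbindlist(rows)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(out, file.path(config$out_dir, "expression.tsv"),
                     sep = "\t")
  out[]
}

log_info <- function(fmt, ...) {
  message(sprintf(paste0("[dmrshare] ", fmt), ...))
}
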