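# Small configurations keep the generator tests fast; statistical claims use
# the invariants the sampler guarantees by construction.

small_cfg <- function(seed = 1, n_windows = 400, ...) {
  sim_config(seed = seed, n_windows = n_windows, dmr_fraction = 0.05,
             shared_fraction = 0.25, shared_promoter_count = 2L,
             n_background_genes = 4L, ...)
}

test_that("identical seeds give byte-identical output files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_experiment(small_cfg(seed = 33), d1)
  simulate_experiment(small_cfg(seed = 33), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("planted counts, truth consistency, round-trip of emitted files", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(seed = 5)
  sim <- simulate_experiment(cfg, d)
  n_planted <- floor(cfg$dmr_fraction * cfg$n_windows)
  truth <- sim$truth
  expect_equal(sum(truth$tissue == "hippocampus"), n_planted)
  expect_equal(sum(truth$tissue == "blood"), n_planted)
  # shared windows appear in both tissues' truth with equal direction
  sh <- truth[truth$shared == TRUE]
  key <- paste(sh$chrom, sh$start, sh$direction)
  expect_equal(sum(duplicated(key)), nrow(sh) / 2)
  # emitted coverage files round-trip through coverage_io
  covs <- list.files(file.path(d, "coverage"), full.names = TRUE)
  expect_length(covs, 24L)
  rec <- read_bismark_coverage(covs[1])
  tmp <- withr::local_tempfile()
  write_bismark_coverage(rec, tmp)
  expect_identical(unname(tools::md5sum(covs[1])),
                   unname(tools::md5sum(tmp)))
  # GTF round-trips through the annotation reader with the planted genes
  genes <- read_gene_annotation(file.path(d, "annotation.gtf"), "gtf")
  expect_setequal(genes$gene_id, sim$genes$gene_id)
  # promoter-shared genes' promoters cover their windows
  idx <- build_feature_index(genes)
  ps <- truth[truth$promoter_shared == TRUE & truth$tissue == "blood"]
  ann <- annotate_dmrs(ps[, c("chrom", "start", "end")], idx)
  expect_true(all(grepl("promoter", ann$features)))
  expect_equal(sort(ann$gene_ids), sort(ps$gene_id))
})

test_that("null generator is centered and planted effects are realized", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 8, n_windows = 1000, dmr_fraction = 0,
                    shared_fraction = 0, shared_promoter_count = 0L,
                    tissues = "hippocampus", n_background_genes = 2L,
                    rho = 0, batch_logit_shift = 0)
  simulate_experiment(cfg, d)
  meta <- read_sample_metadata(file.path(d, "samples.tsv"))
  recs <- lapply(meta$sample_id, function(s)
    read_bismark_coverage(file.path(d, "coverage", paste0(s, ".cov"))))
  names(recs) <- meta$sample_id
  wc <- tile_and_aggregate(recs)
  tr <- as.numeric(meta$age_group[match(wc$samples,
                                        meta$sample_id)] == "old")
  diffs <- vapply(seq_len(nrow(wc$windows)), function(i)
    meth_diff(wc$n_meth[i, ], wc$n_unmeth[i, ], tr), numeric(1))
  expect_lt(abs(mean(diffs)), 1)  # percentage points
})

test_that("planted windows hit their target difference within 5 points", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 13, n_windows = 800, dmr_fraction = 0.05,
                    shared_fraction = 0, shared_promoter_count = 0L,
                    tissues = "hippocampus", n_background_genes = 2L,
                    rho = 0)
  sim <- simulate_experiment(cfg, d)
  meta <- read_sample_metadata(file.path(d, "samples.tsv"))
  recs <- lapply(meta$sample_id, function(s)
    read_bismark_coverage(file.path(d, "coverage", paste0(s, ".cov"))))
  names(recs) <- meta$sample_id
  wc <- tile_and_aggregate(recs)
  tr <- as.numeric(meta$age_group[match(wc$samples,
                                        meta$sample_id)] == "old")
  key <- paste(wc$windows$chrom, wc$windows$start)
  truth <- sim$truth
  hits <- match(paste(truth$chrom, truth$start), key)
  expect_true(all(!is.na(hits)))
  for (j in seq_along(hits)) {
    i <- hits[j]
    d_obs <- meth_diff(wc$n_meth[i, ], wc$n_unmeth[i, ], tr)
    d_true <- 100 * (truth$p_old[j] - truth$p_young[j])
    expect_lt(abs(d_obs - d_true), 5)
    # batch effect at the stated magnitude never flips the direction
    expect_equal(sign(d_obs), sign(d_true))
  }
})

test_that("infeasible configurations fail before writing files", {
  expect_error(sim_config(n_windows = 500), "infeasible")
  cfg <- small_cfg(n_windows = 400)
  cfg$n_windows <- 60  # too small for the spaced placement
  d <- file.path(withr::local_tempdir(), "never")
  expect_error(simulate_experiment(cfg, d), "infeasible")
  expect_false(dir.exists(d))
})

test_that("evaluate_recovery scores perfect, empty and random calls", {
  truth <- data.table::data.table(
    tissue = "hippocampus", chrom = "chr1",
    start = c(0L, 5000L), end = c(1000L, 6000L),
    direction = c("hyper", "hypo"), shared = FALSE,
    promoter_shared = FALSE)
  perfect <- data.table::data.table(
    chrom = "chr1", start = c(0L, 5000L), end = c(1000L, 6000L),
    direction = c("hyper", "hypo"), pass = TRUE)
  ev <- evaluate_recovery(truth, list(hippocampus = perfect))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fdr, 0)
  expect_equal(ev$direction_accuracy, 1)
  empty <- perfect[0L]
  ev0 <- evaluate_recovery(truth, list(hippocampus = empty))
  expect_equal(ev0$sensitivity, 0)
  expect_equal(ev0$n_called, 0L)
  expect_equal(ev0$fdr, 0)
  wrong <- data.table::copy(perfect)[, start := start + 1000L][
    , end := end + 1000L]
  evw <- evaluate_recovery(truth, list(hippocampus = wrong))
  expect_equal(evw$fdr, 1)
})
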