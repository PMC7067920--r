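# Synthetic RRBS experiments with known ground truth: per-sample Bismark
# coverage files, a minimal GTF, sample metadata, a qPCR Ct table, and a
# truth table listing every planted DMR. The sampler is deliberately richer
# than the binomial model the test assumes (beta-binomial within-group
# scatter, negative-binomial coverage, a two-level batch shift) so that the
# overdispersion correction has something to correct.

#' Simulation configuration
#'
#' Defaults describe the emulated study design: 6 young vs 6 old animals in
#' each of two tissues, samples split over two sequencing runs, ~1,000-bp
#' windows with on average 8 CpGs covered at a negative-binomial mean depth
#' of 30x, window baseline methylation from a bimodal Beta mixture,
#' beta-binomial within-group dispersion rho = 0.02, 2% of windows planted
#' as DMRs at +/- 30 percentage points, 10% of planted DMRs shared across
#' tissues in the same direction, and five shared hypermethylated DMRs
#' placed in gene promoters.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_per_group Samples per age group per tissue (default 6).
#' @param tissues Tissue names (default hippocampus, blood).
#' @param n_windows Number of 1,000-bp windows simulated (default 5000).
#' @param window_size Window width in bp (default 1000).
#' @param n_chroms Number of chromosomes the windows are spread over.
#' @param cpg_mean Mean CpGs per window (Poisson, shifted so every window
#'   has at least 3 CpGs and is testable).
#' @param coverage_mean,coverage_disp Negative-binomial read depth per CpG
#'   per sample (mean, size).
#' @param baseline_shapes Two Beta parameter pairs for the 50/50 bimodal
#'   baseline-methylation mixture (default Beta(1,10) and Beta(10,1)).
#' @param rho Beta-binomial within-group dispersion of per-sample window
#'   methylation (default 0.02).
#' @param dmr_fraction Fraction of windows planted as DMRs per tissue
#'   (default 0.02).
#' @param effect_size Planted methylation difference in percentage points
#'   (default 30).
#' @param prop_hyper Fraction of planted DMRs hypermethylated with age.
#' @param shared_fraction Fraction of each tissue's planted DMRs shared with
#'   the other tissue (default 0.1).
#' @param shared_promoter_count Number of shared hypermethylated DMRs placed
#'   in gene promoters (default 5).
#' @param batch_logit_shift Additive logit-scale shift applied to run2
#'   samples (default 0.1).
#' @param n_background_genes Genes placed away from planted windows.
#' @param dct_shift Named or unnamed numeric vector of true delta-Ct shifts
#'   (old minus young) for the shared-promoter genes; recycled/truncated to
#'   `shared_promoter_count`.
#' @param ct_sd Within-group Ct standard deviation in cycles.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_per_group = 6L,
                       tissues = c("hippocampus", "blood"),
                       n_windows = 5000L, window_size = 1000L,
                       n_chroms = 2L, cpg_mean = 8,
                       coverage_mean = 30, coverage_disp = 5,
                       baseline_shapes = list(c(1, 10), c(10, 1)),
                       rho = 0.02, dmr_fraction = 0.02, effect_size = 30,
                       prop_hyper = 0.5, shared_fraction = 0.1,
                       shared_promoter_count = 5L,
                       batch_logit_shift = 0.1,
                       n_background_genes = 20L,
                       dct_shift = c(1, 1, 1, 0.4, 0), ct_sd = 0.3) {
  cfg <- as.list(environment())
  n_planted <- floor(cfg$dmr_fraction * cfg$n_windows)
  n_shared <- floor(cfg$shared_fraction * n_planted)
  if (cfg$shared_promoter_count > n_shared) {
    stop("infeasible config: shared_promoter_count (",
         cfg$shared_promoter_count, ") exceeds the shared DMR count (",
         n_shared, ")")
  }
  if (cfg$effect_size <= 0 || cfg$effect_size > 98) {
    stop("effect_size must be in (0, 98] percentage points")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a complete two-tissue RRBS experiment
#'
#' Writes, under `out_dir`: `coverage/<sample>.cov` (Bismark format, one per
#' sample), `annotation.gtf`, `samples.tsv`, `ct_table.tsv`,
#' `truth_windows.tsv` and `truth_expression.tsv`. Identical seeds give
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list: `truth` (window truth table), `expr_truth`,
#'   `genes` (the emitted gene models), `meta`, `paths`.
#' @export
simulate_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_rng <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_rng, envir = globalenv()))
  }
  set.seed(config$seed)
  ws <- config$window_size
  nw <- config$n_windows
  per_chrom <- ceiling(nw / config$n_chroms)
  win <- data.table::data.table(
    idx = seq_len(nw),
    chrom = paste0("chr", ((seq_len(nw) - 1L) %/% per_chrom) + 1L),
    local = (seq_len(nw) - 1L) %% per_chrom)
  win$start <- win$local * ws
  win$end <- win$start + ws

  plan <- plant_dmrs(config, win)
  truth <- plan$truth
  genes <- plan$genes

  # CpG landscape (shared by all samples and tissues)
  n_cpg <- 3L + stats::rpois(nw, max(config$cpg_mean - 3, 0))
  cpg_win <- rep(seq_len(nw), n_cpg)
  offsets <- unlist(lapply(n_cpg, function(k) sort(sample.int(ws, k))))
  cpg <- data.table::data.table(
    win_idx = cpg_win,
    chrom = win$chrom[cpg_win],
    pos = win$start[cpg_win] + offsets)  # 1-based: start is 0-based, offset >= 1

  # window baseline methylation: 50/50 bimodal Beta mixture
  comp <- stats::runif(nw) < 0.5
  sh1 <- config$baseline_shapes[[1L]]; sh2 <- config$baseline_shapes[[2L]]
  baseline <- ifelse(comp, stats::rbeta(nw, sh1[1L], sh1[2L]),
                     stats::rbeta(nw, sh2[1L], sh2[2L]))
  # squeeze planted baselines so the full effect fits without clipping
  delta <- config$effect_size / 100
  for (tt in config$tissues) {
    tr <- truth[truth$tissue == tt, ]
    hy <- tr$idx[tr$direction == "hyper"]
    ho <- tr$idx[tr$direction == "hypo"]
    baseline[hy] <- pmin(pmax(baseline[hy], 0.05), 0.95 - delta)
    baseline[ho] <- pmin(pmax(baseline[ho], 0.05 + delta), 0.95)
  }

  meta <- make_metadata(config)
  dir.create(file.path(out_dir, "coverage"), recursive = TRUE,
             showWarnings = FALSE)

  truth_rows <- list()
  for (tt in config$tissues) {
    tr <- truth[truth$tissue == tt, ]
    p_young <- baseline
    p_old <- baseline
    p_old[tr$idx] <- baseline[tr$idx] +
      ifelse(tr$direction == "hyper", delta, -delta)
    tr$p_young <- p_young[tr$idx]
    tr$p_old <- p_old[tr$idx]
    truth_rows[[tt]] <- tr
    tmeta <- meta[meta$tissue == tt, ]
    for (i in seq_len(nrow(tmeta))) {
      p_grp <- if (tmeta$age_group[i] == "old") p_old else p_young
      rec <- simulate_sample(config, cpg, p_grp,
                             batch2 = tmeta$run[i] == "run2")
      write_bismark_coverage(
        rec, file.path(out_dir, "coverage",
                       paste0(tmeta$sample_id[i], ".cov")))
    }
  }
  truth <- data.table::rbindlist(truth_rows)

  write_sample_metadata(meta, file.path(out_dir, "samples.tsv"))
  write_sim_gtf(genes, file.path(out_dir, "annotation.gtf"))
  ct <- simulate_ct_table(config, plan$shared_genes, meta)
  data.table::fwrite(ct$table, file.path(out_dir, "ct_table.tsv"),
                     sep = "\t")
  truth_out <- truth[, c("tissue", "chrom", "start", "end", "direction",
                         "shared", "promoter_shared", "gene_id",
                         "p_young", "p_old")]
  data.table::fwrite(truth_out, file.path(out_dir, "truth_windows.tsv"),
                     sep = "\t")
  data.table::fwrite(ct$truth, file.path(out_dir, "truth_expression.tsv"),
                     sep = "\t")
  invisible(list(truth = truth_out, expr_truth = ct$truth, genes = genes,
                 meta = meta,
                 paths = list(
                   coverage_dir = file.path(out_dir, "coverage"),
                   annotation = file.path(out_dir, "annotation.gtf"),
                   metadata = file.path(out_dir, "samples.tsv"),
                   ct_table = file.path(out_dir, "ct_table.tsv"),
                   truth_windows = file.path(out_dir, "truth_windows.tsv"),
                   truth_expression = file.path(out_dir,
                                                "truth_expression.tsv"))))
}

# Choose planted windows (spaced >= 5 windows apart and away from chromosome
# edges so gene features never collide with unrelated planted windows),
# assign directions, designate shared and shared-promoter windows, and place
# genes: one per shared-promoter window plus background genes.
plant_dmrs <- function(config, win) {
  nw <- nrow(win)
  n_planted <- floor(config$dmr_fraction * nw)
  n_shared <- floor(config$shared_fraction * n_planted)
  if (config$shared_promoter_count > n_shared) {
    stop("infeasible config: shared_promoter_count exceeds the shared ",
         "DMR count (", n_shared, ")")
  }
  n_own <- n_planted - n_shared
  need <- n_shared + length(config$tissues) * n_own +
    config$n_background_genes
  # stride-7 grid away from chromosome edges: picks are >= 7 windows apart,
  # so the +/- 3-window footprint of a placed gene (3-kb promoter upstream,
  # 2-kb body downstream) never touches another pick's window
  per_chrom <- ceiling(nw / config$n_chroms)
  grid <- win$idx[win$local >= 5L & win$local < per_chrom - 5L &
                    win$local %% 7L == 5L]
  if (need > length(grid)) {
    stop("infeasible config: need ", need, " spaced DMR/gene sites but ",
         "only ", length(grid), " are available in ", nw, " windows")
  }
  picks <- sample(grid, need)
  shared_idx <- picks[seq_len(n_shared)]
  rest <- if (n_shared > 0L) picks[-seq_len(n_shared)] else picks
  own <- list()
  for (k in seq_along(config$tissues)) {
    own[[config$tissues[k]]] <- rest[seq_len(n_own) + (k - 1L) * n_own]
  }
  bg_idx <- rest[seq(length(config$tissues) * n_own + 1L,
                     length.out = config$n_background_genes)]

  # directions: the first shared_promoter_count shared windows are hyper
  # (and promoter-hosted); the rest follow prop_hyper deterministically
  npc <- config$shared_promoter_count
  n_rest_sh <- n_shared - npc
  shared_dir <- c(rep("hyper", npc),
                  rep(c("hyper", "hypo"),
                      times = c(round(config$prop_hyper * n_rest_sh),
                                n_rest_sh -
                                  round(config$prop_hyper * n_rest_sh))))
  # paste0 with a zero-length vector returns "", not character(0)
  shared_genes <- if (npc > 0L) paste0("sgene", seq_len(npc)) else character(0)
  truth <- list()
  for (tt in config$tissues) {
    oidx <- own[[tt]]
    n_hy <- round(config$prop_hyper * length(oidx))
    own_dir <- rep(c("hyper", "hypo"),
                   times = c(n_hy, length(oidx) - n_hy))
    idx <- c(shared_idx, oidx)
    truth[[tt]] <- data.table::data.table(
      tissue = tt, idx = idx,
      chrom = win$chrom[idx], start = win$start[idx], end = win$end[idx],
      direction = c(shared_dir, own_dir),
      shared = c(rep(TRUE, n_shared), rep(FALSE, length(oidx))),
      promoter_shared = c(rep(TRUE, npc), rep(FALSE, n_shared - npc),
                          rep(FALSE, length(oidx))),
      gene_id = c(shared_genes, rep(NA_character_, n_shared - npc),
                  rep(NA_character_, length(oidx))))
  }
  truth <- data.table::rbindlist(truth)

  # genes: shared-promoter genes sit just downstream of their window so the
  # 3-kb promoter upstream of the TSS covers it; background genes elsewhere
  genes <- list()
  for (j in seq_len(npc)) {
    w <- shared_idx[j]
    tss <- win$end[w]  # + strand: promoter [tss - 3000, tss) covers the window
    genes[[length(genes) + 1L]] <- data.table::data.table(
      gene_id = shared_genes[j], chrom = win$chrom[w], strand = "+",
      tx_start = tss, tx_end = tss + 2000L,
      exon_starts = list(c(tss, tss + 1500L)),
      exon_ends = list(c(tss + 500L, tss + 2000L)))
  }
  for (j in seq_along(bg_idx)) {
    w <- bg_idx[j]
    strand <- if (j %% 2L == 0L) "+" else "-"
    s <- win$start[w]
    genes[[length(genes) + 1L]] <- data.table::data.table(
      gene_id = paste0("bgene", j), chrom = win$chrom[w], strand = strand,
      tx_start = s, tx_end = s + 900L,
      exon_starts = list(c(s, s + 600L)),
      exon_ends = list(c(s + 300L, s + 900L)))
  }
  genes <- data.table::rbindlist(genes)
  list(truth = truth, genes = genes, shared_genes = shared_genes)
}

make_metadata <- function(config) {
  rows <- list()
  for (tt in config$tissues) {
    for (ag in c("young", "old")) {
      n <- config$n_per_group
      rows[[paste(tt, ag)]] <- data.table::data.table(
        sample_id = paste(substr(tt, 1L, 4L), ag, seq_len(n), sep = "_"),
        tissue = tt, age_group = ag,
        run = paste0("run", rep_len(1:2, n)))  # age balanced across runs
    }
  }
  data.table::rbindlist(rows)
}

# one sample's coverage records: beta-binomial window methylation around the
# group mean, NB depth per CpG, optional batch shift on the logit scale
simulate_sample <- function(config, cpg, p_window, batch2 = FALSE) {
  nw <- length(p_window)
  rho <- config$rho
  if (rho > 0) {
    a <- p_window * (1 - rho) / rho
    b <- (1 - p_window) * (1 - rho) / rho
    p_s <- stats::rbeta(nw, a, b)
  } else {
    p_s <- p_window
  }
  if (batch2) {
    p_s <- stats::plogis(stats::qlogis(pmin(pmax(p_s, 1e-6), 1 - 1e-6)) +
                           config$batch_logit_shift)
  }
  p_s <- pmin(pmax(p_s, 0.01), 0.99)
  cov <- stats::rnbinom(nrow(cpg), mu = config$coverage_mean,
                        size = config$coverage_disp)
  n_meth <- stats::rbinom(nrow(cpg), cov, p_s[cpg$win_idx])
  rec <- data.table::data.table(chrom = cpg$chrom, pos = cpg$pos,
                                n_meth = n_meth, n_unmeth = cov - n_meth)
  rec <- rec[cov > 0L]
  data.table::setorderv(rec, c("chrom", "pos"))
  rec[]
}

# minimal GTF 2.2: gene + exon features with gene_id attributes, written
# through rtracklayer so the dialect matches what the reader expects
write_sim_gtf <- function(genes, path) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    es <- g$exon_starts[[1L]]; ee <- g$exon_ends[[1L]]
    rows[[i]] <- data.table::data.table(
      chrom = g$chrom,
      start = c(g$tx_start, es) + 1L,  # to 1-based inclusive
      end = c(g$tx_end, ee),
      strand = g$strand,
      type = c("gene", rep("exon", length(es))),
      gene_id = g$gene_id)
  }
  dt <- data.table::rbindlist(rows)
  gr <- GenomicRanges::GRanges(
    dt$chrom, IRanges::IRanges(dt$start, dt$end), strand = dt$strand,
    type = dt$type, gene_id = dt$gene_id)
  S4Vectors::mcols(gr)$source <- "dmrshare_sim"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

simulate_ct_table <- function(config, shared_genes, meta) {
  hippo <- meta[meta$tissue == config$tissues[1L], ]
  shifts <- rep_len(config$dct_shift, length(shared_genes))
  base_ct <- stats::runif(length(shared_genes), 20, 28)
  rows <- list()
  for (j in seq_along(shared_genes)) {
    shift <- ifelse(hippo$age_group == "old", shifts[j], 0)
    rows[[shared_genes[j]]] <- data.table::data.table(
      sample_id = hippo$sample_id, group = hippo$age_group,
      gene = shared_genes[j],
      ct = round(base_ct[j] + shift +
                   stats::rnorm(nrow(hippo), 0, config$ct_sd), 4))
  }
  rows[["ref"]] <- data.table::data.table(
    sample_id = hippo$sample_id, group = hippo$age_group, gene = "GAPDH",
    ct = round(18 + stats::rnorm(nrow(hippo), 0, config$ct_sd), 4))
  tab <- data.table::rbindlist(rows)
  truth <- data.table::data.table(gene = shared_genes,
                                  true_dct_shift = shifts)
  list(table = tab, truth = truth)
}

#' Compare DMR calls against the planted truth
#'
#' @param truth Window truth table from [simulate_experiment()] (or read
#'   from `truth_windows.tsv`).
#' @param calls Named list of [call_dmrs()] tables, one per tissue.
#' @param shared Optional `shared_dmr_set` from [find_shared_dmrs()].
#' @return `data.table` with one row per tissue (plus a `shared` row when
#'   `shared` is given): `n_planted`, `n_called`, `sensitivity`,
#'   `fdr` (0 when nothing is called), `direction_accuracy`.
#' @export
evaluate_recovery <- function(truth, calls, shared = NULL) {
  truth <- data.table::as.data.table(truth)
  out <- list()
  for (tt in names(calls)) {
    tr <- truth[truth$tissue == tt, ]
    cl <- data.table::as.data.table(calls[[tt]])
    cl <- cl[cl$pass == TRUE]
    key_t <- paste(tr$chrom, tr$start, tr$end)
    key_c <- paste(cl$chrom, cl$start, cl$end)
    hit <- match(key_t, key_c)
    recovered <- !is.na(hit)
    dir_ok <- tr$direction[recovered] == cl$direction[hit[recovered]]
    out[[tt]] <- data.table::data.table(
      set = tt, n_planted = nrow(tr), n_called = nrow(cl),
      sensitivity = mean(recovered),
      fdr = if (nrow(cl) == 0L) 0 else
        sum(!(key_c %in% key_t)) / nrow(cl),
      direction_accuracy = if (any(recovered)) mean(dir_ok) else NA_real_)
  }
  if (!is.null(shared)) {
    tr_sh <- unique(truth[truth$shared == TRUE,
                          c("chrom", "start", "end", "direction")])
    key_t <- paste(tr_sh$chrom, tr_sh$start, tr_sh$end)
    sh <- shared$shared
    key_s <- paste(sh$chrom, sh$start, sh$end)
    hit <- match(key_t, key_s)
    recovered <- !is.na(hit)
    dir_ok <- tr_sh$direction[recovered] == sh$direction[hit[recovered]]
    out[["shared"]] <- data.table::data.table(
      set = "shared", n_planted = nrow(tr_sh), n_called = nrow(sh),
      sensitivity = mean(recovered),
      fdr = if (nrow(sh) == 0L) 0 else
        sum(!(key_s %in% key_t)) / nrow(sh),
      direction_accuracy = if (any(recovered)) mean(dir_ok) else NA_real_)
  }
  data.table::rbindlist(out)[]
}
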