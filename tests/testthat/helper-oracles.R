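# Shared fixtures and independent oracles used across the suite.

# random sorted CpG records
rand_cpg_records <- function(n, seed = 1, chroms = c("chr1", "chr2"),
                             max_pos = 100000L) {
  withr::with_seed(seed, {
    dt <- data.table::data.table(
      chrom = sample(chroms, n, replace = TRUE),
      pos = sample.int(max_pos, n, replace = TRUE),
      n_meth = rpois(n, 5),
      n_unmeth = rpois(n, 5))
  })
  dt <- unique(dt, by = c("chrom", "pos"))
  data.table::setorderv(dt, c("chrom", "pos"))
  dt[]
}

# closed-form 2x2 binomial likelihood-ratio G-statistic on pooled counts
g_stat_2x2 <- function(m1, u1, m0, u0) {
  obs <- c(m1, u1, m0, u0)
  n1 <- m1 + u1; n0 <- m0 + u0
  p_pool <- (m1 + m0) / (n1 + n0)
  exp_ <- c(n1 * p_pool, n1 * (1 - p_pool), n0 * p_pool, n0 * (1 - p_pool))
  keep <- obs > 0
  2 * sum(obs[keep] * log(obs[keep] / exp_[keep]))
}

# exhaustive 1-D maximization of the binomial log-likelihood: with no
# covariate the two groups are independent, so the alternative model
# maximizes each group separately and the null maximizes the pool.
# two-stage grid (coarse scan, then a fine scan around the maximum)
grid_lrt <- function(n_meth, n_unmeth, treatment) {
  ll <- function(y, n, p) sum(y) * log(p) + sum(n - y) * log(1 - p)
  best <- function(y, n) {
    coarse <- seq(0.001, 0.999, by = 0.001)
    v <- vapply(coarse, function(p) ll(y, n, p), numeric(1))
    p0 <- coarse[which.max(v)]
    fine <- seq(max(1e-6, p0 - 0.002), min(1 - 1e-6, p0 + 0.002),
                by = 1e-6)
    max(vapply(fine, function(p) ll(y, n, p), numeric(1)))
  }
  n <- n_meth + n_unmeth
  t1 <- treatment == 1
  ll_alt <- best(n_meth[t1], n[t1]) + best(n_meth[!t1], n[!t1])
  ll_null <- best(n_meth, n)
  2 * (ll_alt - ll_null)
}

# quadratic all-pairs annotation oracle, independent of the package's
# interval machinery: recomputes promoters/exons/introns from gene models
brute_annotate <- function(dmr, genes, promoter_bp = 3000L) {
  feats <- character(); gids <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != dmr$chrom) next
    ex <- g$exons[[1L]]
    tss <- if (g$strand == "+") g$tx_start else g$tx_end - 1L
    prom <- if (g$strand == "+") c(max(0L, tss - promoter_bp), tss) else
      c(tss + 1L, tss + 1L + promoter_bp)
    ivs <- rbind(data.frame(s = prom[1], e = prom[2], f = "promoter"),
                 data.frame(s = ex[, 1], e = ex[, 2], f = "exon"))
    if (nrow(ex) > 1L) {
      ivs <- rbind(ivs, data.frame(s = ex[-nrow(ex), 2], e = ex[-1, 1],
                                   f = "intron"))
    }
    for (j in seq_len(nrow(ivs))) {
      if (max(dmr$start, ivs$s[j]) < min(dmr$end, ivs$e[j])) {
        feats <- c(feats, ivs$f[j]); gids <- c(gids, g$gene_id)
      }
    }
  }
  list(features = sort(unique(feats)), gene_ids = sort(unique(gids)))
}

# tiny window_counts builder for direct statistical tests
make_wc <- function(n_meth, n_unmeth, samples = NULL,
                    chrom = "chr1") {
  n_meth <- rbind(n_meth); n_unmeth <- rbind(n_unmeth)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(n_meth)))
  colnames(n_meth) <- colnames(n_unmeth) <- samples
  nw <- nrow(n_meth)
  structure(list(
    windows = data.table::data.table(chrom = chrom,
                                     start = (seq_len(nw) - 1L) * 1000L,
                                     end = seq_len(nw) * 1000L),
    samples = samples, n_meth = n_meth, n_unmeth = n_unmeth,
    n_cpgs = matrix(3L, nw, ncol(n_meth))),
    class = "window_counts")
}

# metadata for a single-tissue 6 vs 6 design split over two runs
meta_6v6 <- function(tissue = "hippocampus") {
  data.table::data.table(
    sample_id = paste0("s", 1:12),
    tissue = tissue,
    age_group = rep(c("young", "old"), each = 6),
    run = rep(c("run1", "run2"), 6))
}

# simulate one batch of null binomial windows (no effect, no batch shift)
null_window_counts <- function(n_windows, n_per_group = 6,
                               cpgs = 8, cov_mean = 30, seed = 1) {
  withr::with_seed(seed, {
    ns <- 2 * n_per_group
    p <- runif(n_windows, 0.05, 0.95)
    trials <- matrix(rnbinom(n_windows * ns, mu = cov_mean * cpgs,
                             size = 5 * cpgs), n_windows, ns)
    trials <- pmax(trials, 10L)
    meth <- matrix(rbinom(n_windows * ns, trials, rep(p, ns)),
                   n_windows, ns)
  })
  make_wc(meth, trials - meth, samples = paste0("s", seq_len(2 * n_per_group)))
}
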