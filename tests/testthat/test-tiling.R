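test_that("common-site filter keeps exactly the everywhere-covered sites", {
  recs <- list(
    a = data.table::data.table(chrom = "chr1", pos = c(10L, 20L, 30L),
                               n_meth = c(6L, 12L, 5L),
                               n_unmeth = c(6L, 0L, 5L)),
    b = data.table::data.table(chrom = "chr1", pos = c(10L, 20L),
                               n_meth = c(9L, 10L),
                               n_unmeth = c(0L, 10L)))
  # site 10 has coverage (12, 9): the 9 fails the 10x rule in sample b
  mm <- filter_common_sites(recs, min_coverage = 10L)
  expect_equal(mm$sites$pos, 20L)
  expect_equal(unname(mm$rates[1, ]), c(1, 0.5))
  # min_coverage = 1: every site present in both samples is retained
  mm1 <- filter_common_sites(recs, min_coverage = 1L)
  expect_equal(mm1$sites$pos, c(10L, 20L))
})

test_that("common-site filter equals the brute-force intersection", {
  recs <- lapply(1:4, function(i) rand_cpg_records(400, seed = i,
                                                   max_pos = 150L))
  names(recs) <- paste0("s", 1:4)
  mm <- filter_common_sites(recs, min_coverage = 8L)
  keys <- lapply(recs, function(r) {
    r <- r[r$n_meth + r$n_unmeth >= 8L]
    paste(r$chrom, r$pos)
  })
  expected <- Reduce(intersect, keys)
  expect_setequal(paste(mm$sites$chrom, mm$sites$pos), expected)
})

test_that("common-site filter edge cases", {
  expect_error(filter_common_sites(list()), "no samples")
  recs <- list(a = data.table::data.table(chrom = "chr1", pos = 1L,
                                          n_meth = 1L, n_unmeth = 0L))
  expect_warning(mm <- filter_common_sites(recs, min_coverage = 100L),
                 "no site")
  expect_equal(nrow(mm$rates), 0L)
})

test_that("PCA separates constructed groups and orders variance", {
  set.seed(11)
  n_sites <- 200
  base <- runif(n_sites, 0.2, 0.8)
  shift <- ifelse(seq_len(n_sites) <= n_sites / 2, 0.3, 0)
  rates <- sapply(1:8, function(s) {
    g <- s > 4
    pmin(pmax(base + g * shift + rnorm(n_sites, 0, 0.02), 0), 1)
  })
  colnames(rates) <- paste0("s", 1:8)
  mm <- structure(list(sites = data.table::data.table(chrom = "chr1",
                                                      pos = 1:n_sites),
                       samples = colnames(rates), rates = rates),
                  class = "meth_matrix")
  p <- pca_samples(mm, 3)
  # PC1 linearly separates the two groups
  pc1 <- p$scores[, 1]
  expect_true(max(pc1[1:4]) < min(pc1[5:8]) ||
                min(pc1[1:4]) > max(pc1[5:8]))
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-12)
  # site reordering changes scores at most by sign
  perm <- sample(n_sites)
  mm2 <- mm; mm2$rates <- rates[perm, ]; mm2$sites <- mm$sites[perm]
  p2 <- pca_samples(mm2, 3)
  for (k in 1:3) {
    expect_true(isTRUE(all.equal(p$scores[, k], p2$scores[, k])) ||
                  isTRUE(all.equal(p$scores[, k], -p2$scores[, k])))
  }
})

test_that("PCA degenerate and symmetric inputs", {
  rates <- matrix(0.5, 10, 3, dimnames = list(NULL, paste0("s", 1:3)))
  mm <- structure(list(sites = NULL, samples = colnames(rates),
                       rates = rates), class = "meth_matrix")
  expect_error(pca_samples(mm), "degenerate")
  rates[, 1] <- rates[, 2] <- runif(10)
  rates[, 3] <- runif(10)
  mm$rates <- rates
  p <- pca_samples(mm, 2)
  # identical samples score identically on every component
  expect_equal(p$scores[1, ], p$scores[2, ])
})

test_that("window assignment respects 1-based boundary arithmetic", {
  recs <- list(s1 = data.table::data.table(
    chrom = "chr1", pos = c(1L, 1000L, 1001L),
    n_meth = c(5L, 7L, 9L), n_unmeth = c(10L, 8L, 1L)))
  wc <- tile_and_aggregate(recs, window_size = 1000L,
                           min_window_coverage = 1L, min_cpgs = 1L)
  expect_equal(wc$windows$start, c(0L, 1000L))
  # positions 1 and 1000 pool into [0,1000): 5+7 meth, 10+8 unmeth
  expect_equal(unname(wc$n_meth[, 1]), c(12L, 9L))
  expect_equal(unname(wc$n_unmeth[, 1]), c(18L, 1L))
  expect_equal(unname(wc$n_cpgs[, 1]), c(2L, 1L))
})

test_that("aggregation matches the naive per-window double loop", {
  recs <- lapply(1:3, function(i) rand_cpg_records(500, seed = 10 + i,
                                                   max_pos = 20000L))
  names(recs) <- paste0("s", 1:3)
  wc <- tile_and_aggregate(recs, 1000L, min_window_coverage = 1L,
                           min_cpgs = 1L)
  for (k in sample(nrow(wc$windows), 20)) {
    w <- wc$windows[k, ]
    for (s in names(recs)) {
      r <- recs[[s]]
      inside <- r$chrom == w$chrom & r$pos >= w$start + 1L &
        r$pos <= w$end
      expect_equal(unname(wc$n_meth[k, s]), sum(r$n_meth[inside]))
      expect_equal(unname(wc$n_unmeth[k, s]), sum(r$n_unmeth[inside]))
    }
  }
  # conservation: window totals equal the CpG totals inside retained windows
  total_win <- sum(wc$n_meth) + sum(wc$n_unmeth)
  keys <- paste(wc$windows$chrom, wc$windows$start)
  total_cpg <- sum(vapply(recs, function(r) {
    k <- paste(r$chrom, (r$pos - 1L) %/% 1000L * 1000L)
    sum((r$n_meth + r$n_unmeth)[k %in% keys])
  }, numeric(1)))
  expect_equal(total_win, total_cpg)
})

test_that("window retention needs coverage and CpG minima in every sample", {
  recs <- list(
    s1 = data.table::data.table(chrom = "chr1", pos = c(10L, 20L, 30L),
                                n_meth = 4L, n_unmeth = 4L),
    s2 = data.table::data.table(chrom = "chr1", pos = c(10L, 20L),
                                n_meth = 10L, n_unmeth = 10L))
  # s2 has only 2 covered CpGs -> window fails min_cpgs = 3
  wc <- tile_and_aggregate(recs, 1000L, min_window_coverage = 10L,
                           min_cpgs = 3L)
  expect_equal(nrow(wc$windows), 0L)
  wc2 <- tile_and_aggregate(recs, 1000L, min_window_coverage = 10L,
                            min_cpgs = 2L)
  expect_equal(nrow(wc2$windows), 1L)
})
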