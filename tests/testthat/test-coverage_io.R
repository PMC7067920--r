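test_that("bismark coverage parsing maps fields and recomputes from counts", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t3050\t3050\t75\t3\t1",
               "chr1\t3001\t3001\t0\t0\t7"), f)
  rec <- read_bismark_coverage(f)
  expect_equal(rec$pos, c(3001L, 3050L))  # sorted by position
  expect_equal(rec[pos == 3050L, ]$n_meth, 3L)
  expect_equal(rec[pos == 3050L, ]$n_unmeth, 1L)
  expect_false("pct" %in% names(rec))
})

test_that("empty coverage file gives an empty record set, not an error", {
  f <- withr::local_tempfile(fileext = ".cov")
  file.create(f)
  rec <- read_bismark_coverage(f)
  expect_equal(nrow(rec), 0L)
  expect_named(rec, c("chrom", "pos", "n_meth", "n_unmeth"))
})

test_that("malformed coverage lines are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t10\t10\t50\t1\t1",
               "chr1\t20\t20\t50\t-3\t1"), f)
  expect_error(read_bismark_coverage(f), "line 2")
  writeLines("chr1\t10\t10\t50\t1", f)
  expect_error(read_bismark_coverage(f), "6 columns")
})

test_that("coverage write -> read round-trips 1000 random records", {
  rec <- rand_cpg_records(1000, seed = 7)
  f <- withr::local_tempfile(fileext = ".cov")
  write_bismark_coverage(rec, f)
  back <- read_bismark_coverage(f)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  # emitted percentage column agrees with the counts
  raw <- data.table::fread(f, header = FALSE)
  cov <- rec$n_meth + rec$n_unmeth
  expect_lt(max(abs(raw$V4 - ifelse(cov > 0, 100 * rec$n_meth / cov, 0))),
            1e-4)
})

test_that("writing unsorted records is an error", {
  rec <- data.table::data.table(chrom = "chr1", pos = c(20L, 10L),
                                n_meth = 1L, n_unmeth = 1L)
  expect_error(write_bismark_coverage(rec, tempfile()), "sorted")
})

gtf_lines <- function(...) {
  # minimal GTF 2.2 fixture builder: list of c(type, start, end, strand, gene)
  vapply(list(...), function(x) {
    sprintf("chr1\ttest\t%s\t%s\t%s\t.\t%s\t.\tgene_id \"%s\";",
            x[1], x[2], x[3], x[4], x[5])
  }, character(1))
}

test_that("GTF coordinates convert to 0-based half-open and exons merge", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf_lines(c("gene", 101, 300, "+", "g1"),
                       c("exon", 101, 200, "+", "g1"),
                       c("exon", 151, 250, "+", "g1")), f)
  gm <- read_gene_annotation(f, "gtf")
  expect_equal(gm$tx_start, 100L)
  expect_equal(gm$tx_end, 300L)
  # overlapping exon records [100,200) and [150,250) merge to [100,250)
  expect_equal(unname(gm$exons[[1]]), cbind(100L, 250L),
               ignore_attr = TRUE)
})

test_that("BED12 blocks become exons at chromStart offsets", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 1000, 1200, "gx", 0, "+", 1000, 1200, "0",
                     2, "50,50", "0,150"), collapse = "\t"), f)
  gm <- read_gene_annotation(f, "bed12")
  expect_equal(unname(gm$exons[[1]]),
               cbind(c(1000L, 1150L), c(1050L, 1200L)), ignore_attr = TRUE)
})

test_that("GTF and BED12 give identical models for the same gene", {
  fg <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf_lines(c("gene", 1001, 1200, "-", "gx"),
                       c("exon", 1001, 1050, "-", "gx"),
                       c("exon", 1151, 1200, "-", "gx")), fg)
  fb <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 1000, 1200, "gx", 0, "-", 1000, 1200, "0",
                     2, "50,50", "0,150"), collapse = "\t"), fb)
  a <- read_gene_annotation(fg, "gtf")
  b <- read_gene_annotation(fb, "bed12")
  expect_equal(as.list(a), as.list(b))
})

test_that("annotation errors: exon outside span, unknown strand", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf_lines(c("gene", 101, 200, "+", "bad"),
                       c("exon", 101, 250, "+", "bad")), f)
  expect_error(read_gene_annotation(f, "gtf"), "bad")
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 0, 100, "g", 0, "?", 0, 100, "0", 1, "100",
                     "0"), collapse = "\t"), f2)
  expect_error(read_gene_annotation(f2, "bed12"), "strand")
})

test_that("DMR BED output follows the score rule", {
  calls <- data.table::data.table(
    chrom = "chr2", start = 4000L, end = 5000L,
    direction = c("hyper", "hypo", "hyper"),
    qvalue = c(0.001, 1, 1e-200))
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(calls, f)
  bed <- data.table::fread(f, header = FALSE)
  expect_equal(bed$V1, rep("chr2", 3))
  expect_equal(bed$V2, rep(4000L, 3))
  expect_equal(bed$V4, c("hyper", "hypo", "hyper"))
  expect_equal(bed$V5, c(30L, 0L, 1000L))
  expect_equal(bed$V6, rep(".", 3))
})

test_that("sample metadata round-trips and is validated", {
  meta <- meta_6v6()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(meta, f)
  expect_equal(as.data.frame(read_sample_metadata(f)), as.data.frame(meta))
  bad <- data.table::copy(meta)[2, sample_id := meta$sample_id[1]]
  fb <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(bad, fb)
  expect_error(read_sample_metadata(fb), "duplicate")
})
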