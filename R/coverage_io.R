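# I/O for the standard file formats the pipeline touches: Bismark coverage
# files, sample metadata sheets, gene annotation (GTF / BED12) and BED output
# for DMR calls.
#
# Coordinate conventions: Bismark coverage files are 1-based with start == end;
# gene models and all interval arithmetic inside the package are 0-based
# half-open. Conversion happens exactly once, at the I/O boundary.

#' Read a Bismark-style coverage file
#'
#' Parses the 6-column tab-separated coverage format emitted by Bismark's
#' methylation extractor: chromosome, start (1-based), end (equal to start),
#' methylation percentage, count methylated, count unmethylated. The
#' percentage column is advisory only and is ignored; the read counts are the
#' sufficient statistic for everything downstream.
#'
#' @param path Path to a coverage file (plain text, tab-separated).
#' @return A `data.table` with columns `chrom` (character), `pos` (integer,
#'   1-based position of the cytosine), `n_meth` and `n_unmeth` (integer read
#'   counts), sorted by (chrom, pos). An empty file yields a zero-row table.
#' @export
read_bismark_coverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (file.size(path) == 0L) return(empty_cpg_records())
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1),
                          showProgress = FALSE)
  if (ncol(dt) != 6L) {
    stop("malformed coverage file '", path, "': expected 6 columns, got ",
         ncol(dt))
  }
  data.table::setnames(dt, c("chrom", "start", "end", "pct", "n_meth",
                             "n_unmeth"))
  bad <- which(!is_whole(dt$start) | !is_whole(dt$n_meth) |
                 !is_whole(dt$n_unmeth) | dt$n_meth < 0 | dt$n_unmeth < 0 |
                 is.na(dt$start))
  if (length(bad) > 0L) {
    stop("malformed coverage line ", bad[1L], " in '", path,
         "': counts must be non-negative integers")
  }
  out <- dt[, list(chrom = chrom, pos = as.integer(start),
                   n_meth = as.integer(n_meth),
                   n_unmeth = as.integer(n_unmeth))]
  data.table::setkeyv(out, c("chrom", "pos"))
  out[]
}

#' Write CpG records in Bismark coverage format
#'
#' Inverse of [read_bismark_coverage()]. The percentage column is recomputed
#' as `100 * n_meth / (n_meth + n_unmeth)` (6 significant digits; 0 when the
#' site has zero coverage).
#'
#' @param records A `data.table` of CpG records (`chrom`, `pos`, `n_meth`,
#'   `n_unmeth`), sorted by (chrom, pos).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bismark_coverage <- function(records, path) {
  validate_cpg_records(records)
  if (nrow(records) > 0L) {
    ord <- order(records$chrom, records$pos, method = "radix")
    if (!identical(ord, seq_len(nrow(records)))) {
      stop("records must be sorted by (chrom, pos) before writing")
    }
  }
  cov <- records$n_meth + records$n_unmeth
  pct <- ifelse(cov > 0L, 100 * records$n_meth / cov, 0)
  out <- data.table::data.table(records$chrom, records$pos, records$pos,
                                signif(pct, 6), records$n_meth,
                                records$n_unmeth)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

empty_cpg_records <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         n_meth = integer(), n_unmeth = integer())
}

validate_cpg_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("chrom", "pos", "n_meth", "n_unmeth") %in% names(records)))
  if (nrow(records) > 0L &&
      (any(records$n_meth < 0L) || any(records$n_unmeth < 0L))) {
    stop("negative read counts in CpG records")
  }
  invisible(records)
}

is_whole <- function(x) {
  if (is.integer(x)) return(rep(TRUE, length(x)))
  is.numeric(x) & !is.na(x) & x == floor(x)
}

#' Read a sample metadata sheet
#'
#' Four tab-separated columns with header: `sample_id`, `tissue`
#' (`hippocampus` or `blood`), `age_group` (`young` or `old`), `run`
#' (sequencing batch, e.g. `run1` / `run2`).
#'
#' @param path Path to the TSV file.
#' @return A `data.table` with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  meta <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", showProgress = FALSE)
  required <- c("sample_id", "tissue", "age_group", "run")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (any(meta$age_group == "" | is.na(meta$age_group))) {
    stop("every sample needs an age_group label")
  }
  meta[]
}

#' @rdname read_sample_metadata
#' @param meta Metadata `data.table` to write.
#' @export
write_sample_metadata <- function(meta, path) {
  data.table::fwrite(meta[, c("sample_id", "tissue", "age_group", "run")],
                     path, sep = "\t")
  invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' Builds one gene model per `gene_id`: the transcript span, strand, and a
#' merged (union) set of exon intervals. GTF input (1-based, inclusive) is
#' converted to the package-internal 0-based half-open convention; BED12 is
#' already 0-based half-open. Multi-transcript genes collapse to the outermost
#' span and the union of their exons.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"bed12"`.
#' @return A `data.table` with one row per gene: `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tx_start`, `tx_end` (0-based half-open) and a list-column
#'   `exons` of two-column matrices (start, end), merged and sorted.
#' @export
read_gene_annotation <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    meta <- S4Vectors::mcols(gr)
    if (!"gene_id" %in% names(meta)) stop("GTF lacks gene_id attribute")
    keep <- meta$type %in% c("gene", "transcript", "exon")
    gr <- gr[keep]
    meta <- S4Vectors::mcols(gr)
    dt <- data.table::data.table(
      gene_id = as.character(meta$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      type = as.character(meta$type))
  } else {
    # comma-separated block lists defeat fread's type/dec guessing
    bed <- data.table::fread(path, header = FALSE, sep = "\t",
                             colClasses = "character",
                             showProgress = FALSE)
    if (ncol(bed) < 12L) stop("BED12 requires 12 columns, got ", ncol(bed))
    rows <- lapply(seq_len(nrow(bed)), function(i) {
      sizes <- as.integer(strsplit(sub(",$", "", bed[[11L]][i]), ",")[[1L]])
      offs <- as.integer(strsplit(sub(",$", "", bed[[12L]][i]), ",")[[1L]])
      nblock <- as.integer(bed[[10L]][i])
      if (length(sizes) != nblock || length(offs) != nblock) {
        stop("BED12 block fields inconsistent on line ", i)
      }
      cs <- as.integer(bed[[2L]][i])
      data.table::data.table(
        gene_id = as.character(bed[[4L]][i]),
        chrom = as.character(bed[[1L]][i]),
        strand = as.character(bed[[6L]][i]),
        start = c(cs, cs + offs),
        end = c(as.integer(bed[[3L]][i]), cs + offs + sizes),
        type = c("transcript", rep("exon", length(offs))))
    })
    dt <- data.table::rbindlist(rows)
  }
  if (!all(dt$strand %in% c("+", "-"))) {
    stop("unknown strand character: ",
         paste(unique(setdiff(dt$strand, c("+", "-"))), collapse = ", "))
  }
  build_gene_models(dt)
}

# dt: gene_id, chrom, strand, start, end (0-based half-open), type
build_gene_models <- function(dt) {
  gene_id <- NULL  # NSE guard
  out <- dt[, {
    span <- .SD[type %in% c("gene", "transcript")]
    ex <- .SD[type == "exon"]
    if (nrow(ex) == 0L) ex <- span  # single-block genes
    tx_start <- if (nrow(span) > 0L) min(span$start) else min(ex$start)
    tx_end <- if (nrow(span) > 0L) max(span$end) else max(ex$end)
    if (any(ex$start < tx_start) || any(ex$end > tx_end)) {
      stop("exon outside transcript span for gene ", .BY$gene_id)
    }
    if (tx_start >= tx_end) stop("empty transcript span for gene ",
                                 .BY$gene_id)
    list(chrom = chrom[1L], strand = strand[1L],
         tx_start = tx_start, tx_end = tx_end,
         exons = list(merge_intervals(ex$start, ex$end)))
  }, by = gene_id]
  data.table::setorderv(out, c("chrom", "tx_start"))
  out[]
}

# union of 0-based half-open intervals; returns a sorted 2-column matrix
merge_intervals <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Write DMR calls as BED6
#'
#' One line per passing call: chrom, start, end (0-based half-open), name
#' `hyper`/`hypo`, score `min(1000, round(-10 log10 q))`, strand `"."`.
#'
#' @param calls A DMR call table with columns `chrom`, `start`, `end`,
#'   `direction`, `qvalue` (typically the `pass == TRUE` subset of
#'   [call_dmrs()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(calls, path) {
  stopifnot(all(c("chrom", "start", "end", "direction", "qvalue") %in%
                  names(calls)))
  score <- pmin(1000, round(-10 * log10(pmax(calls$qvalue, 1e-300))))
  score[calls$qvalue >= 1] <- 0
  out <- data.table::data.table(calls$chrom, calls$start, calls$end,
                                calls$direction, as.integer(score), ".")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
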