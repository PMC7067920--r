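# Feature annotation of DMRs: promoter (3 kb upstream of the TSS on the
# gene's strand), exon, intron; intergenic DMRs get the nearest gene by TSS
# distance. All coordinates are 0-based half-open.

#' Build a feature index from gene models
#'
#' Derives, per gene: the TSS (`tx_start` on +, `tx_end - 1` on -), the
#' promoter (the `promoter_bp` bases immediately upstream of the TSS on the
#' gene's strand, clipped at 0), the merged exons, and the introns (gaps
#' between consecutive exons within the transcript span).
#'
#' @param genes Gene model table from [read_gene_annotation()].
#' @param promoter_bp Promoter width upstream of the TSS (default 3000).
#' @return A list of class `feature_index`: `features` (data.table with
#'   chrom, start, end, feature, gene_id) and `tss` (data.table with chrom,
#'   pos, gene_id).
#' @export
build_feature_index <- function(genes, promoter_bp = 3000L) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- g$exons[[1L]]
    plus <- g$strand == "+"
    tss <- if (plus) g$tx_start else g$tx_end - 1L
    if (plus) {
      prom <- c(max(0L, tss - promoter_bp), tss)
    } else {
      # upstream of a - strand gene lies to the right: (tss, tss + bp]
      prom <- c(tss + 1L, tss + 1L + promoter_bp)
    }
    feats <- data.table::data.table(
      chrom = g$chrom,
      start = c(prom[1L], ex[, 1L]),
      end = c(prom[2L], ex[, 2L]),
      feature = c("promoter", rep("exon", nrow(ex))),
      gene_id = g$gene_id)
    if (nrow(ex) > 1L) {
      feats <- rbind(feats, data.table::data.table(
        chrom = g$chrom,
        start = ex[-nrow(ex), 2L], end = ex[-1L, 1L],
        feature = "intron", gene_id = g$gene_id))
    }
    feats[feats$start < feats$end, ]
  })
  features <- data.table::rbindlist(rows)
  data.table::setorderv(features, c("chrom", "start"))
  tss_tab <- data.table::data.table(
    chrom = genes$chrom,
    pos = ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L),
    gene_id = genes$gene_id)
  structure(list(features = features, tss = tss_tab),
            class = "feature_index")
}

#' Annotate DMRs against a feature index
#'
#' Any overlap of one base pair or more with a promoter, exon or intron
#' interval assigns that feature (a DMR spanning, say, a promoter and the
#' first exon carries both). DMRs overlapping no feature are intergenic and
#' get the nearest gene by TSS distance on the same chromosome: distance 0 if
#' a TSS lies inside the DMR, otherwise the gap in bp from the closest DMR
#' edge.
#'
#' @param dmrs A table of intervals with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. passing calls from [call_dmrs()].
#' @param index A `feature_index` from [build_feature_index()].
#' @return `data.table`, one row per DMR: input columns plus `features`
#'   (comma-separated subset of promoter/exon/intron), `gene_ids`
#'   (comma-separated), `intergenic`, `nearest_gene`, `tss_distance`.
#' @export
annotate_dmrs <- function(dmrs, index) {
  stopifnot(inherits(index, "feature_index"))
  dmrs <- data.table::as.data.table(dmrs)
  nd <- nrow(dmrs)
  features <- character(nd); gene_ids <- character(nd)
  nearest_gene <- rep(NA_character_, nd)
  tss_distance <- rep(NA_integer_, nd)
  intergenic <- rep(TRUE, nd)
  if (nd == 0L) {
    return(cbind(dmrs, features = character(), gene_ids = character(),
                 intergenic = logical(), nearest_gene = character(),
                 tss_distance = integer()))
  }
  feat <- index$features
  # shared seqlevels so findOverlaps never warns on index-absent chromosomes
  lev <- union(unique(dmrs$chrom), unique(feat$chrom))
  dgr <- GenomicRanges::GRanges(
    factor(dmrs$chrom, levels = lev),
    IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  if (nrow(feat) > 0L) {
    fgr <- GenomicRanges::GRanges(
      factor(feat$chrom, levels = lev),
      IRanges::IRanges(feat$start + 1L, feat$end))
    hits <- GenomicRanges::findOverlaps(dgr, fgr, minoverlap = 1L)
    if (length(hits) > 0L) {
      hdt <- data.table::data.table(
        d = S4Vectors::queryHits(hits),
        feature = feat$feature[S4Vectors::subjectHits(hits)],
        gene_id = feat$gene_id[S4Vectors::subjectHits(hits)])
      ford <- c(promoter = 1L, exon = 2L, intron = 3L)
      agg <- hdt[, list(
        features = paste(unique(feature[order(ford[feature])]),
                         collapse = ","),
        gene_ids = paste(sort(unique(gene_id)), collapse = ",")),
        by = "d"]
      features[agg$d] <- agg$features
      gene_ids[agg$d] <- agg$gene_ids
      intergenic[agg$d] <- FALSE
    }
  }
  tss <- index$tss
  for (i in which(intergenic)) {
    cand <- tss[tss$chrom == dmrs$chrom[i], ]
    if (nrow(cand) == 0L) {
      warning("no gene on chromosome ", dmrs$chrom[i],
              "; DMR left without nearest gene")
      next
    }
    # distance from the half-open interval [start, end) to the TSS point:
    # 0 inside, else the gap to the nearer interval boundary
    d <- pmax(0L, pmax(dmrs$start[i] - cand$pos, cand$pos - dmrs$end[i]))
    j <- which.min(d)
    nearest_gene[i] <- cand$gene_id[j]
    tss_distance[i] <- d[j]
  }
  cbind(dmrs,
        data.table::data.table(features = features, gene_ids = gene_ids,
                               intergenic = intergenic,
                               nearest_gene = nearest_gene,
                               tss_distance = tss_distance))
}
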