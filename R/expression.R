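# Relative gene-expression quantification from qPCR Ct values: delta-delta
# Ct with a reference gene, and a two-tailed two-sample t-test between age
# groups on the delta-Ct scale.

#' Read a long-format Ct table
#'
#' Tab-separated with header: `sample_id`, `group` (`young`/`old`), `gene`,
#' `ct` (positive, cycles; technical replicates pre-averaged).
#'
#' @param path Path to the TSV file.
#' @return `data.table` with those four columns.
#' @export
read_ct_table <- function(path) {
  ct <- data.table::fread(path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (anyDuplicated(ct[, c("sample_id", "gene")])) {
    stop("one Ct per (sample, gene) expected; average technical replicates")
  }
  ct[]
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample: `dCt = Ct(target) - Ct(reference)`;
#' `ddCt = dCt - mean(dCt over the control group)`; fold change
#' `2^(-ddCt)`. By construction the geometric mean of the control-group fold
#' changes is exactly 1, and fold changes are invariant to any per-sample
#' additive shift applied to both target and reference Cts.
#'
#' @param ct_table Long-format Ct table (see [read_ct_table()]).
#' @param target_gene Gene to quantify.
#' @param reference_gene Normalizer gene (default `"GAPDH"`).
#' @param control_group Baseline group for the second delta
#'   (default `"young"`).
#' @return List: `per_sample` (data.table with sample_id, group, dct, ddct,
#'   fold) and `group_summary` (mean fold and mean dCt per group).
#' @export
delta_delta_ct <- function(ct_table, target_gene,
                           reference_gene = "GAPDH",
                           control_group = "young") {
  ct_table <- data.table::as.data.table(ct_table)
  tgt <- ct_table[ct_table$gene == target_gene]
  ref <- ct_table[ct_table$gene == reference_gene]
  if (nrow(tgt) == 0L) stop("no Ct values for target gene ", target_gene)
  miss <- setdiff(tgt$sample_id, ref$sample_id)
  if (length(miss) > 0L) {
    stop("missing reference-gene Ct for sample(s): ",
         paste(miss, collapse = ", "))
  }
  d <- merge(tgt[, c("sample_id", "group", "ct")],
             ref[, c("sample_id", "ct")],
             by = "sample_id", suffixes = c("_target", "_ref"))
  d$dct <- d$ct_target - d$ct_ref
  ctrl <- d$group == control_group
  if (!any(ctrl)) stop("no samples in control group '", control_group, "'")
  d$ddct <- d$dct - mean(d$dct[ctrl])
  d$fold <- 2^(-d$ddct)
  per_sample <- d[, c("sample_id", "group", "dct", "ddct", "fold")]
  fold <- dct <- NULL  # NSE guard
  summary <- per_sample[, list(mean_fold = mean(fold),
                               mean_dct = mean(dct), n = .N),
                        by = "group"]
  list(per_sample = per_sample[], group_summary = summary[])
}

#' Two-tailed t-test of delta-Ct between groups
#'
#' Student's pooled-variance two-sample t-test (Welch optional) on the
#' per-sample `dCt` values of a target gene, old versus young. Testing on
#' the dCt scale makes the result independent of which group anchors the
#' delta-delta normalization.
#'
#' @inheritParams delta_delta_ct
#' @param var_equal Use the pooled-variance (Student) test (default TRUE);
#'   FALSE gives Welch.
#' @return List: `t` (old minus young), `df`, `p_value`, `mean_dct_young`,
#'   `mean_dct_old`.
#' @export
group_ttest <- function(ct_table, target_gene, reference_gene = "GAPDH",
                        var_equal = TRUE) {
  dd <- delta_delta_ct(ct_table, target_gene, reference_gene)
  d <- dd$per_sample
  young <- d$dct[d$group == "young"]
  old <- d$dct[d$group == "old"]
  if (length(young) < 2L || length(old) < 2L) {
    stop("need at least 2 samples per group")
  }
  if (stats::var(young) == 0 && stats::var(old) == 0) {
    if (mean(young) == mean(old)) stop("degenerate input: both groups constant")
  }
  tt <- stats::t.test(old, young, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_dct_young = mean(young), mean_dct_old = mean(old))
}
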