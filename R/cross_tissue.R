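# Cross-tissue analysis: DMRs shared between two tissues in the same window
# with the same direction, and a permutation null for the shared count.

#' Find DMRs shared between two tissues
#'
#' Matches passing DMR calls from two tissues by exact window coordinates
#' (same chrom, start, end) and keeps those whose direction (hyper/hypo)
#' agrees. Both call sets must derive from the same window grid.
#'
#' @param calls_a,calls_b [call_dmrs()] output for the two tissues.
#' @return A list of class `shared_dmr_set`: `shared` (data.table of shared
#'   windows with the per-tissue methylation differences and q-values),
#'   `n_shared_hyper`, `n_shared_hypo`, `n_shared_total`.
#' @export
find_shared_dmrs <- function(calls_a, calls_b) {
  stopifnot(all(c("chrom", "start", "end", "direction", "pass") %in%
                  names(calls_a)),
            all(c("chrom", "start", "end", "direction", "pass") %in%
                  names(calls_b)))
  a <- data.table::as.data.table(calls_a)[calls_a$pass == TRUE]
  b <- data.table::as.data.table(calls_b)[calls_b$pass == TRUE]
  m <- merge(a[, c("chrom", "start", "end", "direction", "meth_diff",
                   "qvalue")],
             b[, c("chrom", "start", "end", "direction", "meth_diff",
                   "qvalue")],
             by = c("chrom", "start", "end"), suffixes = c("_a", "_b"))
  m <- m[m$direction_a == m$direction_b]
  data.table::setnames(m, "direction_a", "direction")
  m$direction_b <- NULL
  data.table::setorderv(m, c("chrom", "start"))
  structure(list(shared = m[],
                 n_shared_hyper = sum(m$direction == "hyper"),
                 n_shared_hypo = sum(m$direction == "hypo"),
                 n_shared_total = nrow(m)),
            class = "shared_dmr_set")
}

#' @export
print.shared_dmr_set <- function(x, ...) {
  cat("shared DMRs: ", x$n_shared_total, " (", x$n_shared_hyper, " hyper, ",
      x$n_shared_hypo, " hypo)\n", sep = "")
  invisible(x)
}

#' Permutation null for the shared-DMR count
#'
#' Per replicate, draws `n_a` and `n_b` windows uniformly without replacement
#' from a universe of `universe_size` analyzed windows, assigns each drawn
#' set exactly the observed numbers of hyper- and hypomethylated regions, and
#' counts the windows selected in both draws with matching direction. With
#' `split_a`/`split_b` omitted the test is direction-agnostic (any common
#' window counts). The p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + reps)`, so it is never exactly 0.
#'
#' Replicate r draws from a generator seeded deterministically by
#' `(seed, r)`, so the null distribution is reproducible and independent of
#' execution order.
#'
#' @param universe_size Number of windows in the analyzed universe.
#' @param n_a,n_b Number of regions selected per tissue.
#' @param split_a,split_b Length-2 integer vectors `(n_hyper, n_hypo)`
#'   summing to `n_a` / `n_b`, or NULL for direction-agnostic mode.
#' @param observed Observed shared count to test.
#' @param reps Number of permutation replicates (default 1000).
#' @param seed Integer seed.
#' @return A list of class `permutation_null`: inputs, `null_counts`
#'   (integer vector of length `reps`), `null_mean`, `null_sd`, `q95`
#'   (95th percentile), `p_value`.
#' @export
permutation_test <- function(universe_size, n_a, n_b, split_a = NULL,
                             split_b = NULL, observed, reps = 1000L,
                             seed = 1L) {
  stopifnot(universe_size > 0L, n_a <= universe_size, n_b <= universe_size,
            observed >= 0L, reps >= 1L)
  if (!is.null(split_a) && sum(split_a) != n_a) {
    stop("split_a must sum to n_a")
  }
  if (!is.null(split_b) && sum(split_b) != n_b) {
    stop("split_b must sum to n_b")
  }
  dir_a <- if (is.null(split_a)) rep(1L, n_a) else
    rep(c(1L, -1L), times = split_a)
  dir_b <- if (is.null(split_b)) rep(1L, n_b) else
    rep(c(1L, -1L), times = split_b)
  agnostic <- is.null(split_a) && is.null(split_b)
  if (exists(".Random.seed", envir = globalenv())) {
    old_rng <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_rng, envir = globalenv()))
  }
  null_counts <- integer(reps)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    sel_a <- sample.int(universe_size, n_a)
    sel_b <- sample.int(universe_size, n_b)
    hit <- match(sel_b, sel_a)
    ok <- !is.na(hit)
    null_counts[r] <- if (agnostic) sum(ok) else
      sum(dir_a[hit[ok]] == dir_b[ok])
  }
  p <- (1 + sum(null_counts >= observed)) / (1 + reps)
  structure(list(universe_size = universe_size, n_a = n_a, n_b = n_b,
                 split_a = split_a, split_b = split_b, reps = reps,
                 seed = seed, observed = observed,
                 null_counts = null_counts,
                 null_mean = mean(null_counts),
                 null_sd = stats::sd(null_counts),
                 q95 = unname(stats::quantile(null_counts, 0.95,
                                              type = 1L)),
                 p_value = p),
            class = "permutation_null")
}

# one RNG stream per replicate, a deterministic function of (seed, r)
derive_seed <- function(seed, r) {
  (as.numeric(seed) * 7919 + r * 104729) %% 2147483647
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("permutation null (", x$reps, " reps): observed = ", x$observed,
      ", null mean = ", signif(x$null_mean, 4), " sd = ",
      signif(x$null_sd, 4), ", 95th pct = ", x$q95,
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Expected random overlap of two region sets
#'
#' Closed-form expectation `n_a * n_b / universe_size` of the number of
#' windows common to two uniform draws without replacement; the
#' direction-agnostic permutation null converges to it.
#'
#' @inheritParams permutation_test
#' @return Numeric scalar.
#' @export
analytic_expected_overlap <- function(universe_size, n_a, n_b) {
  stopifnot(universe_size > 0L, n_a <= universe_size, n_b <= universe_size)
  n_a * n_b / universe_size
}
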