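---
title: "Models and methods behind dmrshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dmrshare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dmrshare)
```

This vignette is the package's own account of its statistics: the models,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations.

## The data and its reduction

The unit of input is a Bismark-style coverage file: one line per CpG with
methylated and unmethylated read counts. Counts are the sufficient
statistic for every model in the package, so the percentage column of the
input is ignored and recomputed on output. Coverage positions are 1-based;
everything else in the package (windows, gene models, BED output) is
0-based half-open, and the conversion happens exactly once at the I/O
boundary — a single convention prevents off-by-one drift.

Strand is not tracked per CpG. Coverage files may or may not be
destranded upstream, and sites are treated as strand-symmetric; if your
extractor reports strands separately, merge them before input.

Two reductions are computed:

* a **site matrix** of methylation proportions at CpGs covered ≥ 10× in
  *every* sample (`min_site_coverage`), used for sample PCA. PCA centers
  sites but does not scale them: proportions already share a scale, and
  unit-variance scaling would inflate near-constant sites.
* **window counts**: counts pooled over the CpGs inside 1,000-bp
  non-overlapping windows (`window_size`), anchored at coordinate 0 per
  chromosome — a fixed origin is what makes "non-overlapping tiling"
  well-defined. A window enters the analysis only if every sample has
  ≥ 10 summed reads (`min_window_coverage`) *and* ≥ 3 covered CpGs
  (`min_cpgs`); the coverage floor stabilizes the regression, the CpG
  floor keeps single-CpG windows from masquerading as regions.

Pooling counts (rather than averaging per-CpG rates) is a deliberate
choice: the pooled proportion is the natural sufficient statistic for the
binomial regression downstream, whereas a mean of rates weights a 2-read
CpG equally with a 60-read one. The same choice applies to the reported
methylation difference: `meth_diff` is the difference of *pooled* group
proportions, in percentage points, old minus young.

## The per-window test

For window $w$ with per-sample methylated counts $y_s$ out of $n_s$
trials, the model is binomial-logistic:

$$ y_s \sim \mathrm{Bin}(n_s, \pi_s), \qquad
   \mathrm{logit}\,\pi_s = \beta_0 + \beta_a\,\mathrm{age}_s
   + \gamma^\top \mathrm{run}_s $$

The null model drops $\beta_a$. Both are fitted by IRLS and compared with
the likelihood-ratio statistic $\Lambda = 2(\ell_1 - \ell_0)$, referred to
$\chi^2_1$. With no covariate this collapses to the classic 2×2 G-test on
pooled counts, which the test suite checks to 1e-6.

**Overdispersion.** Biological replicates scatter more than binomial
sampling allows. Each window gets
$\hat\varphi = X^2_{\mathrm{Pearson}} / (n_{\mathrm{samples}} - p)$ from
the fitted alternative model, floored at 1, and the corrected statistic is
$\Lambda / \hat\varphi$. The floor means the correction can only make
calls harder, never easier. Two consequences worth knowing:

* under truly binomial data, $\hat\varphi$ scatters around 1 and the floor
  keeps the upper half of that scatter, so corrected null p-values are
  mildly *conservative* (about 3.7% of null windows below p = 0.05 at a
  nominal 5% in the package's own null simulations; a KS uniformity test
  at 5,000 windows reliably rejects). The uncorrected statistic is
  calibrated; the conservatism is the price of the safety floor and errs
  against false positives. The type-I criterion in the acceptance suite
  documents this as an expected red on the KS clause while the
  call-fraction clause (≤ 1% of null windows called) passes with margin.
* $\hat\varphi$ is estimated per window, not shrunk across windows —
  shrinkage would be a different method. With 12 samples and 3 parameters
  the estimate is noisy; the floor is what keeps that noise one-sided.

**Numerical choices.** IRLS runs at most 100 iterations to a relative
log-likelihood tolerance of 1e-8; coefficients are clamped to |β| ≤ 20 so
complete separation (e.g. a group at 0% methylation) stays finite — at
that clamp the fitted proportions are within 2e-9 of the boundary, so the
likelihood is numerically saturated. A window that fails to converge is
reported with p = 1 and flagged, never dropped silently and never allowed
to manufacture significance. Windows where one group has zero total
coverage have no defined difference and are dropped with a warning.

## SLIM q-values

P-values are converted to q-values with a Storey-type estimator of the
null proportion $\pi_0$. The survival curve $1 - \widehat F(\lambda)$ is
evaluated on the grid $\lambda = 0.01, \dots, 0.95$; under a pure null it
is the line $\pi_0(1 - \lambda)$, and true effects bend it upward only
near 0. For every candidate cut point the points at $\lambda \ge$ cut are
fitted by ordinary least squares; the cut with the smallest mean squared
residual marks the start of the linear regime, and $\pi_0$ is the negated
slope there, clamped to [0, 1]. Candidate cuts keep at least 10 grid
points so a short tail cannot win on spuriously perfect fit. Then

$$ q_{(i)} = \min_{j \ge i} \frac{\pi_0\, m\, p_{(j)}}{j} \wedge 1 $$

— the usual step-up, with ties resolved by the stable sort so tied
p-values share the q of their last rank. With $\pi_0 = 1$ this is exactly
Benjamini–Hochberg, which is both a config option (`correction = "bh"`)
and an acceptance identity. DMR status is `q < 0.05` and
`|meth_diff| > 10` points, both strict.

## Annotation

Promoters are the 3 kb immediately upstream of the TSS on the gene's
strand (`promoter_bp`): $[TSS-3000, TSS)$ on +, the mirrored interval on
−, clipped at 0. Introns are derived as the gaps between merged exons —
they are not stored, which avoids redundant invariants. Any overlap of
≥ 1 bp assigns a feature, and a DMR can carry several (promoter and first
exon, say) and several genes; promoters are not clipped against
neighboring gene bodies because no such rule is part of the definition.
Multi-transcript genes collapse to one model — outermost span, union of
exons, one TSS — so "promoter" is a per-gene, not per-transcript, notion
here. Intergenic DMRs get the nearest gene by TSS distance, measured from
the nearer edge of the window (0 if the TSS lies inside). Overlap and
nearest queries run on IRanges/GenomicRanges; the test suite checks them
against a quadratic all-pairs oracle.

## Cross-tissue sharing and the permutation null

Two tissues' DMRs are *shared* when the same window (exact grid match)
passes in both with the same direction. Exact matching is appropriate
because both analyses run on the same 0-anchored grid; fuzzy matching
would quietly redefine "same location".

Significance of the shared count: draw $n_A$ and $n_B$ windows uniformly
without replacement from the universe of analyzed windows, assign each
draw exactly the observed hyper/hypo split, count direction-matched
overlaps, repeat (1,000 reps by default). The p-value uses the add-one
estimator $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + R)$, so it is
never exactly 0 at finite replicates. The universe defaults to the union
of both tissues' tested windows — the two grids differ slightly through
per-tissue coverage filters, and the union is the set of windows that
could in principle have been selected in either analysis. Each replicate
draws from a generator seeded deterministically by (seed, replicate), so
the null is reproducible and independent of execution order; the
direction-agnostic and direction-matched modes share draws under the same
seed, which is what makes "matching can only remove overlaps" testable
replicate by replicate. The direction-agnostic null mean has the closed
form $n_A n_B / N$ (at the published sizes, $1528 \cdot 740 / 96000 =
11.7783$), which serves as the engine's analytic oracle.

## ΔΔCt expression analysis

Per sample, $\Delta Ct = Ct_{\mathrm{target}} - Ct_{\mathrm{ref}}$;
$\Delta\Delta Ct$ subtracts the control-group mean; fold $= 2^{-\Delta\Delta Ct}$.
Two identities follow by construction and are asserted exactly: the
geometric mean of control-group folds is 1, and folds are invariant to any
per-sample shift applied to both genes (loading/efficiency offsets
cancel). The group comparison is a two-tailed Student (pooled-variance)
t-test on the $\Delta Ct$ scale — approximately normal, unlike folds, and
independent of which group anchors the second delta; Welch is available
via `var_equal = FALSE`. Technical replicates are averaged upstream of the
input table. Efficiency-corrected (Pfaffl) quantification and
multi-reference normalization are out of scope.

## The synthetic world

`sim_config()` states the emulated design; its defaults *are* the
experiment the analysis assumes, and they are not tuned per test:

| parameter | default | meaning |
|---|---|---|
| `n_per_group` | 6 | animals per age group per tissue |
| `tissues` | hippocampus, blood | two tissues, same genome |
| `n_windows` | 5,000 | 1,000-bp windows across 2 chromosomes |
| `cpg_mean` | 8 | CpGs per window, 3 + Poisson(5) |
| `coverage_mean`, `coverage_disp` | 30, 5 | NB read depth per CpG |
| baseline | Beta(1,10)/Beta(10,1), 50/50 | bimodal CpG landscape |
| `rho` | 0.02 | beta-binomial within-group dispersion |
| `dmr_fraction`, `effect_size` | 2%, 30 pts | planted DMRs |
| `shared_fraction` | 10% of planted | cross-tissue shared, same direction |
| `shared_promoter_count` | 5 | shared hyper DMRs hosted in promoters |
| `batch_logit_shift` | 0.1 | run-2 logit shift (run covariate's target) |
| `dct_shift` | (1, 1, 1, 0.4, 0) | true ΔCt shifts of the five genes |

Counts are deliberately *richer* than the model the test assumes:
per-sample window proportions are beta-binomial around the group mean, so
the overdispersion correction has something to correct, and run-2 samples
get a logit shift so the covariate has something to absorb. Effects are
applied on the probability scale with clipping to [0.01, 0.99] — the DMR
threshold is in percentage points, so direct control of Δ matters more
than logit additivity — and planted baselines are squeezed into a range
where the full ±Δ fits, so realized effects equal nominal ones. Windows
with three or more CpGs everywhere are the testable population, so the
CpG count is drawn as 3 + Poisson; planted and gene-hosting windows sit
on a stride-7 grid away from chromosome edges so a placed gene's 3-kb
promoter and 2-kb body never touch an unrelated planted window, and the
two tissues' non-shared planted sets are disjoint so "shared" in the
truth table is unambiguous. Determinism is a contract: one seed fixes
every emitted byte.

What the generator does **not** emulate — and what a green test therefore
does not establish: genomic CpG clustering and islands (CpG positions are
uniform within windows), spatial autocorrelation of methylation between
neighboring windows, MspI fragment-based coverage structure, bisulfite
conversion error, chromosome-scale genomes, and any real enrichment of
DMRs near functional elements. In particular the permutation null's
exchangeability assumption (uniform draws over windows) is exactly true in
this synthetic world, while in real genomes clustering makes it optimistic
— a circular-shift null would be the stricter choice there, and is out of
scope here as it was in the original design.

## Known limitations

* Per-window $\hat\varphi$ with 12 samples is noisy; the floor makes the
  test conservative rather than liberal (see above), and no information is
  shared across windows.
* The logistic LRT tests pooled proportions; a beta-binomial regression
  would model replicate scatter directly instead of post-hoc deflation.
* Exact-grid matching of shared DMRs cannot see effects that straddle a
  window boundary in one tissue.
* SLIM's $\pi_0$ is a tail-slope estimate; on very small m (tens of
  windows) it is unstable, and `correction = "bh"` is the safer setting.
* One Ct per (sample, gene) is assumed; replicate handling is upstream.
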