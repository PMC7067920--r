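# dmrshare

Windowed differential-methylation analysis of RRBS count data, with
cross-tissue DMR sharing and a permutation significance test.

## What it is for

Reduced-representation bisulfite sequencing (RRBS) yields, per sample, a
table of CpG sites with methylated/unmethylated read counts (Bismark
coverage files). A recurring study design compares an *old* and a *young*
group in two tissues — e.g. hippocampus and peripheral blood — and asks
which genomic regions change methylation with age, and whether changes seen
in blood mirror those in the brain, where they would be clinically
inaccessible. `dmrshare` implements that analysis end to end for anyone
working with Bismark-style coverage files:

1. **Tiling** — CpG counts are pooled into 1,000-bp non-overlapping windows
   (anchored at coordinate 0); windows need ≥ 10× summed coverage and ≥ 3
   covered CpGs in every sample. A separate 10×-in-all-samples CpG matrix
   feeds a sample-level PCA.
2. **Per-window test** — binomial logistic regression of the methylated
   proportion on the age group, with sequencing run as a covariate, fitted
   by IRLS. The statistic is the likelihood-ratio chi-square
   `Λ = 2(ℓ₁ − ℓ₀)` on 1 df; a per-window overdispersion factor
   `φ = X²_Pearson / (n − p)` (floored at 1) deflates it: `Λ/φ ~ χ²₁`.
3. **Multiple testing** — SLIM q-values: the null proportion π₀ is
   estimated from the linear tail of the p-value survival curve by a
   sliding linear model, then `q₍ᵢ₎ = min_{j≥i} π₀ m p₍ⱼ₎ / j`.
   DMRs are windows with q < 0.05 and |Δmethylation| > 10 points.
4. **Annotation** — promoter (3 kb upstream of the TSS, strand-aware),
   exon, intron; intergenic DMRs get the nearest gene and TSS distance.
5. **Cross-tissue sharing** — DMRs in the same window with the same
   direction in both tissues; significance of the shared count is assessed
   against a permutation null (random region sets of the observed sizes and
   direction splits drawn from the analyzed-window universe).
6. **Expression** — ΔΔCt qPCR quantification against a reference gene
   (fold = 2^−ΔΔCt) and a two-tailed t-test on ΔCt.
7. **Synthetic data** — a generator that emits complete experiments
   (coverage files, GTF, metadata, Ct table) with planted DMRs of known
   direction, sharing status and effect size, for validation.

## Worked example

Simulate a two-tissue experiment (6 young vs 6 old per tissue, two
sequencing runs, 3,000 windows, 2% planted DMRs at ±30 points, five shared
hypermethylated DMRs placed in promoters), then run the full analysis:

```r
library(dmrshare)

cfg <- sim_config(seed = 42, n_windows = 3000)
sim <- simulate_experiment(cfg, "simdemo")

rc <- run_config(coverage_dir = "simdemo/coverage",
                 metadata   = "simdemo/samples.tsv",
                 annotation = "simdemo/annotation.gtf",
                 ct_table   = "simdemo/ct_table.tsv",
                 out_dir    = "rundemo", perm_reps = 200)

ra <- run_tissue_analysis(rc, "hippocampus")
rb <- run_tissue_analysis(rc, "blood")
ct <- run_cross_tissue(rc, ra, rb)
print(ct$perm)
#> permutation null (200 reps): observed = 6, null mean = 0.665 sd = 0.864,
#>   95th pct = 2, p = 0.004975

evaluate_recovery(sim$truth,
                  list(hippocampus = ra$calls, blood = rb$calls),
                  ct$shared)
#>            set n_planted n_called sensitivity        fdr direction_accuracy
#> 1: hippocampus        60       65           1 0.07692308                  1
#> 2:       blood        60       60           1 0.00000000                  1
#> 3:      shared         6        6           1 0.00000000                  1

run_expression(rc)
#>      gene mean_fold_old          t    df     p_value
#> 1: sgene1     0.6632390 3.36774923    10 0.007148454
#> 2: sgene2     0.5018771 3.91034858    10 0.002911633
#> 3: sgene3     0.4768592 5.08537777    10 0.000474044
#> 4: sgene4     1.0034814 0.09771476    10 0.924089603
#> 5: sgene5     0.9669865 0.53376094    10 0.605167634
```

Reading the output: all 60 planted DMRs per tissue are recovered with a
false-discovery proportion at or under 8% and every recovered direction
correct; the 6 planted cross-tissue DMRs are found (5 hyper, 1 hypo)
against a permutation null whose 95th percentile is 2, so the shared count
is significant (p ≈ 0.005 at 200 reps); the promoter-shared gene list is
exactly the five planted genes; and the three genes planted with a +1-cycle
ΔCt shift show ~2-fold repression at p < 0.01 while the null gene does not.

A command-line wrapper with `simulate` / `analyze` / `cross` /
`expression` / `all` subcommands is installed at
`system.file("cli", "dmrshare", package = "dmrshare")`.

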