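# tfscope

Time-course analysis of two-color (competitive hybridization) microarray
experiments, built around the **Total Flag Sum (TFS)** classification of
temporal expression responses.

The motivating setting is a toxicogenomic time course: cells exposed to a
chemical at two concentrations, profiled against vehicle controls at 3 h,
8 h and 24 h on two-color arrays with dye-swap replicates. The questions
the package answers are the ones such a design poses:

* which transcripts respond, under a combined fold-change + p-value filter
  with an empirical ("apparent") false discovery rate;
* *when* they respond — early (3 h), mid (8 h) or late (24 h), and whether
  the response is transient, sustained or persistent;
* what global structure the six arrays share (PCA of the standardized
  ratio matrix by SVD);
* whether promoters of responsive genes are enriched for sequence motifs
  relative to expression-defined background gene sets;
* whether array fold changes validate by comparative-Ct (ΔΔCt) qPCR.

Every stage can be exercised on synthetic experiments with planted ground
truth (`sim_config()` / `simulate_experiment()`), so the whole pipeline is
testable without external data.

## The statistics at the core

**Combined filter and apparent FDR.** For each concentration, the
per-dataset ratio cutoff is `mean + 2·SD` of the pooled signed log2 ratios,
applied to |log2 ratio| and intersected with `p < 0.005` (no Bonferroni/Holm
correction). With `n_fc` probes passing the ratio filter alone and `n_both`
passing both, the expected-by-chance count is `round(0.005 · n_fc)` and the
apparent FDR is `expected / n_both`. The package reproduces the worked
arithmetic `apparent_fdr(0.005, 5031, 3912)` → 25 expected, 0.64 %.

**Total Flag Sum.** Arrays where a gene meets the combined threshold
contribute binary flags 1, 2, 4 (or 1…32 for the six-array two-concentration
design); decimal digits record direction per array (1 = up, 2 = down,
0 = none). `(up, up, none)` encodes as `"3.110"`, `(down, down, none)` as
`"3.220"`. Codes are exact strings, never floats. `classify_subgroup()`
maps the 27 three-array call patterns onto the early/mid/late ×
transient/sustained/persistent taxonomy (plus `mixed/unclassified` and
`null`).

**PCA.** The selected genes' log2 ratios are standardized per gene
(mean 0, SD 1 across the M arrays) and decomposed as `A = U Σ Vᵀ`; scores
are `X = U Σ` and component k explains `σₖ² / Σσⱼ²` of the variance.

**Motif analysis.** De novo discovery uses a ZOOPS (zero-or-one occurrence
per sequence) Gibbs site sampler with pseudocount 0.25 and best-of-k
restarts; promoters are scanned on both strands with log2-odds PWM scores;
enrichment of motif-bearing genes in a response set versus an
expression-defined background (expressed-but-unresponsive, or
non-expressed) is tested with a one-sided Fisher exact test, reported with
the enrichment score `(a/(a+b)) / (c/(c+d))`.

## Worked example

```r
library(tfscope)

cfg <- sim_config(n_genes = 2000, n_redundant_probes = 150, seed = 42)
res <- run_pipeline(cfg)

res$fdr
#> Combined-filter FDR report
#>   ratio-filter pass: 292
#>   combined pass:     281
#>   expected by chance: 1
#>   apparent FDR:      0.36%

subset(res$census, n > 0)[1:4, ]
#>               subgroup  n
#> 1   early transient up 41
#> 2   early sustained up 20
#> 3  early persistent up 20
#> 4 early transient down 38

res$pca
#> SVD of 287 x 6 standardized ratio matrix
#> variance fractions: 38.1%, 36.5%, 22.0%, 1.9%, 1.4%, 0.0%

res$motif$pwm$consensus
#> [1] "TGACGTCA"
res$enrichment
#> Motif enrichment: target 214/271 vs background 101/933 | score 7.29 |
#>   one-sided Fisher p = 8.37e-103
```

Reading the output: of 2,150 probes, 281 pass the combined filter (~the
280 planted responders; the apparent FDR estimates ~1 chance passer). The
census recovers the planted subgroup sizes (each response archetype was
planted in 1 % of 2,000 genes; "early transient" unions two planted
patterns). The first principal components separate the time trend from the
concentration difference. The Gibbs sampler recovers the planted CRE-like
consensus `TGACGTCA` exactly, and its enrichment in responsive-gene
promoters (planting rates 0.8 vs 0.1) is overwhelming. A qPCR table for
example responders validates the planted 4-fold change:

```r
res$qpcr[[1]][c("gene_id", "fold_change", "se")]
#> $gene_id   [1] "gene00008"
#> $fold_change [1] 4.07
#> $se        [1] 0.28
```

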