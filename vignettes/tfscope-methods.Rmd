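---
title: "tfscope: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tfscope: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfscope)
```

This vignette is the package's account of its science: the models each
stage assumes, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the choices made where the design
was genuinely open.

## The experimental design being modeled

A two-color competitive hybridization measures, per probe, the intensity
ratio of treated versus control RNA on one array. The design served by
this package is a time course — exposures of 3, 8 and 24 h at a high and a
low concentration, six comparisons in all — with a dye-swap replicate per
comparison (treated and control labels exchanged), so that systematic dye
bias can be cancelled by averaging sign-flipped ratios.

## Data conditioning

**MA normalization** (`ma_normalize()`). Within-array intensity-dependent
ratio bias is removed by subtracting a loess fit of the log2 ratio against
the mean log intensity `A = (log2 ch1 + log2 ch2)/2`, delegated to
`limma::loessFit` (span 0.4 by default, the usual neighborhood for
whole-genome arrays). The correction is a vertical shift at fixed `A`, so
it preserves the rank order of ratios at any fixed intensity.

**Dye-swap combination** (`combine_dye_swap()`). The original analysis
chain combined dye swaps inside a proprietary error model. The package's
documented scheme: flip the reverse (control-vs-treated) ratios onto the
treated-vs-control scale, then take the inverse-variance weighted mean,
with the combined p-value from the two-sided normal tail of
`z = weighted mean / SE(weighted mean)`. When per-probe ratio variances
are absent the combination falls back to equal weights with a warning.
Equivalence with the original proprietary weighting cannot be verified;
the substitute is exact under the generator's error model and symmetric
under exchange of the two array roles.

**Redundant-probe collapse** (`collapse_redundant_probes()`). Probes
sharing a gene accession *and* an identical ternary call pattern across
all conditions are collapsed to one representative. "Same pattern of
expression" is operationalized as identical up/none/down calls — the
quantity the downstream classification actually consumes. The
representative is the probe with the highest mean signal intensity across
conditions (the brightest probe is typically the most reliable; the
choice is otherwise arbitrary and is applied deterministically). Probes
that share an accession but differ in pattern are all retained, so an
accession never loses its last probe.

## The combined filter and the apparent FDR

The per-dataset ratio cutoff (`ratio_sd_threshold()`) is
`mean + k·SD` (default `k = 2`) of the **pooled signed** log2 ratios of
one concentration's three arrays, applied to |log2 ratio|. Pooled-signed
is one of several readings (per-array and absolute-value variants exist);
pooling gives a single per-dataset threshold, matching the downstream use
of one fold-change equivalent per concentration, and a per-array mode is
available (`per_array = TRUE`). With typical near-symmetric ratio
distributions the mean is near zero and the threshold is essentially
`k·SD`; the value is reported nonnegative since it cuts an absolute
ratio.

Calls (`call_significance()`) intersect the ratio cutoff with `p < alpha`
(default 0.005). No family-wise correction is applied — deliberately, as
such corrections remove most true positives in this regime; instead the
**apparent FDR** (`apparent_fdr()`) reports
`round(alpha · n_fc_pass) / n_combined_pass`: of the probes whose fold
change is large, `alpha` of them would be expected to pass the p-filter
by chance if p-values were independent of the ratio filter. That
independence is an approximation — any test statistic couples the two —
so the quantity is an *apparent*, not a calibrated, FDR; the package
reproduces its arithmetic exactly (`apparent_fdr(0.005, 5031, 3912)` →
25 expected, 0.64 %) and separately verifies that the p-values themselves
are calibrated on null simulations.

## Total Flag Sum and the temporal taxonomy

`encode_tfs()` assigns binary flags 1, 2, 4 to the three arrays a gene
passes, and decimal digits for direction (1 up, 2 down, 0 none):
`(up, up, none)` → `"3.110"`. The six-array extension uses flags 1–32 for
the two-concentration design, with the high-concentration block first (a
convention, switchable by reordering inputs; recorded in the code
as the stated argument order). Two numerical choices matter:

* **Codes are strings, never floats.** Decimal flag sums like
  `0.1 + 0.01` are not exactly representable in binary floating point;
  exact string handling makes `decode_tfs(encode_tfs(x)) = x` an identity
  over all 27 and 729 patterns, and inconsistent codes (digit pattern
  contradicting the binary sum, e.g. `"3.101"`) are rejected as integrity
  errors rather than silently reinterpreted.
* A gene significant at all three arrays has binary sum `1 + 2 + 4 = 7`,
  i.e. codes `7.111`/`7.222` for the persistent groups. Published usage
  of this flag system has sometimes printed those groups as
  `3.111`/`3.222`, which contradicts the flag arithmetic; this package
  follows the arithmetic. The sustained codes `3.110`/`3.220` are
  self-consistent and anchor the tests.

`classify_subgroup()` is a total function of the call triple: early/mid/
late by the first passing time point; transient/sustained/persistent by
how long the response lasts (an early response that vanishes at 8 h stays
"transient" even if it recurs at 24 h — both patterns appear in the
taxonomy's transient rows); any sign reversal across called time points
is `mixed/unclassified` (such patterns belong to no taxonomy row);
all-none is `null`. The 14 single-direction rows, `null` and the 12
reversal patterns partition the 27 ternary patterns — checked
exhaustively in the tests.

## PCA by SVD

Genes with at least one call in any of the six conditions are selected;
their log2 ratios are standardized per gene to mean 0 and SD 1 across
arrays (zero-variance genes are dropped with a warning, since their
standardization is undefined), and the matrix is decomposed as
`A = U Σ Vᵀ` with scores `X = U Σ` and variance fractions `σₖ²/Σσⱼ²`.
SVD signs are indeterminate per component; the package fixes them by
making the largest-magnitude loading of each `V` column positive, so
loadings and scores are platform-reproducible. The observed variance
split on any particular dataset is data-dependent and is not treated as a
reference value.

## Promoter motif analysis

**Discovery** (`gibbs_motif_discovery()`): a textbook ZOOPS Gibbs site
sampler — the same algorithmic family as the motif-discovery tool the
original analysis chain used, re-implemented openly. Per sweep each
sequence is held out, a PWM is rebuilt from the remaining assigned sites
(pseudocount 0.25 per base, background = 0-order composition of the input
set), and the held-out sequence samples a site position ∝ likelihood
ratio, or "no site" with prior `1 − site_prior` (default 0.5). Every 10
sweeps a ±1 phase-shift move is accepted if it raises information
content; a restart stops after `patience = 25` sweeps without improvement
or `max_iter = 150`; the best assignment over `n_restarts = 10` restarts
(by information content, in bits) wins. The sampler is seed-deterministic.

**Scanning** (`scan_promoters()`): both strands, log2-odds against the
PWM's background, gene-level binarization ("has the motif" = any window
at or above the threshold) to match the gene-level 2×2 enrichment design.
Positions are 0-based forward-strand starts. A threshold of ~12 bits for
an 8-base near-exact PWM admits only exact consensus matches (~15.6 bits)
and rejects single mismatches (~9–10 bits).

**Backgrounds** (`build_background_sets()`): two expression-defined
control sets — expressed-but-unresponsive (mean control-channel intensity
> 200, |fold change| < 1.2 at every time point) and non-expressed
(intensity < 50, same quietness bound). The fold-change bound is read on
the linear scale, |log2 ratio| < log2 1.2, and intensity is summarized as
the control-channel mean across the three arrays (the concrete reading of
"microarray signal intensity"). The sets are disjoint by construction;
an empty set triggers a warning and is refused by the enrichment step.

**Enrichment** (`motif_enrichment_test()`): one-sided (greater) Fisher
exact p on the 2×2 table, plus an enrichment score defined as the ratio
of hit proportions `(a/(a+b)) / (c/(c+d))` — the score's exact definition
was open and this proportion-ratio reading is labeled as the package's
own. `ora_test()` provides the analogous generic hypergeometric
over-representation test for annotation terms, with optional
Benjamini–Hochberg adjustment clearly labeled as an extension.

## The synthetic-data generator

`simulate_experiment()` emulates the design, not the physics, of a
two-color platform:

* **Baseline intensities** are log2-normal (mean 10, SD 1.5 log2 units —
  bright, well-measured probes dominate, as on whole-genome platforms).
* **Noise** is two-component: multiplicative on log ratios
  (SD 0.25 log2 units) plus additive channel noise (SD 30 intensity
  units) whose delta-method contribution
  `(σ_add²/ln²2)(1/I_t² + 1/I_c²)` inflates the ratio variance of dim
  probes. The observed ratio is drawn Gaussian with exactly this total
  variance, and the same variance is reported per probe, so the
  substitute error model's p-values are exactly calibrated under the
  null — a property the calibration tests rely on. Channel intensities
  carry the additive noise for display and for the background-set logic;
  they are not re-used to recompute the ratio.
* **Dye bias** (default 0.3 log2 units) attaches to the dye orientation
  and cancels under dye-swap combination.
* **Planted responses** follow the 14 temporal archetypes; "transient"
  archetypes use exact zero effect at non-responding time points — the
  simplest testable ground truth, not a claim about biology. The default
  effect size is 2 log2 units (4-fold), the scale of a strong response.
  The low concentration responds at half the high-dose effect, mirroring
  an attenuated low-dose response.
* **Probe redundancy**: extra probes duplicate random genes' signals with
  independent noise, exercising the collapse rule.
* **Promoters** are i.i.d. uniform sequence with one realized IUPAC
  consensus instance planted per selected gene (rates 0.8 responsive /
  0.1 background by default, length 1 kb).
* **qPCR** tables shift the treated-arm target Ct by minus the planted
  log2 fold change against an 18S-like reference.
* One integer seed drives everything; sub-streams for promoters, qPCR and
  discovery are derived from it by fixed offsets, and identical seeds
  give byte-identical outputs.

What the generator does **not** emulate: spot-level image artifacts,
probe-sequence hybridization thermodynamics, intensity-dependent dye
curvature beyond the additive/multiplicative model, correlated noise
between probes of a gene, or realistic promoter composition (no GC
skew, no repeats). Consequently, passing tests demonstrate the
*pipeline's* correctness and calibration under a faithful error model,
not performance on any particular real platform. With the default bright
baseline, small simulations may produce an empty non-expressed
background set (the documented warning); the pipeline then falls back to
the expressed background.

## Problem sizes and numerical checks used by the test suite

The suite's simulation scales are chosen to make the statistical checks
sharp at desk scale: null calibration on 30,000 probes (3 binomial SDs
around α = 0.005), archetype recovery on 10,000 genes with 100 planted
responders per archetype (≥ 95 % subgroup recovery at effect 2 and the
default noise), SVD contracts on 5,000 × 6 matrices (reconstruction
within 1e-8 relative Frobenius error), Fisher p-values against
brute-force enumeration for all 2×2 tables with margins ≤ 30, and
enrichment power over 100 replicate promoter sets of 40 responsive vs 40
background genes at planting rates (0.8, 0.1). Null-uniformity checks of
the Fisher/hypergeometric tests assert conservative validity (empirical
rejection rate ≤ nominal + 3 binomial SDs) rather than exact uniformity,
because exact-test p-values are discrete and super-uniform by
construction.

## Known limitations

* The dye-swap combination and p-value model are documented substitutes
  for a proprietary error model; numerical equivalence with the original
  chain is not claimed.
* The apparent FDR assumes independence of the two filters and is an
  upper-level summary, not a per-gene q-value.
* The Gibbs sampler models one motif per run (ZOOPS); co-occurring motifs
  require repeated masking runs, which the package does not automate.
* Background sequence for discovery is 0-order; GC-rich promoters will
  inflate the information content of GC-rich motifs.
* Six-array TFS ordering (high-concentration block first) is a
  convention; callers supplying the blocks in another order get codes in
  that order.
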