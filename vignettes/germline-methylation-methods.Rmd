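---
title: "Methods: sex-lineage methylation loci, RdDM-target DMRs and TE expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-lineage methylation loci, RdDM-target DMRs and TE expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germmeth)
```

# Scope and model

`germmeth` analyses whole-genome bisulfite data from isolated plant male
sex cells (meiocytes, microspores, pollen) against a somatic reference
(leaf), together with matched TE expression data. The biological model is
the standard one for plant DNA methylation: cytosines occur in three
sequence contexts (CG, CHG, CHH with H ∈ {A, C, T}), each maintained by a
different pathway, and RNA-directed DNA methylation (RdDM) writes de novo
CHH/CHG marks at short loci. Loci hypermethylated specifically in the
sexual lineage fall into two classes: SLM-like loci, which are silent in
somatic tissue (low somatic CHH/CHG — no somatic RdDM activity), and
canonical SLH-like loci, which are somatic RdDM targets that gain further
methylation in sex cells.

All per-cytosine tables carry 1-based positions as CX reports do; every
interval (window, locus, feature, BED output) is 0-based half-open. Each
function's documentation states which convention it speaks.

# The locus-calling procedure

`call_slm()` composes four operations, each exported and tested on its own:

1. **Screen** (`screen_windows()`). Fractional methylation is pooled per
   50-bp window and context as Σ methylated / Σ total — coverage-weighted
   pooling, not a mean of per-cytosine fractions, because windows at low
   depth would otherwise be dominated by single noisy cytosines. For each
   context `diff_X` is the *unweighted* mean of the sex-cell-group window
   fractions minus the somatic fraction; the unweighted mean treats each
   cell type as one biological condition regardless of sequencing depth.
   A window passes when all three differentials are strictly positive and
   their sum strictly exceeds 0.2. Windows in which any required group has
   zero coverage for any context are excluded rather than imputed: an
   absent denominator cannot support a claim in either direction.
2. **Merge** (`merge_candidates()`). Greedy left-to-right merging joins
   candidate windows whose gap is at most 100 bp (inclusive, measured
   end-to-start in half-open space) and drops merged intervals shorter
   than 100 bp. With 50-bp windows this means an isolated window never
   survives on its own — deliberate, as single-window hits are the most
   noise-prone.
3. **Test and filter**. For each merged locus a 2×2 table pools methylated
   and unmethylated reads over all three contexts and all sex groups
   against the somatic group ("total methylation"), and a two-sided
   Fisher's exact test must give p < 0.001. Pooling contexts and groups is
   one of two defensible readings of "total methylation"; it is the
   implemented default because the separate per-group claim is already
   enforced by the consistency filter, which requires the pooled
   all-context fraction to be *strictly* higher in every sex cell type
   than in the somatic group. A sex group with zero covered reads over a
   locus fails the filter: "higher" cannot be asserted from no data.
4. **Classify** (`classify_locus()`). SLM-like iff somatic CHH < 0.05 and
   somatic CHG < 0.1, both strict; anything else — including boundary
   values — is canonical SLH-like. All inequalities in the pipeline are
   strict exactly as printed in the sources that established these
   thresholds, so boundary values consistently fall to the conservative
   side.

Fisher's exact test is implemented in-package (`fisher_exact_2x2()`) as a
vectorized two-sided hypergeometric enumeration, because the callers test
thousands of windows and loci per run. Near-ties are absorbed with a
relative tolerance of 1e-7, the same convention `stats::fisher.test` uses,
so that tables mathematically as extreme as the observed one are counted
despite floating-point rounding; the test suite checks agreement with
`stats::fisher.test` on random tables and with exhaustive enumeration on
all tables with margins ≤ 30. Tables with a zero margin are uninformative
and return p = 1.

# The DMR caller

`call_dmrs()` scans one context (CHH by default) in 50-bp windows with a
50-bp step. A cytosine is *effective* when covered by ≥ 5 reads in both
conditions; windows need ≥ 10 effective cytosines. Pooled counts are
tested by the same Fisher test, corrected by Benjamini–Hochberg across
retained windows, and a window is a DMR at q < 0.005 with an absolute
difference above 10 percentage points. The per-window test and q-value
method are a deliberate, self-contained choice: Fisher + BH is
deterministic, has an exact brute-force oracle, and matches the stated
thresholds; tools in this space variously use logistic regression or SLIM
q-values, which change numbers slightly but not the operating
characteristics at these effect sizes. With `step < window` the scan
over-covers; overlapping significant windows are then deduplicated by
keeping the lowest-q window per overlapping run (an extension, off by
default since step = window).

`homolog_transfer()` consumes the tabular output of an external homology
search (the package does not run BLAST): each locus is lifted through its
best overlapping mapping — lowest e-value, then highest identity, then
longest target — by offsetting from the source interval start and clipping
to the target interval. Loci with no mapping are reported separately, never
silently dropped.

# Profiles

End-anchored metaprofiles (`ends_metaprofile()`) align stranded features at
their biological 5′ or 3′ end and pool counts in fixed bins (default 100
bp) across ± span (default 3 kb). Inside the feature, only bases belonging
to the feature contribute, so bins deeper than a feature's length receive
nothing from it; `n_features` records how many features can reach each bin.
This is the anti-skew rule: without it, deep bins would silently blend
downstream sequence from short features. The 3-kb span and 100-bp bin are
free parameters of this style of ends-analysis; defaults follow common
practice for genomes of this compaction. TE flank profiles
(`flank_profile()`) rescale each body to equal-occupancy bins (a base at
relative position q falls in bin ⌊q·body_bins⌋, so features shorter than
the bin count still contribute proportionally) with fixed 200-bp flanks.

"Substantial methylation" masks for box-plot quantification are
operationalized in `interval_quantify()` as ≥ 4 covered cytosines of the
context per interval (configurable) — an interpretation, flagged as such.

# The synthetic-data generator

The generator exists so that every stage is testable with planted ground
truth; its defaults *are* the study conditions the callers are tested
under, not tuning knobs:

* two bisulfite replicates of each of leaf, meiocyte, microspore and
  pollen; three RNA replicates per cell type;
* Poisson read depth with mean 20 (a negative-binomial overdispersion knob
  exists but defaults off — Poisson is the simplest model that exercises
  the coverage filter);
* compartment methylation means (TE body 0.80/0.60/0.12 for CG/CHG/CHH,
  gene body 0.30/0.05/0.02, intergenic 0.15/0.04/0.02, TE flank
  0.40/0.25/0.10) typical of Brassicaceae methylomes;
* planted sex-cell loci add +0.3 per context in sex cells (so the summed
  differential clears 0.2 by a wide margin in expectation); planted SLH
  loci additionally carry an elevated somatic CHG/CHH background
  (0.20/0.15) so they fail the SLM classification exactly as real somatic
  RdDM targets do; planted DMR loci sit at CHH 0.25 and collapse to 0.02
  in an RdDM-loss (rdr2-like) methylome;
* expression counts are negative-binomial around cluster-specific means
  (peak 500, baseline 10, dispersion 5), with inactive TEs at zero counts
  and active TEs drawn with a 0.85 bias towards elements < 2 kb,
  emulating the short-active/long-inactive length structure of real LTR-TE
  data.

Contexts are assigned strand-specifically from the reference trinucleotide;
cytosines within two bases of a chromosome end get context "unknown" and
are excluded (the sources are silent on end handling). Each output table
draws from its own RNG stream seeded by (master seed, file tag), so adding
samples to a design never perturbs existing ones. Feature packing places
non-overlapping intervals with stick-broken random gaps and fails loudly
when the requested features exceed the chromosome.

What the generator does **not** emulate: read-level artifacts (mapping
bias, bisulfite conversion failure, PCR duplicates), spatial
autocorrelation of methylation beyond compartment structure, partial or
allele-specific methylation, and genome repetitiveness. Passing recovery
tests therefore demonstrate that the callers implement their rules
correctly and are well calibrated under clean sampling noise — not that
they are robust to alignment artifacts in a real repetitive genome.

# TE expression

TPM uses the annotated feature length as effective length (no
fragment-length model is available for TE fragments) and excludes
caller-specified features (e.g. rRNA) before normalization. Activity
thresholds are strict: TPM > 10 in at least one tissue (active), < 0.001
in all (inactive); everything between is `intermediate` and excluded from
both downstream sets, so the three statuses partition the input.

Clustering runs k-means (k = 4, 25 restarts, fixed seed) on per-feature
z-scores of TPM across cell types, replicates averaged first. Z-scoring is
the implemented reading of "clustering on normalized expression": raw-TPM
k-means is dominated by magnitude and cannot produce pattern-based
clusters. Degenerate constant rows are z-scored to zero with a warning.
Cluster numbers are then a pure function of the centroids — clusters are
renumbered by the cell type at which their centroid peaks, in the order
meiocyte, microspore, leaf, pollen when those groups exist — so reruns at
the same seed reproduce identical labeled output. The length comparison
between active and inactive elements uses a two-sided Wilcoxon rank-sum
test; the choice of test is an interpretation, documented as such.

# Integration

DEG tables are consumed, not fitted: the package classifies records at
p < 0.05 (strict) and |log2FC| ≥ 1 (inclusive) and intersects the
up/down sets with locus-targeted genes (distance ≤ 500 bp, inclusive,
computed edge-to-edge in half-open coordinates and ignoring strand). The
fraction of targeted genes differentially expressed in at least one
contrast is reported with its denominator — the full targeted-gene list —
stated explicitly, since that denominator is the one quantity such
summaries habitually leave implicit.

# Numerical choices and degenerate inputs

* A window or interval with zero pooled reads has an undefined fraction:
  it is kept and flagged (`fraction = NA`), never silently dropped, and
  screening excludes it.
* Fisher on a zero-margin table returns 1 by convention.
* `merge_replicates()` requires context agreement at shared positions and
  errors otherwise — a context mismatch means the inputs disagree about
  the reference.
* Coverage thresholds are inclusive (`count_total >= min_reads`, default
  5). Both "more than 5" and "at least 5" readings circulate for this
  filter; a single inclusive knob makes both reachable.
* BH q-values come from `stats::p.adjust`; the step-up definition is
  verified against a brute-force oracle in the tests.
* The replicate-correlation report enforces no minimum: correlation is
  confirmed by inspection, not thresholded, since no defensible universal
  cutoff exists.

# Problem sizes

The test and acceptance runs use one 120–300 kb chromosome with 20–50
features and 10–100 planted loci per scenario, depth 20, and 200 active
TEs for cluster recovery; the exhaustive Fisher check covers all ~164,000
tables with margins ≤ 30. These sizes give every estimator hundreds to
thousands of informative units while keeping a full run in minutes on one
core. The demo (`run_demo()`) uses a 250-kb chromosome and writes a
checksum manifest so reruns are verifiable bit-for-bit.

# Known limitations

* Window boundaries are fixed at multiples of the window width; a planted
  locus straddling a boundary is recovered as one or two merged calls
  whose edges are quantized to 50 bp.
* The Fisher screen is applied to windows preselected by the differential
  rule, so the q-values and p-values are conditional on screening; the
  null-calibration tests bound, but do not exactly size, the false-positive
  rate.
* Symmetric-CG collapsing is not performed — strands stay separate as in
  CX reports, since windows pool counts regardless of strand anyway.
* Homolog transfer assumes approximately length-preserving mappings; loci
  extending past their mapping's target interval are clipped.
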