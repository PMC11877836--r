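# germmeth

Whole-genome bisulfite and transcriptome analysis of the plant male
germline, built for studies that compare isolated sex cells (meiocytes,
microspores, pollen) against somatic tissue in Brassicaceae-scale genomes.

During male reproductive development, RNA-directed DNA methylation (RdDM)
deposits CHH/CHG methylation at loci that are hypermethylated specifically
in the sexual lineage. `germmeth` re-implements, as a tested and reusable R
package, the bespoke computations such a study needs:

* **Methylome ingestion** — Bismark-style CX reports (or a
  fraction+coverage dialect), replicate merging by count pooling, and the
  ≥ 5 informative-read coverage filter (`read_cx_report()`,
  `merge_replicates()`, `coverage_filter()`, `replicate_correlation()`).
* **Windowed quantification and metaprofiles** — pooled fractional
  methylation (Σ methylated / Σ total) in 50-bp windows, 5′/3′ end-anchored
  metaprofiles with the anti-skew rule for short features, scaled-body plus
  fixed-flank TE profiles, and per-interval quantification
  (`window_methylation()`, `ends_metaprofile()`, `flank_profile()`,
  `interval_quantify()`).
* **Sex-lineage hypermethylated locus calling** — the core screen. For
  each 50-bp window and context *X*,
  `diff_X = mean(sex-cell fractions) − somatic fraction`; windows with
  `diff_CG > 0 & diff_CHG > 0 & diff_CHH > 0` and
  `diff_CG + diff_CHG + diff_CHH > 0.2` are merged when within 100 bp,
  retained at ≥ 100 bp, tested by a two-sided Fisher's exact test on pooled
  total methylation (p < 0.001), required to be higher in *every* sex cell
  type than in somatic tissue, and classified **SLM-like** (somatic
  CHH < 0.05 and CHG < 0.1 — no somatic RdDM activity) or **canonical
  SLH-like** otherwise (`call_slm()`).
* **RdDM-target DMR calling** — 50-bp sliding windows over CHH with ≥ 10
  effective cytosines (≥ 5 reads in both conditions), Fisher + Benjamini–
  Hochberg, called at q < 0.005 and > 10 percentage-point difference
  (`call_dmrs()`), plus lifting of loci through homology mappings
  (`homolog_transfer()`).
* **Annotation and integration** — proximity classes
  (overlapping / within 500 bp / beyond), locus-targeted genes, interval-set
  overlap, DEG classification at p < 0.05 and |log2FC| ≥ 1, and Venn
  summaries (`proximity_classify()`, `target_genes()`, `deg_classify()`,
  `slm_deg_overlap()`, `venn_counts()`).
* **TE expression** — TPM (Σ = 10⁶ per sample), activity calls
  (active: TPM > 10 in ≥ 1 tissue; inactive: < 0.001 in all), k-means
  (k = 4) on per-feature z-scores with deterministic centroid-peak
  renumbering, and length composition with a rank-sum comparison
  (`compute_tpm()`, `classify_activity()`, `cluster_active()`,
  `length_composition()`).
* **Synthetic data with planted truth** — a genome/annotation/methylome/
  expression simulator whose planted loci and clusters make every stage
  testable without sequencing data (`sim_config()`, `simulate_genome()`,
  `simulate_methylome()`, `simulate_expression()`), and a one-command
  end-to-end demo (`run_demo()`).

Everything is tidyverse-native: tibbles in and out, `tidy()`/`glance()`
methods on fitted results, and `autoplot()` methods for profiles, locus
calls, DMR calls and expression clusters.

## Worked example

```r
library(germmeth)
library(dplyr)

cfg <- sim_config(seed = 42, chrom_length = 120000, n_genes = 12, n_tes = 16,
                  n_planted_slm = 6, n_planted_slh = 3, n_planted_dmr = 4,
                  expr_cluster_spec = mutate(default_expr_clusters(),
                                             n = c(6L, 3L, 3L, 3L)))
gen  <- simulate_genome(cfg)
meth <- simulate_methylome(gen$genome, gen$annotation, gen$truth, cfg)
methylomes <- lapply(meth, function(r)
  coverage_filter(merge_replicates(r), min_reads = 5))

slm <- call_slm(methylomes,
                sex_groups = c("meiocyte", "microspore", "pollen"),
                somatic_group = "leaf")
slm
#> Sex-lineage hypermethylated locus call
#>   9 loci (5 SLM-like, 4 canonical SLH-like), mean length 216.7 bp
#>   sex groups: meiocyte, microspore, pollen; somatic: leaf

tidy(slm) %>% select(chrom, start, end, length, diff_chh, fisher_p, label)
#> # A tibble: 9 × 7
#>   chrom start   end length diff_chh  fisher_p label
#>   <chr> <int> <int>  <int>    <dbl>     <dbl> <chr>
#> 1 chr1  25100 25250    150    0.287 4.00e-216 SLM_like
#> 2 chr1  27100 27350    250    0.267 2.96e-284 canonical_SLH_like
#> 3 chr1  36650 36900    250    0.242 6.75e-252 canonical_SLH_like
#> 4 chr1  42200 42450    250    0.262 0         SLM_like
#> # ℹ 5 more rows

interval_recovery(tidy(slm),
                  subset(gen$truth$planted_loci, class %in% c("SLM", "SLH")))
#> # A tibble: 1 × 6
#>   n_called n_truth  n_tp n_recovered precision recall
#>      <int>   <int> <int>       <int>     <dbl>  <dbl>
#> 1        9       9     9           9         1      1
```

The nine calls recover all nine planted sex-cell loci; the planted
somatic-RdDM (SLH) loci are classified canonical SLH-like because their
somatic CHH/CHG background exceeds the SLM thresholds, while the quiet-leaf
SLM loci keep the SLM-like label. `diff_chh` is the mean sex-minus-leaf CHH
differential over the locus and `fisher_p` the pooled-count Fisher p-value.

A full end-to-end run (methylomes, locus and DMR calls, metaprofiles, TE
clustering, annotation and DEG integration, with a checksum manifest):

```r
run_demo("demo_out", seed = 1)
```

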