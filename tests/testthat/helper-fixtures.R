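# Shared synthetic study used by several test files: one small chromosome
# with planted loci of all three classes and a four-cluster expression
# design. Built once per test run.

fx_cfg <- sim_config(
  seed = 42L, chrom_length = 120000L, n_genes = 12L, n_tes = 16L,
  n_planted_slm = 6L, n_planted_slh = 3L, n_planted_dmr = 4L,
  expr_cluster_spec = dplyr::mutate(default_expr_clusters(),
                                    n = c(6L, 3L, 3L, 3L))
)
fx_gen <- simulate_genome(fx_cfg)
fx_meth <- simulate_methylome(fx_gen$genome, fx_gen$annotation, fx_gen$truth,
                              fx_cfg)
fx_merged <- lapply(fx_meth, function(r) coverage_filter(merge_replicates(r)))
fx_sex <- c("meiocyte", "microspore", "pollen")

# a free-standing methylome tibble (positions need not match any genome)
mk_meth <- function(pos, context, meth, total, chrom = "chr1", strand = "+") {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 context = context, count_methylated = as.integer(meth),
                 count_total = as.integer(total))
}

# a one-window methylome with one site per context at given fractions
# (depth 100 so fractions are exact)
mk_window_meth <- function(cg, chg, chh, depth = 100) {
  mk_meth(pos = c(2L, 10L, 20L), context = c("CG", "CHG", "CHH"),
          meth = round(c(cg, chg, chh) * depth), total = depth)
}
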