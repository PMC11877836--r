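test_that("simulated features are non-degenerate, in bounds and non-overlapping", {
  ann <- fx_gen$annotation
  pl <- fx_gen$truth$planted_loci
  expect_equal(nrow(ann), fx_cfg$n_genes + fx_cfg$n_tes)
  all_iv <- dplyr::bind_rows(
    dplyr::select(ann, chrom, start, end),
    dplyr::select(pl, chrom, start, end)
  ) %>% dplyr::arrange(chrom, start)
  expect_true(all(all_iv$end > all_iv$start))
  expect_true(all(all_iv$start >= 0))
  expect_true(all(all_iv$end <= fx_cfg$chrom_length))
  # no two packed intervals overlap
  by_chr <- split(all_iv, all_iv$chrom)
  for (iv in by_chr) {
    expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  }
  expect_true(all(pl$class %in% c("SLM", "SLH", "DMR")))
})

test_that("genome simulation is byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 5L, chrom_length = 30000L, n_genes = 4L, n_tes = 6L,
                    n_planted_slm = 2L, n_planted_slh = 1L,
                    expr_cluster_spec = dplyr::mutate(default_expr_clusters(),
                                                      n = c(2L, 1L, 1L, 1L)))
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$annotation, g2$annotation)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g1$genome, f1)
  write_genome_fasta(g2$genome, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("infeasible packing raises an explicit error", {
  cfg <- sim_config(seed = 1L, chrom_length = 20000L, n_genes = 0L,
                    n_tes = 200L,
                    expr_cluster_spec = dplyr::mutate(default_expr_clusters(),
                                                      n = c(50L, 50L, 50L, 50L)))
  expect_error(simulate_genome(cfg), "infeasible packing")
})

test_that("context assignment matches an independent re-scan of the sequence", {
  seq <- fx_gen$genome[["chr1"]]
  sc <- scan_cytosines(seq, "chr1")
  idx <- sample(nrow(sc), 800)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in idx) {
    pos <- sc$pos[i]
    if (sc$strand[i] == "+") {
      down <- substr(seq, pos + 1, pos + 2)
    } else {
      up <- substr(seq, max(pos - 2, 1), pos - 1)
      down <- paste(rev(comp[strsplit(up, "")[[1]]]), collapse = "")
    }
    want <- if (nchar(down) < 2) "unknown"
    else if (substr(down, 1, 1) == "G") "CG"
    else if (substr(down, 2, 2) == "G") "CHG"
    else "CHH"
    expect_identical(sc$context[i], want)
  }
  # every CG dinucleotide yields a symmetric CG site on both strands
  cg_plus <- sc$pos[sc$strand == "+" & sc$context == "CG"]
  cg_minus <- sc$pos[sc$strand == "-" & sc$context == "CG"]
  expect_setequal(cg_plus + 1L, cg_minus)
})

test_that("degenerate methylation rates give all-zero and all-total counts", {
  cm0 <- default_compartment_meth()
  cm0[c("CG", "CHG", "CHH")] <- 0
  cfg0 <- sim_config(seed = 3L, chrom_length = 8000L, n_genes = 1L, n_tes = 2L,
                     n_planted_slm = 0L, n_planted_slh = 0L,
                     compartment_meth = cm0,
                     expr_cluster_spec = dplyr::mutate(default_expr_clusters(),
                                                       n = c(1L, 0L, 0L, 0L)))
  gen <- simulate_genome(cfg0)
  m <- simulate_methylome(gen$genome, gen$annotation, gen$truth, cfg0,
                          groups = "leaf", n_replicates = 1)
  expect_true(all(m$leaf[[1]]$count_methylated == 0))

  cm1 <- cm0
  cm1[c("CG", "CHG", "CHH")] <- 1
  cfg1 <- cfg0; cfg1$compartment_meth <- cm1
  m1 <- simulate_methylome(gen$genome, gen$annotation, gen$truth, cfg1,
                           groups = "leaf", n_replicates = 1)
  expect_identical(m1$leaf[[1]]$count_methylated, m1$leaf[[1]]$count_total)
})

test_that("planted effect reproduces the binomial mean and beats background", {
  # one planted sex-cell locus, effect +0.3 per context, depth 20, 2 reps:
  # the mean sex-minus-somatic CHH difference over repeated simulations must
  # sit within 0.05 of the planted effect, and the locus must exceed matched
  # background in nearly every simulation
  base <- sim_config(seed = 1L, chrom_length = 4000L, n_genes = 0L,
                     n_tes = 0L, n_planted_slm = 1L, n_planted_slh = 0L,
                     cell_types = c("leaf", "meiocyte"), depth_mean = 20,
                     expr_cluster_spec = dplyr::mutate(default_expr_clusters(),
                                                       n = c(0L, 0L, 0L, 0L)))
  diffs <- numeric(100)
  beats_bg <- logical(100)
  for (s in 1:100) {
    cfg <- base; cfg$seed <- 1000L + s
    gen <- simulate_genome(cfg)
    loc <- gen$truth$planted_loci
    m <- simulate_methylome(gen$genome, gen$annotation, gen$truth, cfg)
    pooled <- lapply(m, function(r) merge_replicates(r))
    q <- lapply(pooled, function(x) {
      interval_quantify(x, loc, contexts = "CHH")
    })
    diffs[s] <- q$meiocyte$fraction - q$leaf$fraction
    # matched background: the rest of the chromosome in the sex cells
    bg <- tibble::tibble(chrom = "chr1", start = 0L, end = loc$start)
    qbg <- interval_quantify(pooled$meiocyte, bg, contexts = "CHH")
    beats_bg[s] <- q$meiocyte$fraction > qbg$fraction
  }
  expect_lt(abs(mean(diffs) - 0.3), 0.05)
  expect_gte(sum(beats_bg), 95)
})

test_that("expression generator honors the cluster design and determinism", {
  spec0 <- default_expr_clusters()
  spec0$peak_mean <- 0; spec0$base_mean <- 0
  spec0$n <- c(6L, 3L, 3L, 3L)
  cfg <- fx_cfg
  cfg$expr_cluster_spec <- spec0
  cfg$gene_expr_mean <- 0
  ex0 <- simulate_expression(fx_gen$truth, cfg)
  expect_true(all(as.matrix(ex0$counts[, -(1:2)]) == 0))

  ex1 <- simulate_expression(fx_gen$truth, fx_cfg)
  ex2 <- simulate_expression(fx_gen$truth, fx_cfg)
  expect_identical(ex1$counts, ex2$counts)
  # planted member counts respected
  act <- ex1$truth$te_activity
  expect_equal(sum(act$active), sum(fx_cfg$expr_cluster_spec$n))
  expect_equal(unname(table(act$cluster[act$active])[as.character(1:4)]),
               fx_cfg$expr_cluster_spec$n, ignore_attr = TRUE)

  bad <- default_expr_clusters()  # 200 members > 16 TEs
  expect_error(sim_config(seed = 1, n_tes = 16L, expr_cluster_spec = bad),
               "exceed")
})
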