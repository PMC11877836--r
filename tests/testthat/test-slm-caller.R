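test_that("the window screen applies the printed differential rule strictly", {
  cases <- list(
    list(sex = c(0.20, 0.18, 0.10), som = c(0.10, 0.10, 0.05), pass = TRUE),
    # diffs (0.10, 0.08, 0.05), sum 0.23 > 0.2 -> pass
    list(sex = c(0.30, 0.15, 0.04), som = c(0.05, 0.05, 0.05), pass = FALSE),
    # diffs (0.25, 0.10, -0.01): CHH diff <= 0 -> fail
    list(sex = c(0.10, 0.10, 0.10), som = c(0.05, 0.05, 0.05), pass = FALSE)
    # diffs (0.05, 0.05, 0.05): sum 0.15 <= 0.2 -> fail
  )
  for (cs in cases) {
    meths <- list(
      meiocyte = mk_window_meth(cs$sex[1], cs$sex[2], cs$sex[3]),
      leaf = mk_window_meth(cs$som[1], cs$som[2], cs$som[3])
    )
    got <- screen_windows(meths, "meiocyte", "leaf")
    expect_equal(nrow(got), as.integer(cs$pass))
  }
})

test_that("windows lacking coverage in any group are excluded from screening", {
  sex <- mk_window_meth(0.5, 0.5, 0.5)
  som <- mk_window_meth(0, 0, 0)
  som$count_total[som$context == "CHH"] <- 0L  # leaf CHH uncovered
  got <- screen_windows(list(meiocyte = sex, leaf = som), "meiocyte", "leaf")
  expect_equal(nrow(got), 0)
})

test_that("candidate merging is greedy with an inclusive gap and length floor", {
  w <- tibble::tibble(chrom = "chr1", start = c(100L, 200L), end = c(150L, 250L))
  m <- merge_candidates(w)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100L, 250L))

  w2 <- tibble::tibble(chrom = "chr1", start = c(100L, 260L), end = c(150L, 310L))
  m2 <- merge_candidates(w2)  # gap 110 > 100: two 50-bp runs, both < 100 bp
  expect_equal(nrow(m2), 0)

  w3 <- tibble::tibble(chrom = "chr1", start = c(100L, 250L), end = c(150L, 300L))
  m3 <- merge_candidates(w3)  # gap exactly 100 is inclusive
  expect_equal(nrow(m3), 1)
})

test_that("merging matches a quadratic connected-component oracle", {
  set.seed(31)
  for (rep in 1:5) {
    starts <- sort(sample(seq(0, 5000, 50), 40))
    w <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                        start = starts, end = starts + 50L)
    got <- merge_candidates(w, slm_params(min_len = 0))
    want <- oracle_merge(w, 100)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("Fisher's exact test matches known values and the reference oracle", {
  expect_equal(fisher_exact_2x2(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 0, 3, 4), 1)  # zero margin convention

  set.seed(17)
  a <- rpois(300, 8); b <- rpois(300, 8); c <- rpois(300, 8); d <- rpois(300, 8)
  got <- fisher_exact_2x2(a, b, c, d)
  for (i in seq_len(300)) {
    want <- stats::fisher.test(matrix(c(a[i], c[i], b[i], d[i]), 2))$p.value
    expect_equal(got[i], want, tolerance = 1e-9)
  }
})

test_that("the consistency filter demands strictly higher in every sex cell", {
  expect_true(consistency_filter(matrix(c(0.4, 0.35, 0.5), 1), 0.2))
  expect_false(consistency_filter(matrix(c(0.4, 0.15, 0.5), 1), 0.2))
  expect_false(consistency_filter(matrix(c(0.4, 0.2, 0.5), 1), 0.2))  # equal
  expect_false(consistency_filter(matrix(c(0.4, NA, 0.5), 1), 0.2))   # no reads
})

test_that("classification splits on somatic RdDM activity with strict bounds", {
  expect_equal(classify_locus(0.02, 0.05), "SLM_like")
  expect_equal(classify_locus(0.06, 0.02), "canonical_SLH_like")
  expect_equal(classify_locus(0.05, 0.02), "canonical_SLH_like")  # boundary
  expect_equal(classify_locus(0.02, 0.10), "canonical_SLH_like")  # CHG bound
})

test_that("planted loci are recovered and labeled by their somatic background", {
  slm <- call_slm(fx_merged, fx_sex, "leaf")
  truth <- fx_gen$truth$planted_loci
  sexy <- truth[truth$class %in% c("SLM", "SLH"), ]
  rec <- interval_recovery(slm$loci, sexy)
  expect_gte(rec$precision, 0.9)
  expect_gte(rec$recall, 0.9)
  # no locus overlapping a planted somatic-RdDM (SLH) locus is labeled SLM
  slh <- truth[truth$class == "SLH", ]
  h <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(slm$loci$chrom,
                           IRanges::IRanges(slm$loci$start + 1, slm$loci$end)),
    GenomicRanges::GRanges(slh$chrom, IRanges::IRanges(slh$start + 1, slh$end)))
  over_slh <- unique(S4Vectors::queryHits(h))
  expect_true(length(over_slh) > 0)
  expect_true(all(slm$loci$label[over_slh] == "canonical_SLH_like"))
  # label partition
  expect_equal(slm$summary$n_total,
               slm$summary$n_slm_like + slm$summary$n_slh_like)
})

test_that("tightening thresholds never enlarges the called set", {
  base <- call_slm(fx_merged, fx_sex, "leaf")
  tight_diff <- call_slm(fx_merged, fx_sex, "leaf",
                         slm_params(sum_diff_min = 0.5))
  tight_p <- call_slm(fx_merged, fx_sex, "leaf", slm_params(p_max = 1e-6))
  # every locus surviving a stricter screen is nested inside a baseline locus
  # (edge windows may be trimmed), and the called set never grows
  nested_in <- function(tight, base) {
    all(vapply(seq_len(nrow(tight$loci)), function(i) {
      any(base$loci$chrom == tight$loci$chrom[i] &
            base$loci$start <= tight$loci$start[i] &
            base$loci$end >= tight$loci$end[i])
    }, logical(1)))
  }
  expect_lte(nrow(tight_diff$loci), nrow(base$loci))
  expect_lte(nrow(tight_p$loci), nrow(base$loci))
  expect_true(nested_in(tight_diff, base))
  expect_true(nested_in(tight_p, base))
  # lowering p_max filters after merging, so those loci are an exact subset
  key <- function(x) paste(x$loci$chrom, x$loci$start, x$loci$end)
  expect_true(all(key(tight_p) %in% key(base)))
})

test_that("a single planted locus yields exactly one merged call covering it", {
  cfg <- sim_config(seed = 9L, chrom_length = 6000L, n_genes = 0L, n_tes = 0L,
                    n_planted_slm = 1L, n_planted_slh = 0L,
                    cell_types = c("leaf", "meiocyte"),
                    expr_cluster_spec = dplyr::mutate(default_expr_clusters(),
                                                      n = c(0L, 0L, 0L, 0L)))
  gen <- simulate_genome(cfg)
  m <- simulate_methylome(gen$genome, gen$annotation, gen$truth, cfg)
  merged <- lapply(m, function(r) coverage_filter(merge_replicates(r)))
  res <- call_slm(merged, "meiocyte", "leaf")
  expect_equal(nrow(res$loci), 1)
  pl <- gen$truth$planted_loci
  expect_lte(res$loci$start, pl$start + 50)
  expect_gte(res$loci$end, pl$end - 50)
})
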