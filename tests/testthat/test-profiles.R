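test_that("window assignment pools counts with half-open boundaries", {
  m <- mk_meth(4, "CHH", 3, 10)  # pos0 = 3 -> window [0, 50)
  w <- window_methylation(m, window = 50)
  chh <- w[w$context == "CHH", ]
  expect_equal(chh$start, 0L)
  expect_equal(chh$fraction, 0.3)
  # zero-coverage contexts are flagged, not dropped
  expect_true(all(c("CG", "CHG") %in% w$context))
  expect_true(all(is.na(w$fraction[w$context != "CHH"])))

  m2 <- mk_meth(c(50, 51), "CG", 1, 2)  # pos0 49 and 50 straddle the boundary
  w2 <- window_methylation(m2, window = 50)
  expect_equal(sort(unique(w2$start)), c(0L, 50L))
})

test_that("windowed counts equal a brute-force recomputation and conserve totals", {
  m <- fx_merged$meiocyte[fx_merged$meiocyte$pos < 20000, ]
  w <- window_methylation(m, window = 50)
  ivs <- tibble::tibble(chrom = "chr1",
                        start = unique(w$start),
                        end = unique(w$start) + 50L)
  oracle <- oracle_quantify(m, ivs)
  got <- w %>% dplyr::arrange(start, context)
  oracle <- oracle %>%
    dplyr::mutate(start = ivs$start[row]) %>%
    dplyr::arrange(start, context)
  expect_equal(got$count_methylated, oracle$count_methylated)
  expect_equal(got$count_total, oracle$count_total)
  # conservation per context
  tot <- m %>% dplyr::group_by(context) %>%
    dplyr::summarise(meth = sum(count_methylated), total = sum(count_total))
  wtot <- w %>% dplyr::group_by(context) %>%
    dplyr::summarise(meth = sum(count_methylated), total = sum(count_total))
  expect_equal(as.data.frame(wtot), as.data.frame(tot))
})

test_that("uniform methylomes give flat metaprofiles", {
  m <- fx_merged$leaf
  m$count_total <- 2L
  m$count_methylated <- 1L
  feats <- fx_gen$annotation[fx_gen$annotation$kind == "TE", ]
  for (anc in c("5prime", "3prime")) {
    p <- ends_metaprofile(m, feats, anchor = anc, bin = 100, span = 500)
    expect_true(all(p$fraction[p$count_total > 0] == 0.5))
  }
  fp <- flank_profile(m, feats, flank = 200, body_bins = 4, flank_bin = 100)
  expect_true(all(fp$fraction[fp$count_total > 0] == 0.5))
})

test_that("a single plus-strand feature reduces to per-interval quantification", {
  m <- fx_merged$meiocyte
  feat <- tibble::tibble(chrom = "chr1", start = 10000L, end = 10600L,
                         strand = "+")
  p <- ends_metaprofile(m, feat, anchor = "5prime", bin = 100, span = 300)
  ivs <- tibble::tibble(chrom = "chr1",
                        start = 10000L + c(0L, 100L, 200L),
                        end = 10000L + c(100L, 200L, 300L))
  q <- interval_quantify(m, ivs)
  for (k in 0:2) {
    for (ctx in c("CG", "CHG", "CHH")) {
      pb <- p[p$bin_index == k & p$context == ctx, ]
      qb <- q[q$start == 10000 + k * 100 & q$context == ctx, ]
      expect_equal(pb$count_methylated, qb$count_methylated)
      expect_equal(pb$count_total, qb$count_total)
    }
  }
})

test_that("metaprofiles localize a body/flank methylation step at the anchor", {
  # constructed methylome: CHH 0.8 inside TEs, 0.1 outside
  feats <- fx_gen$annotation[fx_gen$annotation$kind == "TE", ]
  m <- fx_merged$leaf
  inside <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(feats))) {
    inside <- inside | (m$pos - 1 >= feats$start[i] & m$pos - 1 < feats$end[i])
  }
  m$count_total <- 10L
  m$count_methylated <- ifelse(inside, 8L, 1L)
  p <- ends_metaprofile(m, feats, anchor = "5prime", bin = 100, span = 500,
                        contexts = "CHH")
  up <- p$fraction[p$bin_index == -1]
  first_in <- p$fraction[p$bin_index == 0]
  expect_lt(up, 0.3)
  expect_gt(first_in, 0.6)
})

test_that("the anti-skew rule limits deep bins to features long enough", {
  feats <- tibble::tibble(chrom = "chr1", start = c(1000L, 5000L),
                          end = c(1150L, 6000L), strand = "+")
  m <- mk_meth(seq(900, 6100, by = 7), "CHH", 1, 2)
  p <- ends_metaprofile(m, feats, anchor = "5prime", bin = 100, span = 300,
                        contexts = "CHH")
  expect_equal(p$n_features[p$bin_index == -1], 2)  # flank: all features
  expect_equal(p$n_features[p$bin_index == 0], 2)   # both reach 1 bp
  expect_equal(p$n_features[p$bin_index == 1], 2)   # 150 bp > 100 bp
  expect_equal(p$n_features[p$bin_index == 2], 1)   # only the 1-kb feature
  # and no cytosine beyond the short feature end leaks into its bins:
  # bin 1 holds 50 bp of the short feature plus 100 bp of the long one
  sites_short <- sum(m$pos - 1 >= 1100 & m$pos - 1 < 1150)
  sites_long <- sum(m$pos - 1 >= 5100 & m$pos - 1 < 5200)
  expect_equal(p$count_total[p$bin_index == 1], 2L * (sites_short + sites_long))
})

test_that("flank profile collapses to the pooled body fraction at one bin", {
  feats <- fx_gen$annotation[fx_gen$annotation$kind == "TE", ][1:5, ]
  m <- fx_merged$pollen
  fp <- flank_profile(m, feats, flank = 0, body_bins = 1)
  q <- interval_quantify(m, feats)
  for (ctx in c("CG", "CHG", "CHH")) {
    pooled <- q[q$context == ctx, ]
    expect_equal(fp$count_methylated[fp$context == ctx],
                 sum(pooled$count_methylated))
    expect_equal(fp$count_total[fp$context == ctx],
                 sum(pooled$count_total))
  }
})

test_that("planted flank hypermethylation shows up in flank bins only", {
  feats <- fx_gen$annotation[fx_gen$annotation$kind == "TE", ]
  m <- fx_merged$leaf
  near_flank <- rep(FALSE, nrow(m))
  inside <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(feats))) {
    p0 <- m$pos - 1
    inside <- inside | (p0 >= feats$start[i] & p0 < feats$end[i])
    near_flank <- near_flank |
      (p0 >= feats$start[i] - 200 & p0 < feats$start[i]) |
      (p0 >= feats$end[i] & p0 < feats$end[i] + 200)
  }
  m$count_total <- 10L
  m$count_methylated <- ifelse(near_flank & !inside, 6L, 1L)
  fp <- flank_profile(m, feats, flank = 200, body_bins = 4, flank_bin = 100,
                      contexts = "CHH")
  expect_gt(min(fp$fraction[fp$region != "body"]),
            max(fp$fraction[fp$region == "body"]) + 0.2)
})

test_that("interval quantification matches a brute-force scan", {
  m <- mk_meth(1, "CG", 2, 8)
  one <- interval_quantify(m, tibble::tibble(chrom = "chr1", start = 0L, end = 1L))
  expect_equal(one$fraction[one$context == "CG"], 0.25)

  # partition additivity: disjoint intervals tiling a window
  m2 <- fx_merged$leaf[fx_merged$leaf$pos <= 5000, ]
  tiles <- tibble::tibble(chrom = "chr1", start = seq(0L, 4950L, 50L),
                          end = seq(50L, 5000L, 50L))
  q <- interval_quantify(m2, tiles)
  whole <- interval_quantify(m2, tibble::tibble(chrom = "chr1", start = 0L,
                                                end = 5000L))
  sums <- q %>% dplyr::group_by(context) %>%
    dplyr::summarise(meth = sum(count_methylated), total = sum(count_total))
  expect_equal(sums$meth, whole$count_methylated[match(sums$context, whole$context)])
  expect_equal(sums$total, whole$count_total[match(sums$context, whole$context)])

  set.seed(99)
  ivs <- tibble::tibble(chrom = "chr1",
                        start = sample(0:11000, 300))
  ivs$end <- ivs$start + sample(20:400, 300, replace = TRUE)
  m3 <- fx_merged$microspore[fx_merged$microspore$pos < 12000, ]
  got <- interval_quantify(m3, ivs) %>% dplyr::arrange(as.integer(id), context)
  want <- oracle_quantify(m3, ivs) %>% dplyr::arrange(row, context)
  expect_equal(got$count_methylated, want$count_methylated)
  expect_equal(got$count_total, want$count_total)
  expect_equal(got$n_sites, want$n_sites)

  expect_error(
    interval_quantify(m, tibble::tibble(chrom = "chr1", start = 0L, end = 10L),
                      seqlengths = c(chr1 = 5L)),
    "beyond chromosome end")
})
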