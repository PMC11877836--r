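two_feat <- tibble::tibble(feature_id = c("f1", "f2"), length = c(1000, 2000),
                           s1 = c(10, 10))

test_that("TPM follows the length-normalized arithmetic", {
  e <- compute_tpm(two_feat)
  tpm <- e$tpm$s1
  expect_equal(tpm, c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)
  expect_equal(round(tpm, 2), c(666666.67, 333333.33))

  single <- compute_tpm(tibble::tibble(feature_id = "f", length = 500, s1 = 3))
  expect_equal(single$tpm$s1, 1e6)

  doubled <- two_feat; doubled$s1 <- doubled$s1 * 2
  expect_equal(compute_tpm(doubled)$tpm$s1, tpm)
})

test_that("TPM columns sum to one million, also after exclusions", {
  ex <- simulate_expression(fx_gen$truth, fx_cfg)
  e <- compute_tpm(ex$counts)
  sums <- colSums(as.matrix(e$tpm[, -1]))
  expect_equal(unname(sums), rep(1e6, length(sums)), tolerance = 1e-6)
  drop <- ex$counts$feature_id[grepl("^gene", ex$counts$feature_id)][1:5]
  e2 <- compute_tpm(ex$counts, exclude = drop)
  expect_equal(unname(colSums(as.matrix(e2$tpm[, -1]))),
               rep(1e6, length(sums)), tolerance = 1e-6)
  expect_false(any(drop %in% e2$tpm$feature_id))
  expect_warning(compute_tpm(ex$counts, exclude = "not_a_feature"),
                 "not in the count table")

  zero <- two_feat; zero$s1 <- 0
  expect_warning(ez <- compute_tpm(zero), "zero counts")
  expect_equal(ez$tpm$s1, c(0, 0))
})

test_that("activity classification partitions TEs with strict thresholds", {
  tpm <- tibble::tibble(feature_id = c("a", "b", "c"),
                        t1 = c(12, 0.0005, 5), t2 = c(0, 0.0005, 5),
                        t3 = c(0, 0.0005, 5), t4 = c(0, 0.0005, 5))
  fake <- structure(list(tpm = tpm, samples = paste0("t", 1:4)),
                    class = "expr_matrix")
  act <- classify_activity(fake)
  expect_equal(act$status, c("active", "inactive", "intermediate"))
  # boundary: exactly 10 is not "greater than 10"
  tpm10 <- tibble::tibble(feature_id = "x", t1 = 10)
  act10 <- classify_activity(structure(list(tpm = tpm10), class = "expr_matrix"))
  expect_equal(act10$status, "intermediate")
  # partition over the fixture
  ex <- simulate_expression(fx_gen$truth, fx_cfg)
  full <- classify_activity(compute_tpm(ex$counts),
                            features = fx_gen$annotation)
  expect_equal(nrow(full), fx_cfg$n_tes)
  expect_true(all(full$status %in% c("active", "inactive", "intermediate")))
})

test_that("clustering recovers planted structure with deterministic labels", {
  ex <- simulate_expression(fx_gen$truth, fx_cfg)
  expr <- compute_tpm(ex$counts)
  act <- classify_activity(expr, features = fx_gen$annotation)
  ids <- act$te_id[act$status == "active"]
  cl <- cluster_active(expr, ids, k = 4, seed = 7)
  truth <- ex$truth$te_activity
  truth <- truth[truth$active, ]
  j <- dplyr::inner_join(cl$labels, truth, by = "te_id",
                         suffix = c("_called", "_truth"))
  expect_gte(adjusted_rand_index(j$cluster_called, j$cluster_truth), 0.8)
  # canonical renumbering: cluster 1 peaks in meiocyte, 2 in microspore, ...
  peaks <- colnames(cl$centroids)[apply(cl$centroids, 1, which.max)]
  expect_equal(peaks, c("meiocyte", "microspore", "leaf", "pollen"))

  # same seed, permuted feature rows -> identical labeled partition
  perm <- expr
  o <- sample(nrow(perm$tpm))
  perm$tpm <- perm$tpm[o, ]
  perm$counts <- perm$counts[o, ]
  cl2 <- cluster_active(perm, ids, k = 4, seed = 7)
  j2 <- dplyr::inner_join(cl$labels, cl2$labels, by = "te_id")
  expect_equal(adjusted_rand_index(j2$cluster.x, j2$cluster.y), 1)

  # k = 1 puts every active TE in one cluster
  cl1 <- cluster_active(expr, ids, k = 1, seed = 7)
  expect_true(all(cl1$labels$cluster == 1))
})

test_that("length composition separates short-active from long-inactive", {
  allk <- tibble::tibble(te_id = letters[1:4], status = "active",
                         length = 1000)
  lc <- length_composition(dplyr::bind_rows(
    allk, tibble::tibble(te_id = "z", status = "inactive", length = 5000)))
  f_act <- lc$fractions[lc$fractions$status == "active", ]
  expect_equal(f_act$fraction[f_act$bin == "<2000"], 1.0)

  ex <- simulate_expression(fx_gen$truth, fx_cfg)
  act <- classify_activity(compute_tpm(ex$counts),
                           features = fx_gen$annotation)
  lc2 <- length_composition(act)
  f <- lc2$fractions
  short_active <- f$fraction[f$status == "active" & f$bin == "<2000"]
  short_inactive <- f$fraction[f$status == "inactive" & f$bin == "<2000"]
  expect_gt(short_active, short_inactive)
  expect_true(is.finite(lc2$length_test$p_value))
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(13)
  for (i in 1:20) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
})
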