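#' Compute TPM from a count matrix
#'
#' Transcripts per million with annotated feature length as effective
#' length: `TPM_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)` per sample.
#' Features named in `exclude` (e.g. rRNA ids) are removed before
#' normalization so they never absorb library mass.
#'
#' @param counts Tibble with `feature_id`, `length` and one numeric column
#'   per sample (or a `lengths` vector supplied separately).
#' @param lengths Optional named lengths; overrides a `length` column.
#' @param exclude Feature ids dropped before normalization; unknown ids
#'   trigger a warning only.
#' @return An `expr_matrix`: list with `counts`, `tpm` (tibbles,
#'   feature x sample), `lengths`, `samples`.
#' @export
compute_tpm <- function(counts, lengths = NULL, exclude = character()) {
  if (!"feature_id" %in% names(counts)) abort("counts needs a feature_id column")
  if (is.null(lengths)) {
    if (!"length" %in% names(counts)) {
      abort("provide feature lengths (column `length` or `lengths=`)")
    }
    lengths <- stats::setNames(counts$length, counts$feature_id)
  }
  unknown <- setdiff(exclude, counts$feature_id)
  if (length(unknown) > 0) {
    warn(paste0(length(unknown), " exclude ids not in the count table"))
  }
  counts <- counts[!counts$feature_id %in% exclude, ]
  sample_cols <- setdiff(names(counts), c("feature_id", "length"))
  mat <- as.matrix(counts[sample_cols])
  rownames(mat) <- counts$feature_id
  len <- lengths[counts$feature_id]
  if (any(is.na(len) | len <= 0)) abort("feature lengths must be positive")

  rate <- mat / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warn(paste0("samples with zero counts: ",
                paste(sample_cols[zero], collapse = ", ")))
    tot[zero] <- 1  # keeps the column at all-zero TPM
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6

  structure(list(
    counts = tibble::as_tibble(mat, rownames = "feature_id"),
    tpm = tibble::as_tibble(tpm, rownames = "feature_id"),
    lengths = stats::setNames(as.numeric(len), counts$feature_id),
    samples = sample_cols
  ), class = "expr_matrix")
}

#' Classify transposon activity from TPM
#'
#' A TE is `active` when its TPM exceeds `active_min` in at least one
#' sample, `inactive` when it stays below `inactive_max` in all samples, and
#' `intermediate` otherwise (excluded from both downstream sets). The three
#' statuses partition the input.
#'
#' @param expr An `expr_matrix` from [compute_tpm()].
#' @param active_min Strict TPM floor for activity in any one sample.
#' @param inactive_max Strict TPM ceiling (all samples) for inactivity.
#' @param features Optional feature tibble used to restrict to TEs and to
#'   attach `superfamily` and `length`.
#' @return Tibble `te_id`, `status`, `max_tpm`, plus `superfamily` and
#'   `length` when available.
#' @export
classify_activity <- function(expr, active_min = 10, inactive_max = 0.001,
                              features = NULL) {
  tpm <- expr$tpm
  ids <- tpm$feature_id
  if (!is.null(features) && "kind" %in% names(features)) {
    keep <- ids %in% features$id[features$kind == "TE"]
    tpm <- tpm[keep, ]; ids <- ids[keep]
  }
  m <- as.matrix(tpm[, -1, drop = FALSE])
  mx <- apply(m, 1, max)
  out <- tibble::tibble(
    te_id = ids,
    status = dplyr::case_when(mx > active_min ~ "active",
                              mx < inactive_max ~ "inactive",
                              TRUE ~ "intermediate"),
    max_tpm = mx
  )
  if (!is.null(features)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(features, te_id = "id",
                    dplyr::any_of(c("superfamily", "length"))),
      by = "te_id")
  }
  out
}

#' Cluster active transposons by expression pattern
#'
#' k-means on per-feature z-scores of TPM across samples (pattern, not
#' magnitude; degenerate constant rows are z-scored to zero with a warning).
#' Replicate columns named `<group>_<rep>` are averaged per group before
#' scaling. Clusters are renumbered deterministically by the sample group at
#' which their centroid peaks, using the canonical germline order meiocyte,
#' microspore, leaf, pollen when those groups exist (ties and further
#' clusters fall back to column order, then centroid height).
#'
#' @param expr An `expr_matrix`.
#' @param active_ids Feature ids to cluster (>= k).
#' @param k Number of clusters.
#' @param seed RNG seed for k-means initialization.
#' @param nstart Random restarts.
#' @return A `te_clusters` list: `$labels` (tibble `te_id`, `cluster`),
#'   `$centroids` (cluster x group matrix of mean z-scores), `$k`.
#' @export
cluster_active <- function(expr, active_ids, k = 4, seed = 1, nstart = 25) {
  tpm <- expr$tpm
  tpm <- tpm[tpm$feature_id %in% active_ids, ]
  if (nrow(tpm) < k) abort("fewer active TEs than clusters")
  m <- as.matrix(tpm[, -1, drop = FALSE])
  rownames(m) <- tpm$feature_id
  grp <- sub("_[0-9]+$", "", colnames(m))
  gm <- t(apply(m, 1, function(r) tapply(r, grp, mean)))
  gm <- gm[, unique(grp), drop = FALSE]

  sds <- apply(gm, 1, stats::sd)
  if (any(sds == 0)) {
    warn(paste0(sum(sds == 0), " constant expression rows z-scored to zero"))
  }
  z <- (gm - rowMeans(gm)) / ifelse(sds == 0, 1, sds)

  km <- with_seed(as.integer(seed), stats::kmeans(z, centers = k,
                                                  nstart = nstart,
                                                  iter.max = 100))
  # deterministic renumbering by centroid peak group
  canonical <- c("meiocyte", "microspore", "leaf", "pollen")
  cols <- colnames(km$centers)
  pref <- c(intersect(canonical, cols), setdiff(cols, canonical))
  peak <- pref[apply(km$centers[, pref, drop = FALSE], 1, which.max)]
  ord <- order(match(peak, pref),
               -apply(km$centers, 1, max))
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]

  structure(list(
    labels = tibble::tibble(te_id = rownames(z), cluster = labels),
    centroids = km$centers[ord, , drop = FALSE],
    zscores = tibble::as_tibble(z, rownames = "te_id"),
    k = k
  ), class = "te_clusters")
}

#' Per-cluster summaries of active transposons
#'
#' @param clusters A `te_clusters` from [cluster_active()].
#' @param activity Optional [classify_activity()] table supplying
#'   superfamily labels.
#' @return Tibble `cluster`, `n`, `percent_of_active`, and per-superfamily
#'   counts when available.
#' @export
cluster_summary <- function(clusters, activity = NULL) {
  lab <- clusters$labels
  out <- lab %>%
    dplyr::count(.data$cluster, name = "n") %>%
    dplyr::mutate(percent_of_active = 100 * .data$n / sum(.data$n))
  if (!is.null(activity) && "superfamily" %in% names(activity)) {
    comp <- lab %>%
      dplyr::left_join(dplyr::select(activity, "te_id", "superfamily"),
                       by = "te_id") %>%
      dplyr::count(.data$cluster, .data$superfamily) %>%
      tidyr::pivot_wider(names_from = "superfamily", values_from = "n",
                         values_fill = 0L)
    out <- dplyr::left_join(out, comp, by = "cluster")
  }
  out
}

#' Length composition of activity classes
#'
#' Histogram fractions of each activity status across length bins, plus a
#' two-sided Wilcoxon rank-sum comparison of active versus inactive lengths
#' (the usual test for "active elements are shorter").
#'
#' @param calls [classify_activity()] output with a `length` column.
#' @param breaks Sorted interior break points in bp (default 2 kb).
#' @return List with `fractions` (tibble `status`, `bin`, `n`, `fraction`)
#'   and `length_test` (tibble `statistic`, `p_value`, medians).
#' @export
length_composition <- function(calls, breaks = 2000) {
  if (!"length" %in% names(calls)) abort("calls needs a length column")
  if (is.unsorted(breaks)) abort("breaks must be sorted")
  brk <- c(0, breaks, Inf)
  labs <- paste0("<", c(breaks, "Inf"))
  labs[length(labs)] <- paste0(">=", breaks[length(breaks)])
  frac <- calls %>%
    dplyr::filter(!is.na(.data$length)) %>%
    dplyr::mutate(bin = cut(.data$length, breaks = brk, labels = labs,
                            right = FALSE)) %>%
    dplyr::count(.data$status, .data$bin, .drop = FALSE, name = "n") %>%
    dplyr::group_by(.data$status) %>%
    dplyr::mutate(fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n)
                  else NA_real_) %>%
    dplyr::ungroup()
  act <- calls$length[calls$status == "active"]
  ina <- calls$length[calls$status == "inactive"]
  test <- if (length(act) > 0 && length(ina) > 0) {
    w <- stats::wilcox.test(act, ina, alternative = "two.sided", exact = FALSE)
    tibble::tibble(statistic = unname(w$statistic), p_value = w$p.value,
                   median_active = stats::median(act),
                   median_inactive = stats::median(ina))
  } else {
    warn("empty activity class; length comparison undefined")
    tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                   median_active = NA_real_, median_inactive = NA_real_)
  }
  list(fractions = frac, length_test = test)
}
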