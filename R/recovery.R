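#' Precision and recall of called intervals against planted truth
#'
#' A called interval is a true positive when it overlaps at least one truth
#' interval; a truth interval is recovered when at least one call overlaps
#' it. Precision = true-positive calls / calls; recall = recovered truth /
#' truth.
#'
#' @param called,truth Interval tibbles (`chrom`, `start`, `end`).
#' @return Tibble `n_called`, `n_truth`, `n_tp`, `n_recovered`, `precision`,
#'   `recall`.
#' @export
interval_recovery <- function(called, truth) {
  assert_intervals(called); assert_intervals(truth)
  if (nrow(called) == 0 || nrow(truth) == 0) {
    return(tibble::tibble(
      n_called = nrow(called), n_truth = nrow(truth), n_tp = 0L,
      n_recovered = 0L,
      precision = if (nrow(called) == 0) NA_real_ else 0,
      recall = if (nrow(truth) == 0) NA_real_ else 0))
  }
  h <- GenomicRanges::findOverlaps(as_granges0(called), as_granges0(truth),
                                   ignore.strand = TRUE)
  tp <- length(unique(S4Vectors::queryHits(h)))
  rec <- length(unique(S4Vectors::subjectHits(h)))
  tibble::tibble(
    n_called = nrow(called), n_truth = nrow(truth),
    n_tp = tp, n_recovered = rec,
    precision = tp / nrow(called), recall = rec / nrow(truth))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table (1 = identical partitions, ~0 =
#' random agreement).
#'
#' @param a,b Label vectors of equal length.
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("labelings must have equal length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  expected <- sum_a * sum_b / n
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
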