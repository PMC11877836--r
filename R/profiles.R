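#' Pool methylation counts in fixed genomic windows
#'
#' Assigns every covered cytosine to the window `floor((pos - 1) / window)`
#' and pools methylated/total counts per window and context. Windows are
#' emitted for all requested contexts wherever the window holds at least one
#' cytosine of any context; a context with zero pooled reads keeps the row
#' with `fraction = NA` (flagged, not dropped).
#'
#' @param methylome A methylome tibble.
#' @param window Window width in bp (>= 1).
#' @param contexts Contexts to report.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `context`,
#'   `count_methylated`, `count_total`, `fraction`.
#' @export
window_methylation <- function(methylome, window = 50, contexts = CONTEXTS) {
  assert_methylome(methylome)
  stopifnot(window >= 1)
  window <- as.integer(window)
  methylome %>%
    dplyr::filter(.data$context %in% contexts) %>%
    dplyr::mutate(start = ((.data$pos - 1L) %/% window) * window) %>%
    dplyr::group_by(.data$chrom, .data$start, .data$context) %>%
    dplyr::summarise(count_methylated = sum(.data$count_methylated),
                     count_total = sum(.data$count_total), .groups = "drop") %>%
    tidyr::complete(tidyr::nesting(!!rlang::sym("chrom"), !!rlang::sym("start")),
                    context = contexts,
                    fill = list(count_methylated = 0L, count_total = 0L)) %>%
    dplyr::mutate(end = .data$start + window,
                  fraction = fraction_or_na(.data$count_methylated,
                                            .data$count_total)) %>%
    dplyr::select("chrom", "start", "end", "context",
                  "count_methylated", "count_total", "fraction") %>%
    dplyr::arrange(.data$chrom, .data$start, .data$context)
}

# pair every cytosine with every feature whose padded interval covers it;
# returns row indices into `methylome` (mi) and `features` (fi)
#' @importFrom S4Vectors queryHits subjectHits
overlap_pairs <- function(methylome, features, pad_left = 0L, pad_right = 0L) {
  gr_pos <- GenomicRanges::GRanges(
    methylome$chrom, IRanges::IRanges(methylome$pos, methylome$pos))
  gr_feat <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(start = pmax(features$start - pad_left, 0L) + 1L,
                     end = features$end + pad_right))
  h <- GenomicRanges::findOverlaps(gr_pos, gr_feat, ignore.strand = TRUE)
  list(mi = S4Vectors::queryHits(h), fi = S4Vectors::subjectHits(h))
}

# signed distance of a cytosine from a feature anchor in biological
# orientation; 5prime: first feature base = 0, upstream base = -1;
# 3prime: last feature base = -1, first downstream base = 0
anchor_rel <- function(pos0, start, end, strand, anchor) {
  if (anchor == "5prime") {
    ifelse(strand == "-", end - 1L - pos0, pos0 - start)
  } else {
    ifelse(strand == "-", start - 1L - pos0, pos0 - end)
  }
}

#' End-anchored methylation metaprofile over a feature set
#'
#' Aligns stranded features at their biological 5' or 3' end and pools
#' methylation in fixed bins from `span` bp outside to `span` bp inside the
#' feature. Inside the feature only bases belonging to the feature itself
#' contribute, so a feature shorter than `span` stops contributing past its
#' own length (the anti-skew rule: deep bins average only over features long
#' enough to reach them, and `n_features` records how many can). Bin values
#' are coverage-weighted pooled fractions (sum meth / sum total).
#'
#' @param methylome A methylome tibble.
#' @param features Stranded feature tibble (`chrom`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param anchor `"5prime"` or `"3prime"`.
#' @param bin Bin width in bp.
#' @param span Distance covered on each side of the anchor; multiple of
#'   `bin`.
#' @param contexts Contexts to report.
#' @return A `meta_profile` tibble: `anchor`, `bin_index`, `bin_start`,
#'   `bin_end` (anchor-relative), `context`, `count_methylated`,
#'   `count_total`, `fraction`, `n_features`.
#' @export
ends_metaprofile <- function(methylome, features, anchor = c("5prime", "3prime"),
                             bin = 100, span = 3000, contexts = CONTEXTS) {
  anchor <- match.arg(anchor)
  assert_methylome(methylome)
  assert_intervals(features)
  if (nrow(features) == 0) abort("empty feature list")
  if (span %% bin != 0) abort("span must be a multiple of bin")
  bin <- as.integer(bin); span <- as.integer(span)

  pr <- overlap_pairs(methylome, features, pad_left = span, pad_right = span)
  m <- methylome[pr$mi, ]
  f <- features[pr$fi, ]
  len <- f$end - f$start
  rel <- anchor_rel(m$pos - 1L, f$start, f$end, f$strand, anchor)
  keep <- if (anchor == "5prime") {
    (rel >= -span & rel < 0) | (rel >= 0 & rel < pmin(len, span))
  } else {
    (rel >= 0 & rel < span) | (rel < 0 & rel >= -pmin(len, span))
  }
  m <- m[keep, ]; rel <- rel[keep]

  lens <- features$end - features$start
  n_feat_bin <- function(k) {
    # bins fully outside the feature see every feature; inside bins only
    # features long enough to reach them
    inside <- if (anchor == "5prime") k >= 0 else k < 0
    if (!inside) return(nrow(features))
    d <- if (anchor == "5prime") k * bin else (-k - 1L) * bin
    sum(lens > d)
  }

  bins <- seq(-span %/% bin, span %/% bin - 1L)
  prof <- tibble::tibble(bin_index = rep(bins, each = length(contexts)),
                         context = rep(contexts, length(bins)))
  agg <- tibble::tibble(bin_index = rel %/% bin, context = m$context,
                        meth = m$count_methylated, total = m$count_total) %>%
    dplyr::filter(.data$context %in% contexts) %>%
    dplyr::group_by(.data$bin_index, .data$context) %>%
    dplyr::summarise(count_methylated = sum(.data$meth),
                     count_total = sum(.data$total), .groups = "drop")
  out <- prof %>%
    dplyr::left_join(agg, by = c("bin_index", "context")) %>%
    tidyr::replace_na(list(count_methylated = 0L, count_total = 0L)) %>%
    dplyr::mutate(
      anchor = anchor,
      bin_start = .data$bin_index * bin,
      bin_end = (.data$bin_index + 1L) * bin,
      fraction = fraction_or_na(.data$count_methylated, .data$count_total),
      n_features = vapply(.data$bin_index, n_feat_bin, numeric(1))
    ) %>%
    dplyr::select("anchor", "bin_index", "bin_start", "bin_end", "context",
                  "count_methylated", "count_total", "fraction", "n_features") %>%
    dplyr::arrange(.data$bin_index, .data$context)
  class(out) <- c("meta_profile", class(out))
  out
}

#' Scaled-body plus fixed-flank methylation profile
#'
#' Pools methylation across a feature set with the body of each feature
#' rescaled to `body_bins` equal-occupancy bins (a base at relative position
#' q in `[0, 1)` falls in bin `floor(q * body_bins)`, so features shorter
#' than `body_bins` bases still contribute proportionally) and fixed-width
#' bins across the flanking regions.
#'
#' @param methylome A methylome tibble.
#' @param features Stranded feature tibble.
#' @param flank Flank width in bp on each side (>= 0).
#' @param body_bins Number of scaled body bins (>= 1).
#' @param flank_bin Width of flank bins in bp.
#' @param contexts Contexts to report.
#' @return A `meta_profile` tibble with `region` (upstream/body/downstream),
#'   `bin_index` (continuous across the profile), pooled counts and
#'   fractions.
#' @export
flank_profile <- function(methylome, features, flank = 200, body_bins = 6,
                          flank_bin = 100, contexts = CONTEXTS) {
  assert_methylome(methylome)
  assert_intervals(features)
  if (nrow(features) == 0) abort("empty feature list")
  stopifnot(flank >= 0, body_bins >= 1)
  flank <- as.integer(flank); body_bins <- as.integer(body_bins)
  flank_bin <- as.integer(flank_bin)
  n_fl <- if (flank > 0) as.integer(ceiling(flank / flank_bin)) else 0L

  pr <- overlap_pairs(methylome, features, pad_left = flank, pad_right = flank)
  m <- methylome[pr$mi, ]
  f <- features[pr$fi, ]
  len <- f$end - f$start
  rel5 <- anchor_rel(m$pos - 1L, f$start, f$end, f$strand, "5prime")

  region <- dplyr::case_when(
    rel5 < 0 & rel5 >= -flank ~ "upstream",
    rel5 >= 0 & rel5 < len ~ "body",
    rel5 >= len & rel5 < len + flank ~ "downstream",
    TRUE ~ NA_character_
  )
  keep <- !is.na(region)
  m <- m[keep, ]; rel5 <- rel5[keep]; len <- len[keep]; region <- region[keep]

  bin_index <- integer(length(rel5))
  up <- region == "upstream"
  bin_index[up] <- (rel5[up] + flank) %/% flank_bin
  bd <- region == "body"
  bin_index[bd] <- n_fl + pmin(as.integer(rel5[bd] / len[bd] * body_bins),
                               body_bins - 1L)
  dn <- region == "downstream"
  bin_index[dn] <- n_fl + body_bins + (rel5[dn] - len[dn]) %/% flank_bin

  grid <- tibble::tibble(
    bin_index = c(seq_len(n_fl) - 1L, n_fl + seq_len(body_bins) - 1L,
                  n_fl + body_bins + seq_len(n_fl) - 1L),
    region = c(rep("upstream", n_fl), rep("body", body_bins),
               rep("downstream", n_fl))
  )
  grid <- tidyr::crossing(grid, context = contexts)
  agg <- tibble::tibble(bin_index = bin_index, context = m$context,
                        meth = m$count_methylated, total = m$count_total) %>%
    dplyr::filter(.data$context %in% contexts) %>%
    dplyr::group_by(.data$bin_index, .data$context) %>%
    dplyr::summarise(count_methylated = sum(.data$meth),
                     count_total = sum(.data$total), .groups = "drop")
  out <- grid %>%
    dplyr::left_join(agg, by = c("bin_index", "context")) %>%
    tidyr::replace_na(list(count_methylated = 0L, count_total = 0L)) %>%
    dplyr::mutate(fraction = fraction_or_na(.data$count_methylated,
                                            .data$count_total)) %>%
    dplyr::arrange(.data$bin_index, .data$context)
  class(out) <- c("meta_profile", class(out))
  out
}

#' Pool methylation over an interval set
#'
#' Sums methylated/total counts and counts covered cytosines per interval
#' and context. With `min_sites` set, an interval is flagged `substantial`
#' for a context when it holds at least that many covered cytosines of the
#' context — the operational reading of "windows with substantial
#' methylation" used for box-plot quantification.
#'
#' @param methylome A methylome tibble.
#' @param intervals Interval tibble (`chrom`, `start`, `end`, 0-based
#'   half-open; an `id` column is carried through, otherwise row numbers).
#' @param contexts Contexts to report.
#' @param min_sites Optional minimum covered-cytosine count for the
#'   `substantial` flag (default 4 when requested via `flag_substantial`).
#' @param seqlengths Optional named chromosome lengths; intervals beyond a
#'   chromosome end raise an error.
#' @return Tibble `id`, `chrom`, `start`, `end`, `context`, `n_sites`,
#'   `count_methylated`, `count_total`, `fraction` (+ `substantial` when
#'   `min_sites` is given).
#' @export
interval_quantify <- function(methylome, intervals, contexts = CONTEXTS,
                              min_sites = NULL, seqlengths = NULL) {
  assert_methylome(methylome)
  assert_intervals(intervals)
  if (!is.null(seqlengths)) {
    lim <- seqlengths[intervals$chrom]
    if (any(is.na(lim)) || any(intervals$end > lim)) {
      abort("interval beyond chromosome end")
    }
  }
  ivs <- intervals
  if (!"id" %in% names(ivs)) ivs$id <- as.character(seq_len(nrow(ivs)))

  pr <- overlap_pairs(methylome, ivs)
  m <- methylome[pr$mi, ]
  agg <- tibble::tibble(.row = pr$fi, context = m$context,
                        meth = m$count_methylated, total = m$count_total) %>%
    dplyr::filter(.data$context %in% contexts) %>%
    dplyr::group_by(.data$.row, .data$context) %>%
    dplyr::summarise(n_sites = dplyr::n(),
                     count_methylated = sum(.data$meth),
                     count_total = sum(.data$total), .groups = "drop")
  out <- tidyr::crossing(.row = seq_len(nrow(ivs)), context = contexts) %>%
    dplyr::left_join(agg, by = c(".row", "context")) %>%
    tidyr::replace_na(list(n_sites = 0L, count_methylated = 0L,
                           count_total = 0L)) %>%
    dplyr::mutate(id = ivs$id[.data$.row], chrom = ivs$chrom[.data$.row],
                  start = ivs$start[.data$.row], end = ivs$end[.data$.row],
                  fraction = fraction_or_na(.data$count_methylated,
                                            .data$count_total)) %>%
    dplyr::select("id", "chrom", "start", "end", "context", "n_sites",
                  "count_methylated", "count_total", "fraction")
  if (!is.null(min_sites)) {
    out$substantial <- out$n_sites >= min_sites
  }
  out
}
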