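#' Parameters for sliding-window DMR calling
#'
#' Defaults match the published RdDM-target definition: 50-bp windows with a
#' 50-bp step, cytosines effective when covered by at least 5 reads in both
#' conditions, windows retained with at least 10 effective cytosines, and
#' DMRs called at Benjamini-Hochberg q < 0.005 with an absolute percent
#' methylation difference above 10 points, in the CHH context.
#'
#' @param window Window width (bp).
#' @param step Step size (bp, <= window).
#' @param min_cov Minimum reads per cytosine per condition (inclusive).
#' @param min_cytosines Minimum effective cytosines per window (inclusive).
#' @param q_max q-value ceiling (strict).
#' @param min_diff Minimum absolute percent difference (strict, percentage
#'   points).
#' @param context Sequence context tested.
#' @return A `dmr_params` list.
#' @export
dmr_params <- function(window = 50, step = 50, min_cov = 5,
                       min_cytosines = 10, q_max = 0.005, min_diff = 10,
                       context = "CHH") {
  if (step > window) abort("step must be <= window")
  p <- list(window = as.integer(window), step = as.integer(step),
            min_cov = as.integer(min_cov),
            min_cytosines = as.integer(min_cytosines),
            q_max = q_max, min_diff = min_diff, context = context)
  if (any(unlist(p[c("min_cov", "min_cytosines", "q_max", "min_diff")]) < 0)) {
    abort("dmr_params thresholds must be >= 0")
  }
  structure(p, class = "dmr_params")
}

#' Call differentially methylated regions between two conditions
#'
#' Scans the genome in sliding windows over one context. Effective cytosines
#' are positions covered by at least `min_cov` reads in both conditions;
#' windows with at least `min_cytosines` effective cytosines are tested with
#' a two-sided Fisher's exact test on pooled counts, corrected by
#' Benjamini-Hochberg across retained windows. A window is a DMR when
#' q < `q_max` and the absolute percent methylation difference exceeds
#' `min_diff` points. With `step < window`, overlapping significant windows
#' are deduplicated by keeping the lowest-q window in each overlapping run.
#'
#' @param cond_a,cond_b Methylome tibbles for the two conditions (e.g. a
#'   wild type and an RdDM mutant).
#' @param params A [dmr_params()].
#' @return A `dmr_result` with `$windows` (all retained windows and their
#'   statistics) and `$dmrs` (tibble: interval, `n_cytosines`, `fraction_a`,
#'   `fraction_b`, `meth_diff` = a - b on the fraction scale, `pvalue`,
#'   `qvalue`, `direction` = hyper when a > b).
#' @export
call_dmrs <- function(cond_a, cond_b, params = dmr_params()) {
  assert_methylome(cond_a); assert_methylome(cond_b)
  a <- cond_a %>%
    dplyr::filter(.data$context == params$context,
                  .data$count_total >= params$min_cov)
  b <- cond_b %>%
    dplyr::filter(.data$context == params$context,
                  .data$count_total >= params$min_cov)
  eff <- dplyr::inner_join(a, b, by = c("chrom", "pos", "strand"),
                           suffix = c("_a", "_b"))
  if (nrow(eff) == 0) {
    warn("no effective cytosines shared between conditions")
    empty <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      n_cytosines = integer(), fraction_a = numeric(), fraction_b = numeric(),
      meth_diff = numeric(), pvalue = numeric(), qvalue = numeric(),
      direction = character())
    return(structure(list(windows = empty, dmrs = empty, params = params),
                     class = "dmr_result"))
  }
  offsets <- seq(0L, params$window - 1L, by = params$step)
  offsets <- offsets[offsets %% params$step == 0 & offsets < params$window]
  wins <- purrr::map_dfr(offsets, function(off) {
    eff %>%
      dplyr::mutate(start = ((.data$pos - 1L - off) %/% params$window) *
                      params$window + off) %>%
      dplyr::filter(.data$start >= 0) %>%
      dplyr::group_by(.data$chrom, .data$start) %>%
      dplyr::summarise(
        n_cytosines = dplyr::n(),
        meth_a = sum(.data$count_methylated_a),
        total_a = sum(.data$count_total_a),
        meth_b = sum(.data$count_methylated_b),
        total_b = sum(.data$count_total_b),
        .groups = "drop")
  }) %>%
    dplyr::distinct(.data$chrom, .data$start, .keep_all = TRUE) %>%
    dplyr::filter(.data$n_cytosines >= params$min_cytosines)

  if (nrow(wins) == 0) {
    warn("no windows passed the effective-cytosine filter")
  }
  wins <- wins %>%
    dplyr::mutate(
      end = .data$start + params$window,
      fraction_a = fraction_or_na(.data$meth_a, .data$total_a),
      fraction_b = fraction_or_na(.data$meth_b, .data$total_b),
      meth_diff = .data$fraction_a - .data$fraction_b,
      pvalue = fisher_exact_2x2(.data$meth_a, .data$total_a - .data$meth_a,
                                .data$meth_b, .data$total_b - .data$meth_b),
      qvalue = stats::p.adjust(.data$pvalue, method = "BH"),
      direction = ifelse(.data$meth_diff > 0, "hyper", "hypo")
    ) %>%
    dplyr::select("chrom", "start", "end", "n_cytosines", "fraction_a",
                  "fraction_b", "meth_diff", "pvalue", "qvalue", "direction") %>%
    dplyr::arrange(.data$chrom, .data$start)

  dmrs <- wins %>%
    dplyr::filter(.data$qvalue < params$q_max,
                  abs(.data$meth_diff) * 100 > params$min_diff)
  if (params$step < params$window && nrow(dmrs) > 1) {
    # overlapping-step extension: keep the lowest-q window per overlapping run
    dmrs <- dmrs %>%
      dplyr::group_by(.data$chrom) %>%
      dplyr::mutate(run = cumsum(dplyr::coalesce(
        .data$start >= dplyr::lag(cummax(.data$end)), TRUE))) %>%
      dplyr::group_by(.data$chrom, .data$run) %>%
      dplyr::slice_min(.data$qvalue, n = 1, with_ties = FALSE) %>%
      dplyr::ungroup() %>%
      dplyr::select(-"run")
  }
  structure(list(windows = wins, dmrs = dmrs, params = params),
            class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat(sprintf("DMR call (%s): %d retained windows, %d DMRs (%d hyper, %d hypo)\n",
              x$params$context, nrow(x$windows), nrow(x$dmrs),
              sum(x$dmrs$direction == "hyper"),
              sum(x$dmrs$direction == "hypo")))
  invisible(x)
}

#' Lift loci through a homology mapping table
#'
#' Consumes the tabular output of an external homology search (e.g. BLASTN
#' hits filtered at E <= 1e-5 and identity >= 90) and lifts each locus
#' through its best mapping: lowest e-value, then highest identity, then
#' longest target interval. The locus is offset from the source interval
#' start and clipped to the target interval. Loci overlapping no mapping row
#' are reported separately.
#'
#' @param loci Interval tibble in source coordinates.
#' @param mapping Tibble with `src_chrom`, `src_start`, `src_end`,
#'   `tgt_chrom`, `tgt_start`, `tgt_end` and optional `identity`, `evalue`.
#' @return List with `lifted` (loci in target coordinates, with provenance
#'   columns) and `unmapped` (input rows with no mapping).
#' @export
homolog_transfer <- function(loci, mapping) {
  assert_intervals(loci)
  need <- c("src_chrom", "src_start", "src_end",
            "tgt_chrom", "tgt_start", "tgt_end")
  miss <- setdiff(need, names(mapping))
  if (length(miss) > 0) {
    abort(paste0("mapping is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!"identity" %in% names(mapping)) mapping$identity <- NA_real_
  if (!"evalue" %in% names(mapping)) mapping$evalue <- NA_real_
  if (!"id" %in% names(loci)) loci$id <- as.character(seq_len(nrow(loci)))

  src <- dplyr::rename(mapping, chrom = "src_chrom", start = "src_start",
                       end = "src_end")
  pr_q <- GenomicRanges::findOverlaps(
    as_granges0(loci), as_granges0(src), ignore.strand = TRUE)
  hits <- tibble::tibble(li = S4Vectors::queryHits(pr_q),
                         mi = S4Vectors::subjectHits(pr_q))
  best <- hits %>%
    dplyr::mutate(evalue = mapping$evalue[.data$mi],
                  identity = mapping$identity[.data$mi],
                  tgt_len = mapping$tgt_end[.data$mi] -
                    mapping$tgt_start[.data$mi]) %>%
    dplyr::group_by(.data$li) %>%
    dplyr::arrange(.data$evalue, dplyr::desc(.data$identity),
                   dplyr::desc(.data$tgt_len), .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()

  lifted <- loci[best$li, ]
  mp <- mapping[best$mi, ]
  off <- lifted$start - mp$src_start
  new_start <- pmax(mp$tgt_start + off, mp$tgt_start)
  new_end <- pmin(mp$tgt_start + off + (lifted$end - lifted$start),
                  mp$tgt_end)
  lifted$src_chrom <- lifted$chrom
  lifted$src_start <- lifted$start
  lifted$src_end <- lifted$end
  lifted$chrom <- mp$tgt_chrom
  lifted$start <- new_start
  lifted$end <- pmax(new_end, new_start)
  lifted$mapping_evalue <- mp$evalue
  lifted$mapping_identity <- mp$identity

  unmapped <- loci[setdiff(seq_len(nrow(loci)), best$li), ]
  list(lifted = lifted, unmapped = unmapped)
}
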