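#' Parameters for the sex-lineage hypermethylated-locus caller
#'
#' Defaults reproduce the published screening rule: 50-bp windows whose
#' per-context methylation differentials (mean of sex-cell groups minus the
#' somatic group) are all positive and sum above 0.2 are merged when within
#' 100 bp, retained at >= 100 bp, tested by Fisher's exact test on pooled
#' total methylation at p < 0.001, required to be higher in every sex cell
#' type than in the somatic tissue, and classified by somatic RdDM activity:
#' SLM-like when somatic CHH < 0.05 and CHG < 0.1, canonical SLH-like
#' otherwise.
#'
#' @param window Screening window width (bp).
#' @param merge_gap Maximum gap between candidate windows merged into one
#'   locus (bp, inclusive).
#' @param min_len Minimum merged-locus length (bp, inclusive).
#' @param sum_diff_min Minimum summed per-context differential (strict).
#' @param p_max Fisher p-value ceiling (strict).
#' @param leaf_chh_max,leaf_chg_max Somatic CHH/CHG ceilings for the
#'   SLM-like label (strict "lower than").
#' @return An `slm_params` list.
#' @export
slm_params <- function(window = 50, merge_gap = 100, min_len = 100,
                       sum_diff_min = 0.2, p_max = 0.001,
                       leaf_chh_max = 0.05, leaf_chg_max = 0.1) {
  p <- list(window = as.integer(window), merge_gap = as.integer(merge_gap),
            min_len = as.integer(min_len), sum_diff_min = sum_diff_min,
            p_max = p_max, leaf_chh_max = leaf_chh_max,
            leaf_chg_max = leaf_chg_max)
  if (any(unlist(p) < 0)) abort("slm_params thresholds must be >= 0")
  if (p$sum_diff_min > 3) abort("sum_diff_min cannot exceed 3")
  structure(p, class = "slm_params")
}

#' Screen windows for sex-cell hypermethylation
#'
#' Computes per-window per-context fractional methylation for each group,
#' drops windows lacking coverage in any group for any context, and keeps
#' windows with `diff_CG > 0 & diff_CHG > 0 & diff_CHH > 0` and
#' `diff_CG + diff_CHG + diff_CHH > sum_diff_min`, where each differential is
#' the unweighted mean over sex groups minus the somatic fraction. All
#' inequalities are strict.
#'
#' @param methylomes Named list of merged, coverage-filtered methylome
#'   tibbles (one per sample group).
#' @param sex_groups Character vector of sex-cell group names (>= 1).
#' @param somatic_group Name of the single somatic group.
#' @param params An [slm_params()].
#' @return Candidate-window tibble `chrom`, `start`, `end`, `diff_cg`,
#'   `diff_chg`, `diff_chh`, `sum_diff`.
#' @export
screen_windows <- function(methylomes, sex_groups, somatic_group,
                           params = slm_params()) {
  if (length(sex_groups) < 1) abort("need at least one sex group")
  if (length(somatic_group) != 1) abort("need exactly one somatic group")
  groups <- c(sex_groups, somatic_group)
  miss <- setdiff(groups, names(methylomes))
  if (length(miss) > 0) {
    abort(paste0("methylomes missing groups: ", paste(miss, collapse = ", ")))
  }
  wins <- purrr::map(
    methylomes[groups],
    ~ window_methylation(.x, window = params$window) %>%
      dplyr::select("chrom", "start", "end", "context", "fraction")
  )
  wide <- purrr::imap(wins, function(w, g) {
    names(w)[names(w) == "fraction"] <- g
    w
  }) %>%
    purrr::reduce(dplyr::inner_join, by = c("chrom", "start", "end", "context"))
  # a window-context with zero coverage in any group is excluded
  ok <- stats::complete.cases(wide[groups])
  wide <- wide[ok, ]
  sex_mean <- rowMeans(as.matrix(wide[sex_groups]))
  wide$diff <- sex_mean - wide[[somatic_group]]
  d <- wide %>%
    dplyr::select("chrom", "start", "end", "context", "diff") %>%
    tidyr::pivot_wider(names_from = "context", values_from = "diff")
  for (ctx in CONTEXTS) if (!ctx %in% names(d)) d[[ctx]] <- NA_real_
  d <- d[stats::complete.cases(d[CONTEXTS]), ]  # need all three contexts
  d %>%
    dplyr::rename(diff_cg = "CG", diff_chg = "CHG", diff_chh = "CHH") %>%
    dplyr::mutate(sum_diff = .data$diff_cg + .data$diff_chg + .data$diff_chh) %>%
    dplyr::filter(.data$diff_cg > 0, .data$diff_chg > 0, .data$diff_chh > 0,
                  .data$sum_diff > params$sum_diff_min) %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Merge candidate windows into loci
#'
#' Greedy left-to-right merge: consecutive candidate windows on a chromosome
#' are joined while the gap between them (next start minus current end) is at
#' most `merge_gap`; merged intervals shorter than `min_len` are dropped.
#'
#' @param windows Candidate windows from [screen_windows()] (or any sorted
#'   interval tibble).
#' @param params An [slm_params()].
#' @return Tibble `chrom`, `start`, `end`, `n_windows`, `length`.
#' @export
merge_candidates <- function(windows, params = slm_params()) {
  assert_intervals(windows)
  if (nrow(windows) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_windows = integer(),
                          length = integer()))
  }
  windows %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(gap = .data$start - dplyr::lag(.data$end),
                  new_run = dplyr::coalesce(.data$gap > params$merge_gap, TRUE),
                  run = cumsum(.data$new_run)) %>%
    dplyr::group_by(.data$chrom, .data$run) %>%
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_windows = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(length = .data$end - .data$start) %>%
    dplyr::filter(.data$length >= params$min_len) %>%
    dplyr::select("chrom", "start", "end", "n_windows", "length") %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Sex-versus-somatic consistency filter
#'
#' A locus passes only when its pooled all-context methylation fraction is
#' strictly higher in every sex group than in the somatic group. A sex group
#' with no covered reads over the locus cannot assert "higher" and fails.
#'
#' @param sex_fractions Numeric matrix (loci x sex groups) or vector of
#'   pooled all-context fractions per sex group.
#' @param somatic_fraction Numeric vector (or scalar) of somatic pooled
#'   fractions.
#' @return Logical vector, one element per locus.
#' @export
consistency_filter <- function(sex_fractions, somatic_fraction) {
  m <- as.matrix(sex_fractions)
  if (length(somatic_fraction) == 1) {
    somatic_fraction <- rep(somatic_fraction, nrow(m))
  }
  ok <- sweep(m, 1, somatic_fraction, ">")
  ok[is.na(ok)] <- FALSE
  rowSums(ok) == ncol(m) & !is.na(somatic_fraction)
}

#' Classify loci by somatic RdDM activity
#'
#' SLM-like loci show low RdDM activity in somatic tissue: somatic CHH
#' strictly below `leaf_chh_max` and CHG strictly below `leaf_chg_max`.
#' Anything else (including boundary values and loci whose somatic fraction
#' cannot be computed) is a canonical SLH-like locus, an RdDM target already
#' methylated in somatic tissue.
#'
#' @param leaf_chh,leaf_chg Somatic CHH and CHG fractions over each locus.
#' @param params An [slm_params()].
#' @return Character vector: `"SLM_like"` or `"canonical_SLH_like"`.
#' @export
classify_locus <- function(leaf_chh, leaf_chg, params = slm_params()) {
  ifelse(!is.na(leaf_chh) & !is.na(leaf_chg) &
           leaf_chh < params$leaf_chh_max & leaf_chg < params$leaf_chg_max,
         "SLM_like", "canonical_SLH_like")
}

#' Call sex-lineage hypermethylated loci
#'
#' Full pipeline: window screening, merging, Fisher's exact test on pooled
#' total methylation (all contexts, sex groups pooled against the somatic
#' group, two-sided, p < `p_max`), the all-sex-cells consistency filter, and
#' SLM/SLH classification.
#'
#' @param methylomes Named list of merged, coverage-filtered methylome
#'   tibbles.
#' @param sex_groups Sex-cell group names.
#' @param somatic_group Somatic group name.
#' @param params An [slm_params()].
#' @return An `slm_result` with `$loci` (tibble: interval, per-context
#'   differentials, somatic fractions, `fisher_p`, `label`, `n_windows`),
#'   `$candidates` (merged intervals before testing), and `$summary`
#'   (n_total, n_slm_like, n_slh_like, mean_length_bp).
#' @export
call_slm <- function(methylomes, sex_groups, somatic_group,
                     params = slm_params()) {
  cand_windows <- screen_windows(methylomes, sex_groups, somatic_group, params)
  if (nrow(cand_windows) == 0) {
    warn("no candidate windows passed the differential screen")
  }
  loci <- merge_candidates(cand_windows, params)
  groups <- c(sex_groups, somatic_group)

  if (nrow(loci) > 0) {
    loci$id <- sprintf("locus%04d", seq_len(nrow(loci)))
    quant <- purrr::map(methylomes[groups], function(m) {
      interval_quantify(m, loci)
    })
    # pooled all-context counts per locus per group
    pooled <- purrr::imap_dfr(quant, function(q, g) {
      q %>%
        dplyr::group_by(.data$id) %>%
        dplyr::summarise(meth = sum(.data$count_methylated),
                         total = sum(.data$count_total), .groups = "drop") %>%
        dplyr::mutate(group = g)
    })
    sex_meth <- pooled %>%
      dplyr::filter(.data$group %in% sex_groups) %>%
      dplyr::group_by(.data$id) %>%
      dplyr::summarise(meth = sum(.data$meth), total = sum(.data$total))
    som <- pooled %>% dplyr::filter(.data$group == somatic_group)
    ord <- match(loci$id, sex_meth$id)
    sm <- sex_meth[ord, ]
    so <- som[match(loci$id, som$id), ]
    loci$fisher_p <- fisher_exact_2x2(sm$meth, sm$total - sm$meth,
                                      so$meth, so$total - so$meth)

    frac_mat <- sapply(sex_groups, function(g) {
      p <- pooled[pooled$group == g, ]
      p <- p[match(loci$id, p$id), ]
      fraction_or_na(p$meth, p$total)
    })
    frac_mat <- matrix(frac_mat, nrow = nrow(loci),
                       dimnames = list(NULL, sex_groups))
    som_frac <- fraction_or_na(so$meth, so$total)
    loci$consistent <- consistency_filter(frac_mat, som_frac)

    ctx_frac <- function(g, ctx) {
      q <- quant[[g]]
      q <- q[q$context == ctx, ]
      q$fraction[match(loci$id, q$id)]
    }
    loci$somatic_chh <- ctx_frac(somatic_group, "CHH")
    loci$somatic_chg <- ctx_frac(somatic_group, "CHG")
    for (ctx in CONTEXTS) {
      sx <- rowMeans(matrix(sapply(sex_groups, ctx_frac, ctx = ctx),
                            nrow = nrow(loci)))
      loci[[paste0("diff_", tolower(ctx))]] <- sx - ctx_frac(somatic_group, ctx)
    }
    loci$sex_fraction <- fraction_or_na(sm$meth, sm$total)
    loci$somatic_fraction <- som_frac

    candidates <- loci
    loci <- loci %>%
      dplyr::filter(.data$fisher_p < params$p_max, .data$consistent) %>%
      dplyr::mutate(label = classify_locus(.data$somatic_chh,
                                           .data$somatic_chg, params)) %>%
      dplyr::select("id", "chrom", "start", "end", "length", "n_windows",
                    "diff_cg", "diff_chg", "diff_chh", "sex_fraction",
                    "somatic_fraction", "somatic_chh", "somatic_chg",
                    "fisher_p", "label")
  } else {
    candidates <- loci
    loci <- tibble::tibble(
      id = character(), chrom = character(), start = integer(),
      end = integer(), length = integer(), n_windows = integer(),
      diff_cg = numeric(), diff_chg = numeric(), diff_chh = numeric(),
      sex_fraction = numeric(), somatic_fraction = numeric(),
      somatic_chh = numeric(), somatic_chg = numeric(),
      fisher_p = numeric(), label = character())
  }

  structure(list(
    loci = loci,
    candidates = candidates,
    summary = tibble::tibble(
      n_total = nrow(loci),
      n_slm_like = sum(loci$label == "SLM_like"),
      n_slh_like = sum(loci$label == "canonical_SLH_like"),
      mean_length_bp = if (nrow(loci)) mean(loci$length) else NA_real_
    ),
    sex_groups = sex_groups, somatic_group = somatic_group, params = params
  ), class = "slm_result")
}

#' @export
print.slm_result <- function(x, ...) {
  s <- x$summary
  cat("Sex-lineage hypermethylated locus call\n")
  cat(sprintf("  %d loci (%d SLM-like, %d canonical SLH-like), mean length %.1f bp\n",
              s$n_total, s$n_slm_like, s$n_slh_like, s$mean_length_bp))
  cat(sprintf("  sex groups: %s; somatic: %s\n",
              paste(x$sex_groups, collapse = ", "), x$somatic_group))
  invisible(x)
}

#' Write called loci as BED6 and TSV
#'
#' BED names carry the label and scores are -log10 Fisher p (capped at 320).
#'
#' @param result An `slm_result`.
#' @param bed_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_slm_result <- function(result, bed_path = NULL, tsv_path = NULL) {
  loci <- result$loci
  if (!is.null(bed_path)) {
    out <- loci %>%
      dplyr::mutate(id = .data$label,
                    strand = ".") %>%
      dplyr::select("chrom", "start", "end", "id", "strand")
    write_bed6(out, bed_path,
               score = round(pmin(-log10(pmax(loci$fisher_p, 1e-320)), 320), 2))
  }
  if (!is.null(tsv_path)) readr::write_tsv(loci, tsv_path, progress = FALSE)
  invisible(c(bed_path, tsv_path))
}
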