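#' Classify differential-expression records
#'
#' Applies the standard thresholds to an externally produced DEG table:
#' `up` when p < `p_max` and log2 fold change >= `lfc_min`, `down` when
#' p < `p_max` and log2 fold change <= -`lfc_min`, otherwise `ns`. The fold
#' change bound is inclusive; records with missing statistics are flagged
#' `ns` with a warning.
#'
#' @param table Tibble with `gene`, `contrast`, `log2fc`, `pvalue`.
#' @param p_max P-value ceiling (strict).
#' @param lfc_min Absolute log2 fold-change floor (inclusive).
#' @return The table with a `direction` column.
#' @export
deg_classify <- function(table, p_max = 0.05, lfc_min = 1) {
  need <- c("gene", "contrast", "log2fc", "pvalue")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    abort(paste0("DEG table missing columns: ", paste(miss, collapse = ", ")))
  }
  na <- is.na(table$log2fc) | is.na(table$pvalue)
  if (any(na)) {
    warn(paste0(sum(na), " records lack statistics; flagged ns"))
  }
  table %>%
    dplyr::mutate(direction = dplyr::case_when(
      is.na(.data$log2fc) | is.na(.data$pvalue) ~ "ns",
      .data$pvalue < p_max & .data$log2fc >= lfc_min ~ "up",
      .data$pvalue < p_max & .data$log2fc <= -lfc_min ~ "down",
      TRUE ~ "ns"))
}

#' Intersect locus-targeted genes with differential expression
#'
#' Per contrast, counts up- and down-regulated genes and their intersection
#' with a locus-targeted gene list, and over the union of contrasts the
#' fraction of targeted genes differentially expressed in at least one
#' contrast (denominator = the full targeted list, reported explicitly).
#'
#' @param deg A classified DEG table from [deg_classify()].
#' @param slm_genes Character vector of locus-targeted gene ids.
#' @return List with `per_contrast` (tibble: contrast, total_up, total_down,
#'   up_slm, down_slm), `union` (tibble: n_slm_genes, n_up_union,
#'   n_down_union, n_de_union, fraction_de).
#' @export
slm_deg_overlap <- function(deg, slm_genes) {
  if (!"direction" %in% names(deg)) deg <- deg_classify(deg)
  slm_genes <- unique(slm_genes)
  if (length(slm_genes) > 0 && !any(slm_genes %in% deg$gene)) {
    warn("no targeted gene ids found in the DEG table (id space mismatch?)")
  }
  per <- deg %>%
    dplyr::group_by(.data$contrast) %>%
    dplyr::summarise(
      total_up = sum(.data$direction == "up"),
      total_down = sum(.data$direction == "down"),
      up_slm = sum(.data$direction == "up" & .data$gene %in% slm_genes),
      down_slm = sum(.data$direction == "down" & .data$gene %in% slm_genes),
      .groups = "drop")
  up_union <- unique(deg$gene[deg$direction == "up" & deg$gene %in% slm_genes])
  down_union <- unique(deg$gene[deg$direction == "down" &
                                  deg$gene %in% slm_genes])
  de_union <- union(up_union, down_union)
  uni <- tibble::tibble(
    n_slm_genes = length(slm_genes),
    n_up_union = length(up_union),
    n_down_union = length(down_union),
    n_de_union = length(de_union),
    fraction_de = if (length(slm_genes) > 0) {
      length(de_union) / length(slm_genes)
    } else {
      NA_real_
    })
  list(per_contrast = per, union = uni)
}

#' Venn region counts for two or three named sets
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Tibble `region` (e.g. `"A"`, `"A&B"`), `n`; regions are exclusive
#'   and sum to the union size.
#' @export
venn_counts <- function(sets) {
  n <- length(sets)
  if (n < 2 || n > 3) abort("venn_counts supports 2 or 3 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_len(n)]
  }
  sets <- purrr::map(sets, unique)
  all_ids <- unique(unlist(sets))
  memb <- sapply(sets, function(s) all_ids %in% s)
  memb <- matrix(memb, ncol = n, dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  combos <- unlist(purrr::map(seq_len(n), function(k) {
    utils::combn(names(sets), k, FUN = paste, collapse = "&")
  }))
  tibble::tibble(region = combos,
                 n = as.integer(table(factor(key, levels = combos))))
}
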