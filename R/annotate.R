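#' Classify loci by proximity to annotated features
#'
#' For each feature kind (gene, TE) independently, a locus is `overlapping`
#' when it shares at least one base with a feature, `within_near` when the
#' closest feature edge lies within `near` bp (inclusive; adjacency counts
#' as distance 0 without overlap), and `beyond_near` otherwise. Distance is
#' between closest interval edges in half-open coordinates and ignores
#' strand.
#'
#' @param loci Interval tibble.
#' @param features Feature tibble with a `kind` column (`gene` / `TE`).
#' @param near Distance threshold in bp (inclusive).
#' @return Tibble of loci with one class column per feature kind
#'   (`class_gene`, `class_TE`, ...).
#' @export
proximity_classify <- function(loci, features, near = 500) {
  assert_intervals(loci); assert_intervals(features)
  if (!"id" %in% names(loci)) loci$id <- as.character(seq_len(nrow(loci)))
  gl <- as_granges0(loci)
  out <- dplyr::select(loci, "id", "chrom", "start", "end")
  for (k in unique(features$kind)) {
    f <- features[features$kind == k, ]
    cls <- rep("beyond_near", nrow(loci))
    if (nrow(f) > 0) {
      gf <- as_granges0(f)
      d <- GenomicRanges::distanceToNearest(gl, gf, ignore.strand = TRUE)
      dist <- rep(NA_real_, nrow(loci))
      dist[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
      ov <- GenomicRanges::countOverlaps(gl, gf, ignore.strand = TRUE) > 0
      cls[!is.na(dist) & dist <= near] <- "within_near"
      cls[ov] <- "overlapping"
    }
    out[[paste0("class_", k)]] <- cls
  }
  out
}

#' Per-kind proximity percentages
#'
#' @param classified Output of [proximity_classify()].
#' @return Long tibble `kind`, `class`, `n`, `percent`; the three classes
#'   partition each locus set so percentages sum to 100 per kind.
#' @export
proximity_summary <- function(classified) {
  cols <- grep("^class_", names(classified), value = TRUE)
  purrr::map_dfr(cols, function(cl) {
    tibble::tibble(kind = sub("^class_", "", cl),
                   class = factor(classified[[cl]],
                                  levels = c("overlapping", "within_near",
                                             "beyond_near"))) %>%
      dplyr::count(.data$kind, .data$class, .drop = FALSE, name = "n") %>%
      dplyr::mutate(percent = 100 * .data$n / sum(.data$n))
  })
}

#' Genes targeted by loci
#'
#' A gene is targeted by a locus when it overlaps the locus or lies within
#' `near` bp of it (inclusive). A locus may target several genes and a gene
#' several loci; pairs are returned with locus provenance plus the
#' deduplicated gene list.
#'
#' @param loci Interval tibble (an `id` column is used when present).
#' @param features Feature tibble; only rows with `kind == "gene"` are used
#'   (or all rows if there is no `kind` column).
#' @param near Distance threshold in bp (inclusive).
#' @return List with `pairs` (tibble `locus_id`, `gene_id`, `distance`) and
#'   `genes` (character vector of distinct targeted gene ids).
#' @export
target_genes <- function(loci, features, near = 500) {
  assert_intervals(loci); assert_intervals(features)
  if ("kind" %in% names(features)) features <- features[features$kind == "gene", ]
  if (!"id" %in% names(loci)) loci$id <- as.character(seq_len(nrow(loci)))
  if (!"id" %in% names(features)) {
    features$id <- as.character(seq_len(nrow(features)))
  }
  if (nrow(loci) == 0 || nrow(features) == 0) {
    return(list(pairs = tibble::tibble(locus_id = character(),
                                       gene_id = character(),
                                       distance = numeric()),
                genes = character()))
  }
  gl <- as_granges0(loci)
  gf <- as_granges0(features)
  h <- GenomicRanges::findOverlaps(gl, gf, maxgap = near, ignore.strand = TRUE)
  li <- S4Vectors::queryHits(h); fi <- S4Vectors::subjectHits(h)
  dist <- GenomicRanges::distance(gl[li], gf[fi], ignore.strand = TRUE)
  pairs <- tibble::tibble(locus_id = loci$id[li], gene_id = features$id[fi],
                          distance = as.numeric(dist)) %>%
    dplyr::filter(.data$distance <= near) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$locus_id, .data$gene_id)
  list(pairs = pairs, genes = unique(pairs$gene_id))
}

#' Overlap counts between two interval sets
#'
#' Counts intervals private to each set and the number of distinct
#' overlapping pairs (symmetric in the two sets) at a minimum overlap of
#' `min_overlap` bp.
#'
#' @param set_a,set_b Interval tibbles.
#' @param min_overlap Minimum shared bases (>= 1).
#' @return Tibble `n_a_only`, `n_b_only`, `n_shared` (overlapping pairs).
#' @export
locus_set_overlap <- function(set_a, set_b, min_overlap = 1) {
  assert_intervals(set_a); assert_intervals(set_b)
  ga <- as_granges0(set_a); gb <- as_granges0(set_b)
  h <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap,
                                   ignore.strand = TRUE)
  tibble::tibble(
    n_a_only = nrow(set_a) - length(unique(S4Vectors::queryHits(h))),
    n_b_only = nrow(set_b) - length(unique(S4Vectors::subjectHits(h))),
    n_shared = length(h)
  )
}
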