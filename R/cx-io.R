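#' Read a per-cytosine methylation call table
#'
#' Two dialects are supported. `"cx"` is the Bismark-style CX report: seven
#' tab-separated columns `chrom`, `pos` (1-based), `strand`,
#' `count_methylated`, `count_unmethylated`, `context`, `trinucleotide`.
#' `"bedgraph_cov"` carries a fraction plus coverage: `chrom`, `pos`,
#' `strand`, `context`, `fraction`, `count_total`; methylated counts are
#' recovered as `fraction * count_total`, which must be integral.
#' Malformed lines (unknown context token, fraction outside `[0, 1]`,
#' non-integral methylated count, methylated exceeding total, duplicated
#' (chrom, pos, strand)) are rejected with their line number.
#'
#' @param path File path.
#' @param dialect `"cx"` or `"bedgraph_cov"`.
#' @return A methylome tibble (`chrom`, `pos`, `strand`, `context`,
#'   `count_methylated`, `count_total`), sorted by (chrom, pos, strand).
#' @export
read_cx_report <- function(path, dialect = c("cx", "bedgraph_cov")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "cx") {
    df <- readr::read_tsv(
      path,
      col_names = c("chrom", "pos", "strand", "count_methylated",
                    "count_unmethylated", "context", "trinucleotide"),
      col_types = "cicincc", progress = FALSE
    )
    df$count_methylated <- as.integer(df$count_methylated)
    df$count_total <- df$count_methylated + as.integer(df$count_unmethylated)
  } else {
    df <- readr::read_tsv(
      path,
      col_names = c("chrom", "pos", "strand", "context", "fraction",
                    "count_total"),
      col_types = "ciccni", progress = FALSE
    )
    bad <- which(df$fraction < 0 | df$fraction > 1)
    if (length(bad) > 0) {
      abort(paste0("line ", bad[1], ": fraction ", df$fraction[bad[1]],
                   " outside [0, 1] (methylated exceeds total?)"))
    }
    meth <- df$fraction * df$count_total
    bad <- which(abs(meth - round(meth)) > 1e-6)
    if (length(bad) > 0) {
      abort(paste0("line ", bad[1],
                   ": fraction * coverage is not an integer count"))
    }
    df$count_methylated <- as.integer(round(meth))
  }
  bad <- which(is.na(df$pos) | df$pos < 1)
  if (length(bad) > 0) abort(paste0("line ", bad[1], ": invalid position"))
  bad <- which(!df$context %in% CONTEXTS)
  if (length(bad) > 0) {
    abort(paste0("line ", bad[1], ": unknown context token '",
                 df$context[bad[1]], "'"))
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0) abort(paste0("line ", bad[1], ": invalid strand"))
  bad <- which(df$count_methylated > df$count_total | df$count_methylated < 0)
  if (length(bad) > 0) {
    abort(paste0("line ", bad[1], ": count_methylated ",
                 df$count_methylated[bad[1]], " exceeds count_total ",
                 df$count_total[bad[1]]))
  }
  key <- paste(df$chrom, df$pos, df$strand)
  bad <- which(duplicated(key))
  if (length(bad) > 0) {
    abort(paste0("line ", bad[1], ": duplicate position ", key[bad[1]]))
  }
  df %>%
    dplyr::select("chrom", "pos", "strand", "context",
                  "count_methylated", "count_total") %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
}

#' Write a methylome table as a CX report
#'
#' Emits the seven-column CX dialect understood by [read_cx_report()]. The
#' trinucleotide column is filled from a `trinucleotide` column when present,
#' otherwise with the context token.
#'
#' @param methylome A methylome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(methylome, path) {
  assert_methylome(methylome)
  out <- tibble::tibble(
    chrom = methylome$chrom, pos = methylome$pos, strand = methylome$strand,
    count_methylated = methylome$count_methylated,
    count_unmethylated = methylome$count_total - methylome$count_methylated,
    context = methylome$context,
    trinucleotide = if ("trinucleotide" %in% names(methylome)) {
      methylome$trinucleotide
    } else {
      methylome$context
    }
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Merge replicate methylomes by summing counts
#'
#' Counts are summed per (chrom, pos, strand) across replicates, the standard
#' pooling applied to biological replicates after their correlation has been
#' confirmed. Context must agree wherever replicates share a site.
#'
#' @param replicates A list of methylome tibbles (>= 1).
#' @return A single merged methylome tibble.
#' @export
merge_replicates <- function(replicates) {
  if (is.data.frame(replicates)) replicates <- list(replicates)
  if (length(replicates) < 1) abort("need at least one replicate")
  purrr::walk(replicates, assert_methylome)
  all <- dplyr::bind_rows(replicates)
  key <- paste(all$chrom, all$pos, all$strand, sep = "\r")
  f <- factor(key, levels = unique(key))
  ctx_rank <- match(all$context, CONTEXTS)
  sums <- rowsum(cbind(meth = all$count_methylated,
                       total = all$count_total,
                       n = 1,
                       ctx = ctx_rank,
                       ctx2 = ctx_rank^2), f, reorder = FALSE)
  # per-site context variance must be zero (all replicates agree)
  bad <- which(sums[, "ctx2"] * sums[, "n"] - sums[, "ctx"]^2 > 0)
  if (length(bad) > 0) {
    off <- all[match(levels(f)[bad[1]], key), ]
    abort(paste0("context disagreement between replicates at ",
                 off$chrom, ":", off$pos, off$strand))
  }
  first <- all[!duplicated(key), ]
  merged <- tibble::tibble(
    chrom = first$chrom, pos = first$pos, strand = first$strand,
    context = first$context,
    count_methylated = as.integer(sums[, "meth"]),
    count_total = as.integer(sums[, "total"])
  )
  dplyr::arrange(merged, .data$chrom, .data$pos, .data$strand)
}

#' Filter cytosines by informative read coverage
#'
#' Retains cytosines with `count_total >= min_reads`. The default of 5 reads
#' applies the usual informative-coverage floor for whole-genome bisulfite
#' data; every analysis stage downstream of ingestion sees only filtered
#' sites.
#'
#' @param methylome A methylome tibble.
#' @param min_reads Minimum total reads (inclusive).
#' @return Filtered methylome tibble.
#' @export
coverage_filter <- function(methylome, min_reads = 5) {
  assert_methylome(methylome)
  stopifnot(min_reads >= 0)
  dplyr::filter(methylome, .data$count_total >= min_reads)
}

#' Pairwise replicate correlation on windowed fractional methylation
#'
#' Pools counts in fixed windows per replicate (all contexts together) and
#' computes Pearson correlation between every pair over windows covered in
#' both members of the pair.
#'
#' @param replicates List of >= 2 methylome tibbles.
#' @param window Window width in bp.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(replicates, window = 50) {
  if (length(replicates) < 2) abort("need at least two replicates")
  wins <- purrr::imap(replicates, function(rep, i) {
    assert_methylome(rep)
    rep %>%
      dplyr::mutate(win = (.data$pos - 1L) %/% as.integer(window)) %>%
      dplyr::group_by(.data$chrom, .data$win) %>%
      dplyr::summarise(meth = sum(.data$count_methylated),
                       total = sum(.data$count_total), .groups = "drop") %>%
      dplyr::filter(.data$total > 0) %>%
      dplyr::mutate(frac = .data$meth / .data$total)
  })
  n <- length(replicates)
  m <- diag(1, n)
  nm <- names(replicates)
  if (is.null(nm)) nm <- paste0("rep", seq_len(n))
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ij <- dplyr::inner_join(wins[[i]], wins[[j]],
                              by = c("chrom", "win"), suffix = c("_a", "_b"))
      m[i, j] <- m[j, i] <- stats::cor(ij$frac_a, ij$frac_b)
    }
  }
  m
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write feature annotation as BED6
#'
#' Intervals are written 0-based half-open as BED requires.
#'
#' @param features Feature tibble with `chrom`, `start`, `end`, `id`,
#'   `strand`.
#' @param path Output path.
#' @param score Optional numeric score column values.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(features, path, score = 0) {
  assert_intervals(features)
  out <- tibble::tibble(
    chrom = features$chrom, start = features$start, end = features$end,
    name = if ("id" %in% names(features)) features$id else ".",
    score = score,
    strand = if ("strand" %in% names(features)) features$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file; extra columns beyond the first six are ignored.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `id`,
#'   `score`, `strand` (0-based half-open).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "id"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  tibble::as_tibble(df[, seq_len(min(ncol(df), 6))])
}

#' Write feature annotation as GFF3
#'
#' @param features Feature tibble (`id`, `chrom`, `start`, `end`, `strand`,
#'   `kind`, optionally `superfamily`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  assert_intervals(features)
  attrs <- paste0("ID=", features$id,
                  ifelse(!is.na(features$superfamily %||% NA),
                         paste0(";superfamily=", features$superfamily), ""))
  lines <- paste(features$chrom, "germmeth",
                 ifelse(features$kind == "gene", "gene", "transposable_element"),
                 features$start + 1L, features$end, ".", features$strand, ".",
                 attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
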