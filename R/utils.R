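#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

CONTEXTS <- c("CG", "CHG", "CHH")

# Coordinate conventions: per-cytosine tables carry 1-based positions (`pos`),
# matching CX reports; all interval tables (windows, loci, features, BED) are
# 0-based half-open (`start`, `end`).

#' Derive a reproducible child seed from a master seed and a text tag
#'
#' Each simulated output stream (one per sample file) is seeded from the master
#' seed and a stable tag, so adding samples to a design never perturbs the
#' draws of existing ones.
#'
#' @param seed Master integer seed.
#' @param tag Character tag naming the stream (e.g. `"meiocyte_rep1"`).
#' @return An integer seed below 2^31.
#' @export
stream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  # small deterministic string hash (polynomial rolling, modular arithmetic)
  h <- 0
  for (k in utf8ToInt(paste0(tag, collapse = ""))) {
    h <- (h * 131 + k) %% 2147483629
  }
  as.integer((abs(seed) %% 2147483629 * 31 + h) %% 2147483629 + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
as_granges0 <- function(df) {
  # 0-based half-open tibble -> GRanges (1-based closed)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

assert_methylome <- function(x, arg = deparse(substitute(x))) {
  need <- c("chrom", "pos", "strand", "context", "count_methylated", "count_total")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("`", arg, "` is missing methylome columns: ",
                 paste(miss, collapse = ", ")))
  }
  invisible(x)
}

assert_intervals <- function(x, arg = deparse(substitute(x))) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("`", arg, "` is missing interval columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (any(x$end < x$start)) abort(paste0("`", arg, "` has end < start"))
  invisible(x)
}

fraction_or_na <- function(meth, total) {
  ifelse(total > 0, meth / total, NA_real_)
}
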