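#' Simulate a genome with packed annotation and planted loci
#'
#' Draws a random sequence per chromosome, packs non-overlapping gene, TE and
#' planted-locus intervals into it (uniform random gaps via stick breaking),
#' and records the planted ground truth. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named character vector of sequences),
#'   `annotation` (tibble of [FeatureRecord]-style rows: `id`, `chrom`,
#'   `start`, `end`, `strand`, `kind`, `superfamily`, `length`; 0-based
#'   half-open) and `truth` (a `ground_truth` list with `planted_loci`,
#'   the genome and the annotation).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  with_seed(stream_seed(config$seed, "genome"), {
    chroms <- sprintf("chr%d", seq_len(config$n_chrom))

    gene_len <- round(stats::runif(config$n_genes, 1000, 3000))
    n_short <- stats::rbinom(1, config$n_tes, config$te_short_frac)
    te_len <- round(c(stats::runif(n_short, 300, 1999),
                      stats::runif(config$n_tes - n_short, 2000, 6000)))
    te_len <- sample(te_len)
    n_pl <- config$n_planted_slm + config$n_planted_slh + config$n_planted_dmr
    pl_len <- round(stats::runif(n_pl, 150, 300))

    feats <- tibble::tibble(
      kind = c(rep("gene", config$n_genes), rep("TE", config$n_tes),
               rep("planted", n_pl)),
      sub = c(rep(NA_character_, config$n_genes),
              sample(names(config$te_superfamily_probs), config$n_tes,
                     replace = TRUE, prob = config$te_superfamily_probs),
              rep(c("SLM", "SLH", "DMR"),
                  c(config$n_planted_slm, config$n_planted_slh,
                    config$n_planted_dmr))),
      len = c(gene_len, te_len, pl_len)
    )
    feats <- feats[sample(nrow(feats)), ]
    feats$chrom <- sample(chroms, nrow(feats), replace = TRUE)

    placed <- purrr::map_dfr(chroms, function(ch) {
      f <- feats[feats$chrom == ch, ]
      k <- nrow(f)
      if (k == 0) return(f[0, ])
      min_gap <- 20L
      free <- config$chrom_length - sum(f$len) - (k + 1L) * min_gap
      if (free < 0) {
        abort(paste0(
          "infeasible packing on ", ch, ": total feature length ", sum(f$len),
          " plus minimal gaps exceeds chrom_length ", config$chrom_length))
      }
      cuts <- sort(stats::runif(k))
      gaps <- floor(diff(c(0, cuts, 1)) * free) + min_gap
      starts <- cumsum(gaps[seq_len(k)] + c(0L, f$len[-k]))
      f$start <- as.integer(starts)
      f$end <- as.integer(starts + f$len)
      f
    })

    annotation <- placed %>%
      dplyr::filter(.data$kind != "planted") %>%
      dplyr::arrange(.data$chrom, .data$start) %>%
      dplyr::mutate(
        strand = sample(c("+", "-"), dplyr::n(), replace = TRUE),
        id = sprintf("%s%04d", ifelse(.data$kind == "gene", "gene", "te"),
                     seq_len(dplyr::n()))
      ) %>%
      dplyr::select(id = "id", chrom = "chrom", start = "start", end = "end",
                    strand = "strand", kind = "kind", superfamily = "sub",
                    length = "len")

    planted <- placed %>%
      dplyr::filter(.data$kind == "planted") %>%
      dplyr::arrange(.data$chrom, .data$start) %>%
      dplyr::mutate(id = sprintf("locus%03d", seq_len(dplyr::n()))) %>%
      dplyr::select(id = "id", chrom = "chrom", start = "start", end = "end",
                    class = "sub", length = "len")

    genome <- vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
            collapse = "")
    }, character(1))
    names(genome) <- chroms

    truth <- structure(list(
      planted_loci = planted,
      te_activity = NULL,
      genome = genome,
      annotation = annotation,
      config = config
    ), class = "ground_truth")
    list(genome = genome, annotation = annotation, truth = truth)
  })
}

#' Scan a sequence for cytosines and assign strand-specific contexts
#'
#' Contexts are read from the reference: a cytosine followed by G is CG; by
#' H,G is CHG; by H,H is CHH (H = A, C or T). Minus-strand cytosines are G on
#' the reference and read their context from the reverse complement. Cytosines
#' within two bases of a chromosome end get context `"unknown"` and are
#' excluded from simulated methylomes.
#'
#' @param seq A single sequence string.
#' @param chrom Chromosome name to stamp on the output.
#' @return Tibble with `chrom`, `pos` (1-based), `strand`, `context`,
#'   `trinucleotide`.
#' @export
scan_cytosines <- function(seq, chrom = "chr1") {
  b <- strsplit(toupper(seq), "")[[1]]
  L <- length(b)
  ip <- which(b == "C")
  im <- which(b == "G")

  # two downstream bases are required for any call; end cytosines -> unknown
  classify <- function(n1, n2, has2) {
    ctx <- rep("unknown", length(n1))
    ctx[has2 & n1 == "G"] <- "CG"
    ctx[has2 & n1 != "G" & n2 == "G"] <- "CHG"
    ctx[has2 & n1 != "G" & n2 != "G"] <- "CHH"
    ctx
  }
  ctx_plus <- function(i) {
    classify(b[pmin(i + 1, L)], b[pmin(i + 2, L)], i <= L - 2)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ctx_minus <- function(i) {
    classify(comp[b[pmax(i - 1, 1)]], comp[b[pmax(i - 2, 1)]], i >= 3)
  }
  tri <- function(i, strand) {
    if (strand == "+") {
      ifelse(i <= L - 2, paste0(b[i], b[pmin(i + 1, L)], b[pmin(i + 2, L)]), "NNN")
    } else {
      ifelse(i >= 3,
             paste0(comp[b[i]], comp[b[pmax(i - 1, 1)]], comp[b[pmax(i - 2, 1)]]),
             "NNN")
    }
  }
  out <- dplyr::bind_rows(
    tibble::tibble(chrom = chrom, pos = ip, strand = "+",
                   context = if (length(ip)) ctx_plus(ip) else character(),
                   trinucleotide = if (length(ip)) tri(ip, "+") else character()),
    tibble::tibble(chrom = chrom, pos = im, strand = "-",
                   context = if (length(im)) ctx_minus(im) else character(),
                   trinucleotide = if (length(im)) tri(im, "-") else character())
  )
  dplyr::arrange(out, .data$pos, .data$strand)
}

# membership of 1-based positions in a 0-based half-open interval set
# (intervals assumed sorted and non-overlapping after reduce)
pos_in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0) return(rep(FALSE, length(pos)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  p0 <- pos - 1L
  i <- findInterval(p0, starts)
  i > 0 & p0 < ends[pmax(i, 1)]
}

merge_interval_set <- function(starts, ends) {
  if (length(starts) == 0) return(list(starts = integer(), ends = integer()))
  o <- order(starts)
  s <- starts[o]; e <- ends[o]
  ms <- s[1]; me <- e[1]; out_s <- integer(); out_e <- integer()
  for (k in seq_along(s)[-1]) {
    if (s[k] <= me) me <- max(me, e[k]) else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[k]; me <- e[k]
    }
  }
  list(starts = c(out_s, ms), ends = c(out_e, me))
}

#' Simulate multi-cell-type per-cytosine methylomes
#'
#' Every context-resolved cytosine in the genome receives a Poisson (or
#' negative-binomial) read depth and a binomial methylated count at the
#' compartment- and context-specific mean, plus planted effects: sex-cell
#' groups gain `slm_effect` inside planted SLM and SLH loci; SLH loci carry an
#' elevated somatic CHG/CHH baseline in every group; planted DMR loci sit at
#' `dmr_chh_wt` CHH (or `dmr_chh_mut` when `rdd_loss = TRUE`). Rates are
#' clipped to `[0, 1]`. One RNG stream per (group, replicate) table.
#'
#' @param genome,annotation,truth As returned by [simulate_genome()].
#' @param config The [sim_config()].
#' @param groups Sample groups to simulate (default `config$cell_types`).
#' @param n_replicates Replicates per group (default from config).
#' @param rdd_loss Simulate an RdDM-loss (rdr2-like) methylome: planted DMR
#'   loci drop to `dmr_chh_mut`.
#' @return Named list: group -> list of replicate methylome tibbles
#'   (`chrom`, `pos`, `strand`, `context`, `count_methylated`, `count_total`).
#' @export
simulate_methylome <- function(genome, annotation, truth, config,
                               groups = config$cell_types,
                               n_replicates = config$n_replicates,
                               rdd_loss = FALSE) {
  validate_sim_config(config)
  cm <- config$compartment_meth

  sites <- purrr::map_dfr(names(genome), function(ch) {
    s <- scan_cytosines(genome[[ch]], ch)
    s <- s[s$context != "unknown", ]

    ann <- truth$annotation[truth$annotation$chrom == ch, ]
    te <- ann[ann$kind == "TE", ]
    gene <- ann[ann$kind == "gene", ]
    fl <- merge_interval_set(pmax(te$start - 200L, 0L), te$end + 200L)

    comp <- rep("intergenic", nrow(s))
    comp[pos_in_intervals(s$pos, fl$starts, fl$ends)] <- "te_flank"
    comp[pos_in_intervals(s$pos, gene$start, gene$end)] <- "gene_body"
    comp[pos_in_intervals(s$pos, te$start, te$end)] <- "te_body"
    s$compartment <- comp

    pl <- truth$planted_loci[truth$planted_loci$chrom == ch, ]
    s$in_slm <- pos_in_intervals(s$pos, pl$start[pl$class == "SLM"],
                                 pl$end[pl$class == "SLM"])
    s$in_slh <- pos_in_intervals(s$pos, pl$start[pl$class == "SLH"],
                                 pl$end[pl$class == "SLH"])
    s$in_dmr <- pos_in_intervals(s$pos, pl$start[pl$class == "DMR"],
                                 pl$end[pl$class == "DMR"])
    s
  })

  cmat <- as.matrix(cm[CONTEXTS])
  rownames(cmat) <- cm$compartment
  base_p <- cmat[cbind(sites$compartment, sites$context)]
  # SLH loci: elevated somatic RdDM-like background in every group
  slh_bg <- config$slh_somatic_background
  p_bg <- base_p
  p_bg[sites$in_slh & sites$context == "CHG"] <- slh_bg[["CHG"]]
  p_bg[sites$in_slh & sites$context == "CHH"] <- slh_bg[["CHH"]]
  # DMR loci: constitutive CHH level, lost in the mutant
  dmr_level <- if (rdd_loss) config$dmr_chh_mut else config$dmr_chh_wt
  p_bg[sites$in_dmr & sites$context == "CHH"] <- dmr_level

  eff <- config$slm_effect[sites$context]
  p_sex <- pmin(pmax(p_bg + ifelse(sites$in_slm | sites$in_slh, eff, 0), 0), 1)
  p_som <- pmin(pmax(p_bg, 0), 1)

  draw <- function(group, rep_i) {
    tag <- paste(group, rep_i, if (rdd_loss) "rdd_loss" else "wt", sep = "_")
    with_seed(stream_seed(config$seed, paste0("methylome_", tag)), {
      n <- nrow(sites)
      total <- if (config$depth_dispersion > 0) {
        stats::rnbinom(n, size = config$depth_dispersion, mu = config$depth_mean)
      } else {
        stats::rpois(n, config$depth_mean)
      }
      p <- if (group == config$somatic) p_som else p_sex
      tibble::tibble(
        chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
        context = sites$context,
        count_methylated = stats::rbinom(n, total, p),
        count_total = as.integer(total)
      )
    })
  }
  out <- purrr::map(groups, function(g) {
    purrr::map(seq_len(n_replicates), function(r) draw(g, r))
  })
  names(out) <- groups
  out
}

#' Simulate a TE/gene expression count matrix with planted clusters
#'
#' Active TEs (chosen with a bias towards short elements) are split into the
#' clusters of `expr_cluster_spec`, each drawing negative-binomial counts that
#' peak in one cell type; inactive TEs draw zero counts so their TPM is below
#' any activity floor in every sample; genes draw a flat baseline. Updates
#' `truth$te_activity`.
#'
#' @param truth Ground truth from [simulate_genome()].
#' @param config The [sim_config()].
#' @return List with `counts` (tibble: `feature_id`, `length`, one column per
#'   sample `<group>_<rep>`), and `truth` with `te_activity` filled in
#'   (`te_id`, `active`, `cluster`).
#' @export
simulate_expression <- function(truth, config) {
  validate_sim_config(config)
  ann <- truth$annotation
  tes <- ann[ann$kind == "TE", ]
  genes <- ann[ann$kind == "gene", ]
  spec <- config$expr_cluster_spec
  n_active <- sum(spec$n)
  if (n_active > nrow(tes)) abort("cluster member counts exceed available TEs")

  with_seed(stream_seed(config$seed, "expression"), {
    w <- ifelse(tes$length < 2000, config$active_short_bias,
                1 - config$active_short_bias)
    active_ids <- sample(tes$id, n_active, prob = w)
    cluster <- rep(spec$cluster, spec$n)

    samples <- as.vector(t(outer(config$cell_types,
                                 seq_len(config$n_expr_replicates),
                                 function(g, r) paste0(g, "_", r))))
    sample_group <- rep(config$cell_types, each = config$n_expr_replicates)

    mu_te <- matrix(0, nrow(tes), length(samples),
                    dimnames = list(tes$id, samples))
    for (k in seq_len(nrow(spec))) {
      ids <- active_ids[cluster == spec$cluster[k]]
      mu <- ifelse(sample_group == spec$peak[k], spec$peak_mean[k],
                   spec$base_mean[k])
      mu_te[ids, ] <- matrix(mu, length(ids), length(samples), byrow = TRUE)
    }
    mu_gene <- matrix(config$gene_expr_mean, nrow(genes), length(samples),
                      dimnames = list(genes$id, samples))
    mu <- rbind(mu_te, mu_gene)

    cnt <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
    pos <- mu > 0
    cnt[pos] <- stats::rnbinom(sum(pos), size = config$expr_dispersion,
                               mu = mu[pos])

    counts <- tibble::as_tibble(cnt, rownames = "feature_id") %>%
      dplyr::left_join(dplyr::select(ann, feature_id = "id", length = "length"),
                       by = "feature_id") %>%
      dplyr::relocate("length", .after = "feature_id")

    truth$te_activity <- tibble::tibble(
      te_id = tes$id,
      active = tes$id %in% active_ids,
      cluster = cluster[match(tes$id, active_ids)]
    )
    list(counts = counts, truth = truth)
  })
}

#' Simulate a differential-expression table for sex-cell contrasts
#'
#' Computes per-contrast log2 fold changes and Welch-test p-values on
#' log2(TPM + 1) from a simulated count matrix, giving the integration stage a
#' realistic externally-produced DEG table.
#'
#' @param counts Count tibble from [simulate_expression()].
#' @param config The [sim_config()].
#' @return Tibble with `gene`, `contrast`, `log2fc`, `pvalue`.
#' @export
simulate_deg <- function(counts, config) {
  mat <- as.matrix(counts[, -(1:2)])
  rownames(mat) <- counts$feature_id
  rate <- mat / counts$length
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  lt <- log2(tpm + 1)
  grp <- sub("_[0-9]+$", "", colnames(lt))
  sex <- setdiff(config$cell_types, config$somatic)
  som <- lt[, grp == config$somatic, drop = FALSE]
  purrr::map_dfr(sex, function(g) {
    x <- lt[, grp == g, drop = FALSE]
    lfc <- rowMeans(x) - rowMeans(som)
    p <- vapply(seq_len(nrow(x)), function(i) {
      if (stats::sd(c(x[i, ], som[i, ])) == 0) return(1)
      tryCatch(stats::t.test(x[i, ], som[i, ])$p.value, error = function(e) 1)
    }, numeric(1))
    tibble::tibble(gene = rownames(lt),
                   contrast = paste0(g, "_vs_", config$somatic),
                   log2fc = lfc, pvalue = p)
  })
}
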