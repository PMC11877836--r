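#' Default configuration for the end-to-end synthetic demo
#'
#' A compact study: one 250-kb chromosome, 30 genes, 40 TEs, 12 planted
#' sex-cell hypermethylated loci, 6 planted somatic-RdDM loci and 10 planted
#' RdDM-loss DMR loci, two bisulfite replicates of leaf, meiocyte,
#' microspore and pollen, and a four-cluster TE expression experiment.
#'
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
demo_config <- function(seed = 1L) {
  sim_config(seed = seed, chrom_length = 250000L, n_genes = 30L, n_tes = 40L,
             n_planted_slm = 12L, n_planted_slh = 6L, n_planted_dmr = 10L,
             expr_cluster_spec = dplyr::mutate(default_expr_clusters(),
                                               n = c(12L, 6L, 6L, 6L)))
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline end to end on synthetic data
#'
#' simulate -> ingest (CX round trip, replicate merge, coverage filter) ->
#' locus calling -> DMR calling -> metaprofiles -> TE expression -> locus
#' annotation -> DEG integration, writing every artifact under `outdir` and
#' a manifest JSON with md5 checksums, seeds and recovery metrics. Identical
#' seeds produce identical manifests.
#'
#' @param outdir Writable output directory (created if absent).
#' @param seed Master seed.
#' @param config Optional [sim_config()]; defaults to [demo_config()] with
#'   `seed`.
#' @param min_reads Coverage filter applied at ingestion.
#' @return The manifest, invisibly; also written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
run_demo <- function(outdir, seed = 1L, config = NULL, min_reads = 5) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  probe <- file.path(outdir, ".write_probe")
  if (!ok || inherits(try(writeLines("", probe), silent = TRUE), "try-error")) {
    abort(paste0("output directory is not writable: ", outdir))
  }
  unlink(probe)
  if (is.null(config)) config <- demo_config(seed)

  paths <- character()
  add <- function(p) {
    paths[[length(paths) + 1]] <<- p
    p
  }

  stage_msg("simulate", "genome, annotation and planted truth")
  gen <- simulate_genome(config)
  write_genome_fasta(gen$genome, add(file.path(outdir, "genome.fa")))
  write_gff3(gen$annotation, add(file.path(outdir, "features.gff3")))
  write_bed6(gen$annotation, add(file.path(outdir, "features.bed")))
  jsonlite::write_json(
    list(planted_loci = gen$truth$planted_loci, seed = config$seed),
    add(file.path(outdir, "truth.json")), auto_unbox = TRUE, digits = NA)

  stage_msg("simulate", "per-cytosine methylomes for ",
            paste(config$cell_types, collapse = ", "))
  meths <- simulate_methylome(gen$genome, gen$annotation, gen$truth, config)

  stage_msg("ingest", "CX round trip, replicate merge, coverage filter >= ",
            min_reads)
  merged <- purrr::imap(meths, function(reps, grp) {
    tabs <- purrr::imap(reps, function(tab, i) {
      p <- add(file.path(outdir, sprintf("%s_rep%d.cx.tsv", grp, i)))
      write_cx_report(tab, p)
      read_cx_report(p, dialect = "cx")
    })
    coverage_filter(merge_replicates(tabs), min_reads = min_reads)
  })

  stage_msg("call-slm", "window screen, merge, Fisher, consistency, classify")
  sex <- setdiff(config$cell_types, config$somatic)
  slm <- call_slm(merged, sex_groups = sex, somatic_group = config$somatic)
  write_slm_result(slm, bed_path = add(file.path(outdir, "slm_loci.bed")),
                   tsv_path = add(file.path(outdir, "slm_loci.tsv")))
  planted_sex <- gen$truth$planted_loci %>%
    dplyr::filter(.data$class %in% c("SLM", "SLH"))
  slm_rec <- interval_recovery(slm$loci, planted_sex)

  stage_msg("call-dmr", "RdDM-loss CHH DMRs, wild type vs mutant")
  wt <- coverage_filter(merge_replicates(
    simulate_methylome(gen$genome, gen$annotation, gen$truth, config,
                       groups = config$somatic)[[1]]), min_reads)
  mut <- coverage_filter(merge_replicates(
    simulate_methylome(gen$genome, gen$annotation, gen$truth, config,
                       groups = config$somatic, rdd_loss = TRUE)[[1]]),
    min_reads)
  dmr <- call_dmrs(wt, mut)
  readr::write_tsv(dmr$dmrs, add(file.path(outdir, "dmrs.tsv")),
                   progress = FALSE)
  planted_dmr <- gen$truth$planted_loci %>%
    dplyr::filter(.data$class == "DMR")
  dmr_rec <- interval_recovery(dmr$dmrs, planted_dmr)

  stage_msg("metaplot", "5' end-anchored TE metaprofile (somatic)")
  tes <- gen$annotation %>% dplyr::filter(.data$kind == "TE")
  prof <- ends_metaprofile(merged[[config$somatic]], tes, anchor = "5prime",
                           bin = 100, span = 1000)
  readr::write_tsv(prof, add(file.path(outdir, "te_metaprofile.tsv")),
                   progress = FALSE)

  stage_msg("te-expr", "TPM, activity, k-means clusters")
  ex <- simulate_expression(gen$truth, config)
  readr::write_tsv(ex$counts, add(file.path(outdir, "te_counts.tsv")),
                   progress = FALSE)
  expr <- compute_tpm(ex$counts)
  act <- classify_activity(expr, features = gen$annotation)
  clus <- cluster_active(expr, act$te_id[act$status == "active"],
                         k = nrow(config$expr_cluster_spec),
                         seed = stream_seed(config$seed, "kmeans"))
  readr::write_tsv(cluster_summary(clus, act),
                   add(file.path(outdir, "te_clusters.tsv")), progress = FALSE)
  tru <- ex$truth$te_activity %>% dplyr::filter(.data$active)
  joined <- dplyr::inner_join(clus$labels, tru, by = "te_id",
                              suffix = c("_called", "_truth"))
  ari <- adjusted_rand_index(joined$cluster_called, joined$cluster_truth)

  stage_msg("annotate", "locus proximity to genes and TEs")
  prox <- proximity_classify(slm$loci, gen$annotation)
  jsonlite::write_json(proximity_summary(prox),
                       add(file.path(outdir, "proximity.json")),
                       auto_unbox = TRUE, digits = NA)

  stage_msg("integrate", "targeted genes x differential expression")
  tg <- target_genes(slm$loci, gen$annotation)
  deg <- deg_classify(simulate_deg(ex$counts, config))
  ov <- slm_deg_overlap(deg, tg$genes)
  down_sets <- purrr::map(sex, function(g) {
    ct <- paste0(g, "_vs_", config$somatic)
    deg$gene[deg$contrast == ct & deg$direction == "down" &
               deg$gene %in% tg$genes]
  })
  names(down_sets) <- sex
  venn <- venn_counts(down_sets)
  jsonlite::write_json(list(per_contrast = ov$per_contrast, union = ov$union,
                            venn_down = venn),
                       add(file.path(outdir, "integration.json")),
                       auto_unbox = TRUE, digits = NA)

  stage_msg("manifest", "checksums and recovery metrics")
  files <- unlist(paths)
  manifest <- list(
    seed = config$seed,
    artifacts = tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files))),
    metrics = list(
      slm = c(as.list(glance(slm)),
              list(precision = slm_rec$precision, recall = slm_rec$recall)),
      dmr = c(as.list(glance(dmr)),
              list(precision = dmr_rec$precision, recall = dmr_rec$recall)),
      te = list(n_active = sum(act$status == "active"),
                cluster_ari = ari),
      integration = as.list(ov$union)
    )
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  stage_msg("done", "manifest at ", manifest_path)
  invisible(manifest)
}
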