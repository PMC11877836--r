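#' Default compartment methylation levels
#'
#' Mean fractional methylation per genomic compartment and sequence context
#' used by the simulator. Values are typical of Brassicaceae methylomes:
#' heavily methylated TE bodies in CG/CHG, modest CHH everywhere, near-silent
#' intergenic CHH/CHG so that planted sex-cell hypermethylation stands out the
#' way real sexual-lineage loci do against somatic tissue.
#'
#' @return A tibble with columns `compartment`, `CG`, `CHG`, `CHH`.
#' @export
default_compartment_meth <- function() {
  tibble::tribble(
    ~compartment,   ~CG,  ~CHG, ~CHH,
    "te_body",     0.80,  0.60, 0.12,
    "te_flank",    0.40,  0.25, 0.10,
    "gene_body",   0.30,  0.05, 0.02,
    "intergenic",  0.15,  0.04, 0.02
  )
}

#' Default expression-cluster design for active transposons
#'
#' Four clusters of active LTR transposons, each peaking in one cell type
#' (meiocyte-dominant cluster largest, mirroring the strong meiotic burst seen
#' in real male-germline data). Counts are negative-binomial means per sample
#' group.
#'
#' @return A tibble with columns `cluster`, `peak`, `n`, `peak_mean`,
#'   `base_mean`.
#' @export
default_expr_clusters <- function() {
  tibble::tibble(
    cluster = 1:4,
    peak = c("meiocyte", "microspore", "leaf", "pollen"),
    n = c(80L, 40L, 40L, 40L),
    peak_mean = 500,
    base_mean = 10
  )
}

#' Build a validated simulation configuration
#'
#' Describes one synthetic study: a random genome with packed gene/TE
#' annotation, a multi-cell-type bisulfite design (somatic leaf plus three male
#' sex cell types, two replicates each), planted hypermethylated loci of three
#' classes, and a TE expression experiment with planted cluster structure.
#'
#' Planted locus classes:
#' \describe{
#'   \item{SLM}{hypermethylated in sex cells only; somatic background stays at
#'     the quiet intergenic level, so somatic CHH < 0.05 and CHG < 0.1.}
#'   \item{SLH}{hypermethylated in sex cells on top of an elevated somatic
#'     CHH/CHG background (an RdDM target already active in leaf), so the
#'     somatic RdDM-activity screen rejects the SLM label.}
#'   \item{DMR}{constitutive CHH methylation at `dmr_chh_wt` that collapses to
#'     `dmr_chh_mut` when a methylome is simulated with `rdd_loss = TRUE`
#'     (an rdr2-like mutant).}
#' }
#'
#' @param seed Master integer seed; every output stream derives its own seed
#'   from it via [stream_seed()].
#' @param n_chrom,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes,n_tes Number of gene and TE features to pack.
#' @param te_superfamily_probs Named probabilities for TE superfamily labels;
#'   must sum to 1.
#' @param te_short_frac Fraction of TEs drawn short (< 2 kb).
#' @param compartment_meth Tibble as [default_compartment_meth()].
#' @param depth_mean Mean sequencing depth per cytosine (Poisson).
#' @param depth_dispersion Negative-binomial size for depth; 0 keeps Poisson.
#' @param n_planted_slm,n_planted_slh,n_planted_dmr Planted locus counts.
#' @param slm_effect Named per-context additive methylation effect applied to
#'   sex cells inside planted SLM/SLH loci.
#' @param slh_somatic_background Named CHG/CHH somatic baseline inside SLH
#'   loci (must exceed the SLM classification thresholds to matter).
#' @param dmr_chh_wt,dmr_chh_mut CHH level inside planted DMR loci in wild
#'   type and in the RdDM-loss mutant.
#' @param cell_types Ordered sample-group names; `somatic` must be among them.
#' @param somatic Name of the somatic group.
#' @param n_replicates Bisulfite replicates per group.
#' @param expr_cluster_spec Tibble as [default_expr_clusters()].
#' @param n_expr_replicates RNA replicates per group.
#' @param expr_dispersion Negative-binomial size for expression counts.
#' @param gene_expr_mean Baseline negative-binomial mean for gene counts.
#' @param active_short_bias Probability weight that an active TE is drawn from
#'   the short (< 2 kb) pool, emulating the short-active/long-inactive length
#'   structure of real LTR-TE data.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 1L,
                       chrom_length = 3e5,
                       n_genes = 40L,
                       n_tes = 60L,
                       te_superfamily_probs = c(Gypsy = 0.5, Copia = 0.3, other = 0.2),
                       te_short_frac = 0.7,
                       compartment_meth = default_compartment_meth(),
                       depth_mean = 20,
                       depth_dispersion = 0,
                       n_planted_slm = 30L,
                       n_planted_slh = 10L,
                       n_planted_dmr = 0L,
                       slm_effect = c(CG = 0.3, CHG = 0.3, CHH = 0.3),
                       slh_somatic_background = c(CHG = 0.20, CHH = 0.15),
                       dmr_chh_wt = 0.25,
                       dmr_chh_mut = 0.02,
                       cell_types = c("leaf", "meiocyte", "microspore", "pollen"),
                       somatic = "leaf",
                       n_replicates = 2L,
                       expr_cluster_spec = default_expr_clusters(),
                       n_expr_replicates = 3L,
                       expr_dispersion = 5,
                       gene_expr_mean = 200,
                       active_short_bias = 0.85) {
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes), n_tes = as.integer(n_tes),
    te_superfamily_probs = te_superfamily_probs,
    te_short_frac = te_short_frac,
    compartment_meth = compartment_meth,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    n_planted_slm = as.integer(n_planted_slm),
    n_planted_slh = as.integer(n_planted_slh),
    n_planted_dmr = as.integer(n_planted_dmr),
    slm_effect = slm_effect,
    slh_somatic_background = slh_somatic_background,
    dmr_chh_wt = dmr_chh_wt, dmr_chh_mut = dmr_chh_mut,
    cell_types = cell_types, somatic = somatic,
    n_replicates = as.integer(n_replicates),
    expr_cluster_spec = expr_cluster_spec,
    n_expr_replicates = as.integer(n_expr_replicates),
    expr_dispersion = expr_dispersion,
    gene_expr_mean = gene_expr_mean,
    active_short_bias = active_short_bias
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$te_superfamily_probs) - 1) > 1e-9) {
    abort("te_superfamily_probs must sum to 1 (within 1e-9)")
  }
  if (any(cfg$te_superfamily_probs < 0 | cfg$te_superfamily_probs > 1)) {
    abort("te_superfamily_probs must lie in [0, 1]")
  }
  cm <- cfg$compartment_meth
  lv <- unlist(cm[CONTEXTS])
  if (any(lv < 0 | lv > 1)) abort("compartment_meth levels must lie in [0, 1]")
  if (!setequal(cm$compartment, c("te_body", "te_flank", "gene_body", "intergenic"))) {
    abort("compartment_meth must cover te_body, te_flank, gene_body, intergenic")
  }
  if (cfg$depth_mean <= 0) abort("depth_mean must be > 0")
  if (!cfg$somatic %in% cfg$cell_types) abort("somatic group must be in cell_types")
  if (!all(CONTEXTS %in% names(cfg$slm_effect))) {
    abort("slm_effect must name CG, CHG and CHH")
  }
  spec <- cfg$expr_cluster_spec
  if (sum(spec$n) > cfg$n_tes) {
    abort("expr_cluster_spec member counts exceed n_tes")
  }
  if (!all(spec$peak[spec$n > 0] %in% cfg$cell_types)) {
    abort("expr_cluster_spec peaks must be cell_types")
  }
  invisible(cfg)
}
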