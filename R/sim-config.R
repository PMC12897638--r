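#' Simulation configuration for the twin-pair methylome generator
#'
#' Bundles every tunable of the synthetic whole-genome bisulfite twin-pair
#' study: the design (number of monozygotic pairs, one control-fed CON and
#' one nutrient-restricted RES fetus per pair), the sequencing model
#' (negative-binomial depth, beta-binomial counts), the treatment effect
#' model, and the gene/feature layout used for annotation.
#'
#' The defaults emulate a CpG-dense, well-covered methylome panel of the
#' kind that survives coverage filtering in a real WGBS study: four twin
#' pairs, 128,000 CpGs over two 800 kb chromosomes (a CpG-island-dense panel,
#' ~12 bp spacing), mean depth 15, a
#' moderately bimodal baseline methylation distribution, 5% of CpGs truly
#' affected in clustered runs of 40 consecutive CpGs (differentially
#' methylated regions spanning the smoothing window), a 0.2
#' methylation-scale effect multiplied by a per-pair severity gradient, and
#' a 95% bias toward hypermethylation in RES.
#'
#' @param n_pairs Number of monozygotic twin pairs (default 4).
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_cpgs Total number of simulated CpG sites across all chromosomes.
#' @param mean_depth Mean sequencing depth per CpG per sample (reads).
#' @param depth_dispersion Negative-binomial size parameter for depth.
#' @param baseline_alpha,baseline_beta Beta shape parameters of the per-site
#'   baseline methylation level.
#' @param phi Beta-binomial overdispersion (intra-class correlation) in (0,1).
#' @param dm_fraction Fraction of CpGs carrying a true treatment effect.
#' @param effect_size Methylation-scale shift in (0,1) applied to RES twins
#'   at affected sites (before per-pair severity scaling and clipping).
#' @param hyper_fraction Fraction of true effects with positive sign
#'   (hypermethylation in RES; default 0.95).
#' @param pair_severity Numeric vector, one multiplier in \[0,1\] per pair,
#'   scaling the treatment effect for that pair. Strictly increasing by
#'   default so phenotype severity and dmCpG burden co-vary across pairs.
#' @param pair_effect_sd SD of the pair-level logit-scale shift shared by
#'   both twins of a pair.
#' @param dm_cluster_size Run length (in consecutive CpGs) of a true
#'   differentially methylated cluster.
#' @param n_genes Genes per chromosome in the synthetic annotation.
#' @param exons_per_gene Integer range (length-2) of exons per transcript.
#' @param engineer_overlap Place one locus per chromosome where two genes
#'   overlap so a single CpG can be exon of one gene and intron of another.
#' @param promoter_up,promoter_down Promoter window around the TSS in bp
#'   (upstream, downstream on the transcript strand).
#' @param n_islands CpG islands per chromosome.
#' @param con_fetal_mass_kg,con_liver_g_per_kg Control phenotype means.
#' @param lsi_slope Expected Liver Sparing Index of a pair is
#'   `1 - lsi_slope * severity`: no severity means no relative liver loss
#'   (LSI 1), and increasing severity gives monotonically decreasing LSI
#'   (the default puts the most severe pair near 0.79).
#' @param phenotype_noise_sd SD of multiplicative phenotype noise.
#' @param seed Integer master seed; fully determines all outputs.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cpgs = 500, n_genes = 5, seed = 1)
#' @export
sim_config <- function(n_pairs = 4L,
                       n_chroms = 2L,
                       chrom_length = 8e5,
                       n_cpgs = 128000L,
                       mean_depth = 15,
                       depth_dispersion = 5,
                       baseline_alpha = 1.2,
                       baseline_beta = 0.8,
                       phi = 0.05,
                       dm_fraction = 0.05,
                       effect_size = 0.2,
                       hyper_fraction = 0.95,
                       pair_severity = c(0.85, 0.9, 0.95, 1.0),
                       pair_effect_sd = 0.2,
                       dm_cluster_size = 40,
                       n_genes = 30L,
                       exons_per_gene = c(2L, 6L),
                       engineer_overlap = TRUE,
                       promoter_up = 2000,
                       promoter_down = 200,
                       n_islands = 10L,
                       con_fetal_mass_kg = 5.0,
                       con_liver_g_per_kg = 30,
                       lsi_slope = 0.21,
                       phenotype_noise_sd = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs), n_chroms = as.integer(n_chroms),
    chrom_length = chrom_length, n_cpgs = as.integer(n_cpgs),
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    baseline_alpha = baseline_alpha, baseline_beta = baseline_beta,
    phi = phi, dm_fraction = dm_fraction, effect_size = effect_size,
    hyper_fraction = hyper_fraction, pair_severity = pair_severity,
    pair_effect_sd = pair_effect_sd, dm_cluster_size = dm_cluster_size,
    n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
    engineer_overlap = isTRUE(engineer_overlap),
    promoter_up = promoter_up, promoter_down = promoter_down,
    n_islands = as.integer(n_islands),
    con_fetal_mass_kg = con_fetal_mass_kg,
    con_liver_g_per_kg = con_liver_g_per_kg,
    lsi_slope = lsi_slope,
    phenotype_noise_sd = phenotype_noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_pairs < 1L) stop2("n_pairs must be >= 1")
    if (mean_depth <= 0) stop2("mean_depth must be > 0")
    if (phi <= 0 || phi >= 1) stop2("phi must lie strictly in (0, 1)")
    for (f in c("dm_fraction", "hyper_fraction"))
      if (cfg[[f]] < 0 || cfg[[f]] > 1) stop2(f, " must lie in [0, 1]")
    if (effect_size < 0 || effect_size >= 1)
      stop2("effect_size must lie in [0, 1)")
    if (length(pair_severity) != n_pairs)
      stop2("pair_severity must have length n_pairs (", n_pairs, "), got ",
            length(pair_severity))
    if (any(pair_severity < 0 | pair_severity > 1))
      stop2("pair_severity entries must lie in [0, 1]")
    if (n_cpgs < 1L) stop2("n_cpgs must be >= 1")
    if (length(exons_per_gene) != 2L || any(exons_per_gene < 1L))
      stop2("exons_per_gene must be a length-2 positive integer range")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_pairs, "twin pairs,", x$n_cpgs, "CpGs on",
      x$n_chroms, "chromosomes of", format(x$chrom_length, big.mark = ","),
      "bp\n  mean depth", x$mean_depth, "| phi", x$phi,
      "| dm_fraction", x$dm_fraction, "| effect", x$effect_size,
      "| hyper_fraction", x$hyper_fraction, "\n  pair severity:",
      paste(x$pair_severity, collapse = ", "), "| seed", x$seed, "\n")
  invisible(x)
}
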