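#' Assemble a pipeline configuration
#'
#' A single object driving [run_pipeline()] end to end. Either a
#' simulation block (`sim`) or input paths (`counts_paths`, `sheet_path`,
#' `features_path`, ...) must be supplied; flags mirror the module
#' defaults (`min_depth` 5, `min_samples` 2, `alpha` 0.05, `min_diff`
#' 0.10, `consensus_k` 3, `smooth_halfwidth` 250 bp, `top_n` 30, `fdr`
#' 0.05).
#'
#' @param out_dir Output directory for stage TSVs and the run manifest.
#' @param sim Optional [sim_config()]: run on synthetic data.
#' @param counts_paths Named vector of count-file paths (sample id names).
#' @param dialect Count-file dialect, see [read_counts()].
#' @param sheet_path,features_path,gene_map_path,gmt_path,phenotypes_path
#'   Input file paths for a run on real data (`features_path` may be GFF3
#'   `.gff3`/`.gff` or the BED dialect).
#' @param min_depth,min_samples Coverage pre-filter, see
#'   [coverage_filter()].
#' @param tier A [tier_config()].
#' @param smooth_halfwidth Pairwise smoothing half-window (bp).
#' @param top_n Rows per region in the top-site tables.
#' @param fdr Enrichment significance threshold.
#' @param enrich_top_n Terms kept per source for the plot-ready table.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = NULL,
                            counts_paths = NULL,
                            dialect = "bismark_cov",
                            sheet_path = NULL,
                            features_path = NULL,
                            gene_map_path = NULL,
                            gmt_path = NULL,
                            phenotypes_path = NULL,
                            min_depth = 5L, min_samples = 2L,
                            tier = tier_config(),
                            smooth_halfwidth = 250,
                            top_n = 30L, fdr = 0.05, enrich_top_n = 12L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(sim)) {
    for (p in c(counts_paths, sheet_path, features_path, gmt_path,
                phenotypes_path))
      if (!is.null(p) && !file.exists(p))
        stop2("configured input path does not exist: ", p)
    if (is.null(counts_paths) || is.null(sheet_path))
      stop2("either a simulation block or counts_paths + sheet_path ",
            "must be provided")
  }
  structure(list(out_dir = out_dir, sim = sim, counts_paths = counts_paths,
                 dialect = dialect, sheet_path = sheet_path,
                 features_path = features_path,
                 gene_map_path = gene_map_path, gmt_path = gmt_path,
                 phenotypes_path = phenotypes_path,
                 min_depth = min_depth, min_samples = min_samples,
                 tier = tier, smooth_halfwidth = smooth_halfwidth,
                 top_n = top_n, fdr = fdr, enrich_top_n = enrich_top_n,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim`
#' mapping is passed to [sim_config()] and a `tier` mapping to
#' [tier_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$tier)) y$tier <- do.call(tier_config, y$tier)
  do.call(pipeline_config, y)
}

#' Run the two-tier differential-methylation pipeline
#'
#' Orchestrates: ingest (or simulate) -> coverage filter -> dispersion ->
#' group Wald test -> group-level dmCpG tier; per-pair Wald tests ->
#' per-pair tier -> k-of-n consensus; annotation of both tiers ->
#' regional summaries and top-site tables -> over-representation
#' enrichment per region -> Liver Sparing Index and severity association.
#' Every stage writes a TSV under `out_dir` and is recorded in a JSON
#' manifest (stage, parameters, row counts, output MD5 hashes, wall
#' time). Reruns with an identical configuration reproduce identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list())
  say <- function(...) if (config$log_level == "info")
    message("[twinmeth] ", ...)

  tsv <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  stage <- function(name, params, paths, n_rows) {
    manifest$stages[[name]] <<- list(
      stage = name, params = params,
      outputs = lapply(paths, function(p)
        list(path = basename(p), md5 = unname(tools::md5sum(p)))),
      n_rows = n_rows,
      elapsed_s = round(as.numeric(Sys.time()) - t0, 3))
    t0 <<- as.numeric(Sys.time())
    say(name, " done (", paste(n_rows, collapse = "/"), " rows)")
  }
  t0 <- as.numeric(Sys.time())

  on.exit({
    manifest$complete <- FALSE
    write_manifest(manifest, config)
  })

  # -- stage 1: ingest or simulate ------------------------------------
  if (!is.null(config$sim)) {
    features <- gen_feature_annotation(config$sim)
    simdat <- gen_twin_methylome(config$sim, features)
    cm <- simdat$counts
    phen <- gen_phenotypes(config$sim)
    terms <- gen_gene_sets(features, seed = config$sim$seed)
    gene_map <- attr(features, "gene_map")
    p1 <- c(tsv(simdat$truth, "truth"),
            tsv(phen, "phenotypes"),
            write_features_gff3(features, file.path(config$out_dir,
                                                    "features.gff3")),
            write_gmt(terms, file.path(config$out_dir, "gene_sets.gmt")))
    stage("simulate", unclass(config$sim), p1, c(sites = nrow(cm$sites)))
  } else {
    sheet <- read_sample_sheet(config$sheet_path)
    cm <- read_counts(config$counts_paths, config$dialect, sheet)
    features <- if (is.null(config$features_path)) NULL
      else if (grepl("\\.gff3?$", config$features_path))
        read_features_gff3(config$features_path)
      else read_features_bed(config$features_path)
    gene_map <- if (!is.null(config$gene_map_path))
      read_gene_map(config$gene_map_path) else attr(features, "gene_map")
    phen <- if (!is.null(config$phenotypes_path))
      utils::read.table(config$phenotypes_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL
    terms <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
      else NULL
    stage("ingest", list(dialect = config$dialect), character(0),
          c(sites = nrow(cm$sites)))
  }

  # -- stage 2: coverage filter ---------------------------------------
  cm <- coverage_filter(cm, config$min_depth, config$min_samples)
  fl <- attr(cm, "filter_log")
  stage("coverage_filter",
        list(min_depth = config$min_depth, min_samples = config$min_samples),
        character(0), c(kept = fl$n_kept, dropped = fl$n_in - fl$n_kept))

  # -- stage 3: dispersion --------------------------------------------
  phi <- estimate_dispersion(cm, "genomewide")
  stage("dispersion", list(scope = "genomewide"), character(0),
        c(phi_x1000 = round(1000 * phi$phi)))

  # -- stage 4/5: group test and tier ---------------------------------
  grp <- wald_test_group(cm, phi)
  p4 <- tsv(grp, "group_test")
  stage("group_test", list(phi = phi$phi), p4, nrow(grp))

  grp_dm <- filter_group_level(grp, config$tier)
  p5 <- tsv(grp_dm, "group_dmcpgs")
  stage("group_tier", unclass(config$tier)[c("alpha", "min_diff")], p5,
        nrow(grp_dm))

  # -- stage 6: pairwise tests and tier -------------------------------
  pairs <- sort(unique(cm$sheet$pair))
  pair_res <- lapply(pairs, function(pr)
    wald_test_pair(cm, pr, phi, config$smooth_halfwidth))
  names(pair_res) <- as.character(pairs)
  pair_dm <- filter_pairwise(pair_res, config$tier)
  p6 <- tsv(do.call(rbind, pair_dm), "pairwise_dmcpgs")
  stage("pairwise_tier",
        list(smooth_halfwidth = config$smooth_halfwidth),
        p6, vapply(pair_dm, nrow, 1L))

  # -- stage 7: consensus ---------------------------------------------
  cons <- consensus(pair_dm, config$tier)
  p7 <- tsv(cons, "consensus_dmcpgs")
  stage("consensus", list(k = config$tier$consensus_k), p7, nrow(cons))

  # -- stage 8: annotation --------------------------------------------
  if (!is.null(features)) {
    idx <- build_interval_index(features)
    grp_ann <- annotate_sites(grp_dm, idx)
    cons_ann <- annotate_sites(cons, idx)
    p8 <- c(tsv(grp_ann, "group_annotated"),
            tsv(cons_ann, "consensus_annotated"))
    stage("annotate", list(), p8, c(nrow(grp_ann), nrow(cons_ann)))

    # -- stage 9: summaries, top sites --------------------------------
    grp_sum <- regional_summary(grp_ann, "group")
    cons_sum <- regional_summary(cons_ann, "consensus")
    tops <- rank_top_sites(cons_ann, config$top_n, "consensus")
    tops_grp <- rank_top_sites(grp_ann, config$top_n, "group")
    p9 <- c(tsv(grp_sum, "group_regional_summary"),
            tsv(cons_sum, "consensus_regional_summary"),
            unlist(lapply(names(tops), function(rg)
              tsv(tops[[rg]], paste0("top_sites_consensus_", rg)))),
            unlist(lapply(names(tops_grp), function(rg)
              tsv(tops_grp[[rg]], paste0("top_sites_group_", rg)))))
    stage("summarize", list(top_n = config$top_n), p9,
          c(group_total = grp_sum$site_count[1],
            consensus_total = cons_sum$site_count[1]))

    # -- stage 10: enrichment -----------------------------------------
    if (!is.null(terms)) {
      universe <- sort(unique(stats::na.omit(features$gene_symbol)))
      enr <- list()
      for (tier_name in c("group", "consensus")) {
        ann <- if (tier_name == "group") grp_ann else cons_ann
        for (rg in c("promoter", "exon", "intron")) {
          q <- map_to_genes(ann, rg)
          if (!length(q)) next
          rows <- enrich(q, terms, universe, config$fdr)
          rows$tier <- tier_name; rows$region <- rg
          enr[[paste(tier_name, rg)]] <- rows
        }
      }
      enr_all <- do.call(rbind, enr)
      top_terms <- if (!is.null(enr_all) && nrow(enr_all))
        do.call(rbind, lapply(split(enr_all,
                                    paste(enr_all$tier, enr_all$region,
                                          enr_all$source)),
                              select_top_terms, config$enrich_top_n))
        else enr_all
      p10 <- c(tsv(enr_all %||% data.frame(), "enrichment"),
               tsv(top_terms %||% data.frame(), "enrichment_top_terms"))
      stage("enrich", list(fdr = config$fdr), p10,
            c(terms_tested = if (is.null(enr_all)) 0L else nrow(enr_all),
              significant = if (is.null(enr_all)) 0L
                else sum(enr_all$significant)))
    } else if (!is.null(config$gmt_path) || !is.null(config$sim)) {
      stop2("enrichment stage enabled but no gene sets available")
    }
  }

  # -- stage 11: LSI and severity association -------------------------
  if (!is.null(phen)) {
    lsi <- compute_lsi(phen)
    names(pair_dm) <- as.character(pairs)
    sev <- severity_association(pair_dm, lsi)
    p11 <- c(tsv(lsi, "lsi"), tsv(sev$table, "severity_burden"))
    stage("lsi_severity", list(), p11,
          c(pairs = nrow(lsi),
            rho_burden_x100 = round(100 * (sev$rho_burden %||% NA))))
    manifest$severity <- sev[c("rho_burden", "rho_hyper_fraction", "note")]
  }

  on.exit()
  manifest$complete <- TRUE
  write_manifest(manifest, config)
  say("pipeline complete: ", length(manifest$stages), " stages")
  invisible(manifest)
}

write_manifest <- function(manifest, config) {
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
}
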