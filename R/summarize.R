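#' Two-decimal region proportions (half-up rounding)
#'
#' Proportion of the tier's total dmCpG count attributable to each region,
#' rounded half-up to two decimals as in the printed summary tables. With
#' a zero total all proportions are reported as 0.
#'
#' @param site_counts Numeric vector of per-region site counts.
#' @param total_count The tier's total dmCpG count.
#' @return Numeric vector of proportions, same length as `site_counts`.
#' @export
region_proportions <- function(site_counts, total_count) {
  if (total_count == 0) return(rep(0, length(site_counts)))
  round_half_up(site_counts / total_count, 2)
}

#' Regional summary of annotated dmCpGs
#'
#' One row per region (`total`, `promoter`, `exon`, `intron`, `genic`,
#' `intergenic`): site count, proportion of the tier total (half-up, two
#' decimals), count of unique associated genes (promoter/exon/intron
#' only), and direction tallies. Counts are non-additive across regions
#' because sites can carry multiple annotation categories. In the
#' consensus tier a `mixed` column appears; at group level every site is
#' hyper or hypo.
#'
#' @param annotated [annotate_sites()] output carrying a `direction`
#'   column.
#' @param tier `"group"` or `"consensus"`.
#' @return data.frame, one row per region.
#' @export
regional_summary <- function(annotated, tier = c("group", "consensus")) {
  tier <- match.arg(tier)
  regions <- c("total", "promoter", "exon", "intron", "genic", "intergenic")
  total_n <- nrow(annotated)
  rows <- lapply(regions, function(rg) {
    sel <- if (rg == "total") rep(TRUE, total_n) else annotated[[rg]]
    d <- annotated$direction[sel]
    genes <- if (rg %in% c("promoter", "exon", "intron"))
      length(map_to_genes(annotated[sel, , drop = FALSE], rg)) else NA_integer_
    out <- data.frame(region = rg, site_count = sum(sel),
                      proportion = region_proportions(sum(sel), total_n),
                      n_genes = genes,
                      hyper = sum(d == "hyper"), hypo = sum(d == "hypo"),
                      stringsAsFactors = FALSE)
    if (tier == "consensus") out$mixed <- sum(d == "mixed")
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank top dmCpG sites by absolute methylation difference
#'
#' Per region, rows are ordered by `|diff|` descending with ties broken by
#' adjusted p ascending, then (chrom, pos), and the first `n` are kept —
#' one row per site, so a gene with several strong sites appears several
#' times. The group tier ranks on `meth_diff`/`padj`; the consensus tier
#' on `mean_diff`/`min_padj`.
#'
#' @param annotated [annotate_sites()] output for one tier.
#' @param n Rows per region (default 30).
#' @param tier `"group"` or `"consensus"`.
#' @param regions Region labels to tabulate.
#' @return Named list of data.frames (`chrom`, `pos`, `diff`, `padj`,
#'   `genes`), one per region.
#' @export
rank_top_sites <- function(annotated, n = 30L, tier = c("group", "consensus"),
                           regions = c("promoter", "exon", "intron")) {
  tier <- match.arg(tier)
  dcol <- if (tier == "group") "meth_diff" else "mean_diff"
  pcol <- if (tier == "group") "padj" else "min_padj"
  out <- lapply(regions, function(rg) {
    d <- annotated[annotated[[rg]], , drop = FALSE]
    gcol <- paste0("genes_", rg)
    ord <- order(-abs(d[[dcol]]), d[[pcol]], d$chrom, d$pos)
    d <- d[ord, , drop = FALSE][seq_len(min(n, nrow(d))), , drop = FALSE]
    res <- data.frame(chrom = d$chrom, pos = d$pos, diff = d[[dcol]],
                      padj = d[[pcol]],
                      genes = if (gcol %in% names(d)) d[[gcol]] else "",
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
  })
  names(out) <- regions
  out
}

#' Liver Sparing Index per twin pair
#'
#' LSI = (RES liver g / RES fetal kg) / (CON liver g / CON fetal kg).
#' Values below 1 indicate relative liver loss in the nutrient-restricted
#' twin, values above 1 relative liver sparing; exactly 1 is reported as
#' neutral.
#'
#' @param phenotypes data.frame with `pair`, `group`, `fetal_mass_kg`,
#'   `liver_mass_g`.
#' @return data.frame: `pair`, `ratio_con`, `ratio_res`, `lsi`,
#'   `category`.
#' @export
compute_lsi <- function(phenotypes) {
  stopifnot(all(c("pair", "group", "fetal_mass_kg", "liver_mass_g") %in%
                  names(phenotypes)))
  if (any(phenotypes$fetal_mass_kg <= 0) || any(phenotypes$liver_mass_g <= 0))
    stop2("masses must be positive")
  out <- do.call(rbind, lapply(split(phenotypes, phenotypes$pair), function(d) {
    con <- d[d$group == "CON", ]; res <- d[d$group == "RES", ]
    if (nrow(con) != 1L || nrow(res) != 1L)
      stop2("pair '", d$pair[1], "' must have exactly one CON and one RES twin")
    rc <- con$liver_mass_g / con$fetal_mass_kg
    rr <- res$liver_mass_g / res$fetal_mass_kg
    data.frame(pair = d$pair[1], ratio_con = rc, ratio_res = rr,
               lsi = rr / rc, category = lsi_category(rr / rc),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname compute_lsi
#' @param lsi Numeric LSI value(s).
#' @export
lsi_category <- function(lsi) {
  if (any(lsi <= 0)) stop2("LSI must be positive")
  ifelse(lsi < 1, "loss", ifelse(lsi > 1, "sparing", "neutral"))
}

#' Association between phenotype severity and dmCpG burden
#'
#' Spearman rank correlation between each pair's Liver Sparing Index and
#' (a) its per-pair dmCpG burden and (b) its hyper fraction,
#' `hyper / (hyper + hypo)`. With as few pairs as a twin study offers the
#' correlation is descriptive — the output records `n_pairs` and carries
#' no p-value. Constant inputs make the correlation undefined; it is
#' reported as NA with a note.
#'
#' @param pair_sets [filter_pairwise()] output: per-pair dmCpG sets.
#' @param lsi [compute_lsi()] output.
#' @return List with `table` (per-pair burden, hyper fraction, LSI),
#'   `rho_burden`, `rho_hyper_fraction`, `n_pairs`, `note`.
#' @export
severity_association <- function(pair_sets, lsi) {
  tab <- do.call(rbind, lapply(names(pair_sets), function(nm) {
    d <- pair_sets[[nm]]
    hyper <- sum(d$direction == "hyper"); hypo <- sum(d$direction == "hypo")
    data.frame(pair = nm, n_dmcpg = nrow(d),
               hyper_fraction = if (hyper + hypo > 0)
                 hyper / (hyper + hypo) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tab <- merge(tab, lsi[, c("pair", "lsi")], by = "pair", sort = TRUE)
  if (nrow(tab) < 3)
    stop2("need >= 3 pairs with both burden and LSI")
  safe_cor <- function(x, y) {
    if (length(unique(x)) < 2 || length(unique(stats::na.omit(y))) < 2)
      return(NA_real_)
    stats::cor(x, y, method = "spearman", use = "complete.obs")
  }
  rb <- safe_cor(tab$lsi, tab$n_dmcpg)
  rh <- safe_cor(tab$lsi, tab$hyper_fraction)
  note <- if (anyNA(c(rb, rh)))
    "correlation undefined for constant input(s)" else
      sprintf("descriptive rank correlation over n = %d pairs", nrow(tab))
  list(table = tab, rho_burden = rb, rho_hyper_fraction = rh,
       n_pairs = nrow(tab), note = note)
}
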