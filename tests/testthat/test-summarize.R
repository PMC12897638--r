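fake_annotated <- function(n_prom = 2, n_exon = 3, n_intron = 4, n_inter = 1,
                           direction = NULL) {
  n <- n_prom + n_exon + n_intron + n_inter
  df <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
                   meth_diff = rep(0.2, n), padj = rep(0.01, n),
                   promoter = rep(c(TRUE, FALSE, FALSE, FALSE),
                                  c(n_prom, n_exon, n_intron, n_inter)),
                   exon = rep(c(FALSE, TRUE, FALSE, FALSE),
                              c(n_prom, n_exon, n_intron, n_inter)),
                   intron = rep(c(FALSE, FALSE, TRUE, FALSE),
                                c(n_prom, n_exon, n_intron, n_inter)),
                   cpg_island = FALSE, stringsAsFactors = FALSE)
  df$genic <- df$exon | df$intron
  df$intergenic <- rep(c(FALSE, FALSE, FALSE, TRUE),
                       c(n_prom, n_exon, n_intron, n_inter))
  df$genes_promoter <- ifelse(df$promoter, "P1", "")
  df$genes_exon <- ifelse(df$exon, c("", "E1", "E1", "E2")[seq_len(nrow(df)) %% 4 + 1], "")
  df$genes_exon[df$exon & df$genes_exon == ""] <- "E1"
  df$genes_intron <- ifelse(df$intron, "I1", "")
  df$genes_genic <- paste0(df$genes_exon,
                           ifelse(df$genes_exon != "" & df$genes_intron != "", ";", ""),
                           df$genes_intron)
  df$direction <- direction %||% rep("hyper", n)
  df
}

test_that("regional proportions use half-up rounding against printed counts", {
  # group tier printed counts: totals and per-region proportions
  counts <- c(promoter = 40533, exon = 126667, intron = 785381,
              genic = 830632, intergenic = 783214)
  prop <- region_proportions(counts, 1636305)
  expect_equal(unname(prop[c("exon", "intron", "genic", "intergenic")]),
               c(0.08, 0.48, 0.51, 0.48))
  # consensus tier
  counts2 <- c(promoter = 1314, exon = 7116, intron = 22239,
               genic = 24942, intergenic = 16657)
  expect_equal(unname(region_proportions(counts2, 42231)),
               c(0.03, 0.17, 0.53, 0.59, 0.39))
  # explicit half-up boundary
  expect_equal(region_proportions(125, 1000), 0.13)
  expect_equal(region_proportions(0, 0), 0)
})

test_that("regional summary tallies directions and unique genes per region", {
  ann <- fake_annotated(direction = c("hyper", "hypo", rep("hyper", 8)))
  s <- regional_summary(ann, "group")
  expect_equal(s$site_count[s$region == "total"], 10L)
  expect_equal(s$site_count[s$region == "promoter"], 2L)
  expect_equal(s$hyper + s$hypo, s$site_count)
  expect_equal(s$proportion,
               region_proportions(s$site_count, 10))
  expect_equal(s$n_genes[s$region == "intron"], 1L)
  # empty input yields an all-zero table
  z <- regional_summary(fake_annotated()[0, ], "consensus")
  expect_true(all(z$site_count == 0) && all(z$proportion == 0))
})

test_that("mixed sites count toward totals but not hyper/hypo", {
  ann <- fake_annotated(direction = c(rep("hyper", 8), "mixed", "hypo"))
  ann$mean_diff <- ann$meth_diff; ann$min_padj <- ann$padj
  s <- regional_summary(ann, "consensus")
  tot <- s[s$region == "total", ]
  expect_equal(tot$hyper + tot$hypo + tot$mixed, tot$site_count)
  expect_equal(tot$mixed, 1L)
})

test_that("top-site ranking is by |diff| with padj and position tie-breaks", {
  ann <- fake_annotated(n_prom = 0, n_exon = 5, n_intron = 0, n_inter = 0)
  ann$meth_diff <- c(0.52, -0.42, 0.41, 0.30, -0.30)
  ann$padj <- c(0.01, 0.01, 0.01, 0.004, 0.002)
  tops <- rank_top_sites(ann, n = 4, tier = "group")
  expect_equal(tops$exon$diff, c(0.52, -0.42, 0.41, -0.30))
  # equal |diff|: smaller padj first
  expect_equal(tops$exon$pos[4], 50L)
  # fewer than n rows: all returned
  expect_equal(nrow(rank_top_sites(ann, n = 30, tier = "group")$exon), 5L)
})

test_that("LSI arithmetic and categories match the worked examples", {
  ph <- data.frame(pair = c(1, 1), group = c("CON", "RES"),
                   fetal_mass_kg = c(5, 5), liver_mass_g = c(150, 120))
  r <- compute_lsi(ph)
  expect_equal(r$lsi, 0.8)
  expect_equal(r$category, "loss")
  expect_equal(lsi_category(c(0.791, 0.820, 0.900, 1.048)),
               c("loss", "loss", "loss", "sparing"))
  expect_equal(lsi_category(1), "neutral")
  bad <- ph[1, ]
  expect_error(compute_lsi(bad), "pair '1'")
})

test_that("severity association recovers a perfect monotone relation", {
  mk <- function(n, dirs = rep("hyper", n))
    data.frame(chrom = "chr1", pos = seq_len(n), direction = dirs)
  sets <- list(`1` = mk(100), `2` = mk(80), `3` = mk(60), `4` = mk(40))
  lsi <- data.frame(pair = as.character(1:4), lsi = c(0.7, 0.8, 0.9, 1.05))
  out <- severity_association(sets, lsi)
  expect_equal(out$rho_burden, -1)
  # constant burden: undefined, flagged
  setsc <- list(`1` = mk(5), `2` = mk(5), `3` = mk(5), `4` = mk(5))
  outc <- severity_association(setsc, lsi)
  expect_true(is.na(outc$rho_burden))
  expect_match(outc$note, "undefined")
})
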