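test_that("feature generator produces the requested gene structure", {
  cfg <- tiny_config(n_genes = 1L, exons_per_gene = c(2L, 2L),
                     engineer_overlap = FALSE, n_islands = 0L)
  fs <- gen_feature_annotation(cfg)
  tab <- table(fs$kind[fs$chrom == "chr1"])
  expect_equal(unname(tab[["promoter"]]), 1L)
  expect_equal(unname(tab[["exon"]]), 2L)
  expect_equal(unname(tab[["intron"]]), 1L)
  expect_equal(unname(tab[["gene_body"]]), 1L)
  # intron is exactly the inter-exon gap
  ex <- fs[fs$kind == "exon" & fs$chrom == "chr1", ]
  intr <- fs[fs$kind == "intron" & fs$chrom == "chr1", ]
  expect_equal(intr$start, min(ex$end) + 1)
  expect_equal(intr$end, max(ex$start) - 1)
})

test_that("engineered overlap yields a position with exon and intron of different genes", {
  cfg <- tiny_config(engineer_overlap = TRUE)
  fs <- gen_feature_annotation(cfg)
  ex <- fs[fs$kind == "exon", ]
  intr <- fs[fs$kind == "intron", ]
  found <- FALSE
  for (i in seq_len(nrow(ex))) {
    j <- intr$chrom == ex$chrom[i] & intr$start <= ex$start[i] &
      intr$end >= ex$end[i] & intr$gene_symbol != ex$gene_symbol[i]
    if (any(j)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("infeasible gene packing fails with a named constraint", {
  cfg <- tiny_config(n_genes = 50L, chrom_length = 2e4, n_cpgs = 100L)
  expect_error(gen_feature_annotation(cfg), "infeasible packing")
})

test_that("same seed gives byte-identical annotation and counts", {
  cfg <- tiny_config()
  f1 <- gen_feature_annotation(cfg)
  f2 <- gen_feature_annotation(cfg)
  expect_identical(f1, f2)
  s1 <- gen_twin_methylome(cfg)
  s2 <- gen_twin_methylome(cfg)
  expect_identical(s1$counts$meth, s2$counts$meth)
  expect_identical(s1$counts$total, s2$counts$total)
  expect_identical(s1$truth, s2$truth)
  p1 <- tempfile(fileext = ".gff3"); p2 <- tempfile(fileext = ".gff3")
  write_features_gff3(f1, p1); write_features_gff3(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(gen_phenotypes(cfg), gen_phenotypes(cfg))
})

test_that("hyper_fraction 1 forces all positive signs; zero effect means no dm", {
  s <- gen_twin_methylome(tiny_config(hyper_fraction = 1))
  expect_true(all(s$truth$true_effect_sign[s$truth$is_dm] == "+"))
  s0 <- gen_twin_methylome(tiny_config(effect_size = 0, dm_fraction = 0.5))
  expect_false(any(s0$truth$is_dm))
  expect_true(all(s0$truth$effect_pair1 == 0))
})

test_that("dm fraction is recovered within the binomial 99% interval", {
  cfg <- tiny_config(n_cpgs = 20000L, chrom_length = 5e5, dm_fraction = 0.05)
  s <- gen_twin_methylome(cfg)
  f <- mean(s$truth$is_dm)
  half <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / 20000)
  expect_gte(f, 0.05 - half)
  expect_lte(f, 0.05 + half)
})

test_that("truth table signs match the applied shifts", {
  s <- gen_twin_methylome(tiny_config(n_cpgs = 4000L))
  eff <- as.matrix(s$truth[, grep("^effect_pair", names(s$truth))])
  dm <- s$truth$is_dm
  expect_true(all(rowSums(abs(eff[!dm, , drop = FALSE])) == 0))
  sgn <- ifelse(s$truth$true_effect_sign[dm] == "+", 1, -1)
  # every nonzero realised per-pair effect agrees with the recorded sign
  expect_true(all(eff[dm, ] * sgn >= 0))
  expect_true(all(rowSums(abs(eff[dm, , drop = FALSE])) > 0))
})

test_that("null sites show no systematic group difference at scale", {
  cfg <- sim_config(n_cpgs = 20000L, chrom_length = 5e5, effect_size = 0,
                    mean_depth = 15, seed = 7)
  s <- gen_twin_methylome(cfg)
  cm <- s$counts
  con <- cm$sheet$sample[cm$sheet$group == "CON"]
  res <- cm$sheet$sample[cm$sheet$group == "RES"]
  rc <- sum(cm$meth[, con]) / sum(cm$total[, con])
  rr <- sum(cm$meth[, res]) / sum(cm$total[, res])
  expect_lt(abs(rr - rc), 0.01)
})

test_that("counts are overdispersed relative to a binomial oracle when phi > 0", {
  set.seed(99)
  m <- 30L; p <- 0.4; phi <- 0.2; n <- 4000
  x <- twinmeth:::rbetabinom(n, m, p, phi)
  v_bin <- m * p * (1 - p)
  v_bb <- m * p * (1 - p) * (1 + (m - 1) * phi)
  expect_gt(var(x), 2 * v_bin)        # far beyond binomial variance
  expect_lt(abs(var(x) - v_bb) / v_bb, 0.2)
})

test_that("phenotypes follow the severity gradient", {
  ph0 <- gen_phenotypes(tiny_config(pair_severity = c(0, 0, 0, 0)))
  lsi0 <- compute_lsi(ph0)
  expect_true(all(abs(lsi0$lsi - 1) < 0.05))
  cfg <- tiny_config(pair_severity = c(0.2, 0.4, 0.6, 0.8))
  lsi <- compute_lsi(gen_phenotypes(cfg))
  expect_true(all(diff(lsi$lsi[order(lsi$pair)]) < 0))
})

test_that("generator rejects invalid configurations", {
  expect_error(tiny_config(phi = 0), "phi")
  expect_error(tiny_config(phi = 1), "phi")
  expect_error(tiny_config(pair_severity = c(0.5, 1)), "pair_severity")
  expect_error(tiny_config(dm_fraction = 1.2), "dm_fraction")
  expect_error(tiny_config(mean_depth = 0), "mean_depth")
})
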