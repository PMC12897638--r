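test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    p <- round(runif(n), 3)
    if (i %% 3 == 0) p[2] <- p[1]          # force ties
    padj <- bh_adjust(p)
    expect_equal(padj, pmin(naive_bh(p), 1))
    expect_true(all(padj >= p & padj <= 1))
  }
  expect_error(bh_adjust(c(0.2, 1.4)), "0, 1")
})

test_that("dispersion estimation clips degenerate data and needs replicates", {
  cm <- make_cm(
    total_con = list(rep(10, 3), rep(10, 3)),
    meth_con = list(rep(5, 3), rep(5, 3)),
    total_res = list(rep(10, 3), rep(10, 3)),
    meth_res = list(rep(5, 3), rep(5, 3)))
  est <- estimate_dispersion(cm)
  expect_equal(est$phi, est$phi_floor)     # identical ratios -> floor
  cm1 <- make_cm(total_con = list(c(10, 10)), meth_con = list(c(5, 2)),
                 total_res = list(c(0, 0)), meth_res = list(c(0, 0)))
  cm1$total[, "CON1"] <- c(10L, 0L)        # leave <2 covered everywhere
  cm1$meth[, "CON1"] <- c(5L, 0L)
  cm1$total[, "RES1"] <- c(0L, 0L)
  expect_error(estimate_dispersion(cm1), "2 covered samples")
})

test_that("genomewide dispersion recovers the simulated phi", {
  cfg <- sim_config(n_cpgs = 5000L, chrom_length = 2e5, mean_depth = 30,
                    phi = 0.10, effect_size = 0, seed = 21)
  s <- gen_twin_methylome(cfg)
  est <- estimate_dispersion(s$counts)
  expect_lt(abs(est$phi - 0.10), 0.03)
})

test_that("group Wald test handles symmetry, arithmetic and the sign convention", {
  eq <- make_cm(
    total_con = rep(list(rep(10, 1)), 4), meth_con = rep(list(5), 4),
    total_res = rep(list(rep(10, 1)), 4), meth_res = rep(list(5), 4))
  r <- wald_test_group(eq, 0.05)
  expect_equal(r$meth_diff, 0)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  # CON ratios (0.2, 0.4), RES (0.8, 0.6) at equal depth -> +0.4
  cm <- make_cm(total_con = list(10, 10), meth_con = list(2, 4),
                total_res = list(10, 10), meth_res = list(8, 6))
  r2 <- wald_test_group(cm, 0.05)
  expect_equal(r2$meth_diff, 0.4)
  expect_gt(r2$z, 0)
})

test_that("swapping group labels negates meth_diff and preserves p", {
  set.seed(8)
  cm <- make_cm(
    total_con = replicate(4, rpois(20, 12) + 1, simplify = FALSE),
    meth_con = replicate(4, rep(0L, 20), simplify = FALSE),
    total_res = replicate(4, rpois(20, 12) + 1, simplify = FALSE),
    meth_res = replicate(4, rep(0L, 20), simplify = FALSE))
  cm$meth <- matrix(rbinom(length(cm$total), cm$total, 0.4),
                    nrow(cm$total), dimnames = dimnames(cm$total))
  swapped <- cm
  swapped$sheet$group <- ifelse(cm$sheet$group == "CON", "RES", "CON")
  a <- wald_test_group(cm, 0.05)
  b <- wald_test_group(swapped, 0.05)
  expect_equal(a$meth_diff, -b$meth_diff)
  expect_equal(a$p, b$p)
})

test_that("|z| grows with the group mean difference at fixed depth", {
  zs <- vapply(c(0.1, 0.2, 0.3, 0.4), function(d) {
    k <- round((0.5 + d / 2) * 100)
    cm <- make_cm(total_con = list(100, 100),
                  meth_con = list(100 - k, 100 - k),
                  total_res = list(100, 100), meth_res = list(k, k))
    abs(wald_test_group(cm, 0.05)$z)
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("zero-variance guard and untestable flags behave", {
  cm <- make_cm(total_con = list(c(10, 10, 0)), meth_con = list(c(0, 10, 0)),
                total_res = list(c(10, 10, 0)), meth_res = list(c(0, 10, 0)))
  r <- wald_test_group(cm, 0.05)
  expect_equal(r$p[1:2], c(1, 1))          # both-zero and both-one
  expect_equal(r$status[3], "no_coverage")
  expect_true(is.na(r$padj[3]))
})

test_that("pair test reduces to the site ratio in an isolated window", {
  cm <- make_cm(total_con = list(10), meth_con = list(1),
                total_res = list(10), meth_res = list(9))
  r <- wald_test_pair(cm, 1, 0.05)
  expect_equal(r$meth_diff_pair, 0.8)      # isolated site: smoothed = raw
  expect_equal(r$site_diff, 0.8)
  expect_gt(r$z, 0)
})

test_that("pair test smooths across a window and flags uncovered twins", {
  # three sites within 250 bp; middle site gets pooled evidence
  cm <- make_cm(total_con = list(c(10, 10, 10, 0)),
                meth_con = list(c(0, 0, 0, 0)),
                total_res = list(c(10, 10, 10, 5)),
                meth_res = list(c(10, 10, 10, 5)),
                pos = c(100L, 200L, 300L, 5000L))
  r <- wald_test_pair(cm, 1, 0.05)
  expect_equal(r$meth_diff_pair[2], 1)
  expect_lt(r$se[2], r$se[1] * 1.01)       # window pooling tightens the SE
  expect_equal(r$status[4], "no_site_coverage")
  expect_true(is.na(r$p[4]))
  # smoothed contrast equals the weighted mean of per-site differences
  expect_equal(r$meth_diff_pair[1], 1)
})

test_that("pair BH adjustment is applied within the pair", {
  cm <- make_cm(total_con = list(rep(20, 6)), meth_con = list(rep(2, 6)),
                total_res = list(rep(20, 6)), meth_res = list(rep(18, 6)),
                pos = c(1L, 1000L, 2000L, 3000L, 4000L, 5000L) * 10L)
  r <- wald_test_pair(cm, 1, 0.05)
  expect_equal(r$padj, bh_adjust(r$p))
})
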