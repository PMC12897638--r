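sheet1 <- data.frame(sample = c("CON1", "RES1"), group = c("CON", "RES"),
                     pair = c(1, 1))

test_that("dialect coordinate conventions converge on the same record", {
  d <- tempfile(); dir.create(d)
  bg <- file.path(d, "s.bedGraph")
  writeLines("chr1\t99\t100\t50\t5\t5", bg)
  cov <- file.path(d, "s.cov")
  writeLines("chr1\t100\t100\t50\t5\t5", cov)
  r1 <- read_counts(c(CON1 = bg, RES1 = bg), "methyldackel_bedgraph", sheet1)
  r2 <- read_counts(c(CON1 = cov, RES1 = cov), "bismark_cov", sheet1)
  expect_equal(r1$sites, data.frame(chrom = "chr1", pos = 100L))
  expect_identical(r1$sites, r2$sites)
  expect_identical(r1$meth, r2$meth)
  expect_equal(unname(r1$meth[1, "CON1"]), 5L)
  expect_equal(unname(r1$total[1, "CON1"]), 10L)
})

test_that("invalid and duplicate count records are rejected with context", {
  f <- tempfile()
  writeLines(c("chr1\t10\t10\t50\t7\t-1"), f)
  expect_error(read_counts(c(CON1 = f, RES1 = f), "bismark_cov", sheet1),
               "line 1")
  writeLines(c("chr1\t10\t10\t50\t5\t5", "chr1\t10\t10\t40\t4\t6"), f)
  expect_error(read_counts(c(CON1 = f, RES1 = f), "bismark_cov", sheet1),
               "duplicate site")
  writeLines("chr1\t10\tgarbage", f)
  expect_error(read_counts(c(CON1 = f, RES1 = f), "bismark_cov", sheet1),
               "malformed")
})

test_that("sites absent from one sample read back as zero total, and round-trip", {
  d <- tempfile(); dir.create(d)
  writeLines(c("chr1\t100\t100\t50\t3\t3", "chr1\t200\t200\t100\t4\t0"),
             file.path(d, "a.cov"))
  writeLines("chr1\t100\t100\t25\t2\t6", file.path(d, "b.cov"))
  cm <- read_counts(c(CON1 = file.path(d, "a.cov"),
                      RES1 = file.path(d, "b.cov")), "bismark_cov", sheet1)
  expect_equal(nrow(cm$sites), 2L)
  expect_equal(unname(cm$total[, "RES1"]), c(8L, 0L))
  for (dia in c("bismark_cov", "methyldackel_bedgraph")) {
    od <- tempfile(); paths <- write_counts(cm, od, dia)
    back <- read_counts(paths, dia, sheet1)
    expect_identical(back$sites, cm$sites)
    expect_identical(back$meth, cm$meth)
    expect_identical(back$total, cm$total)
  }
})

test_that("strand collapsing pools counts onto the plus-strand cytosine", {
  cpgs <- data.frame(chrom = "chr1", pos = c(100L, 300L))
  rec <- data.frame(chrom = "chr1", pos = c(100L, 101L, 200L),
                    meth = c(3L, 2L, 1L), total = c(6L, 4L, 8L))
  out <- collapse_strands(rec, cpgs)
  expect_equal(out$pos, c(100L, 200L))
  expect_equal(out$meth, c(5L, 1L))
  expect_equal(out$total, c(10L, 8L))
  # pooled ratio, not mean of ratios
  rec2 <- data.frame(chrom = "chr1", pos = c(100L, 101L),
                     meth = c(3L, 0L), total = c(6L, 4L))
  out2 <- collapse_strands(rec2, cpgs)
  expect_equal(out2$meth / out2$total, 0.3)
  # ambiguous adjacent CpG declarations fail
  expect_error(collapse_strands(rec, data.frame(chrom = "chr1",
                                                pos = c(100L, 101L))),
               "overlapping collapse")
})

test_that("methylation ratio is plain division with a no-coverage error", {
  expect_equal(compute_ratio(5, 10), 0.5)
  expect_equal(compute_ratio(0, 7), 0)
  expect_equal(compute_ratio(7, 7), 1)
  expect_error(compute_ratio(0, 0), "no coverage")
  expect_error(compute_ratio(8, 7), "meth_reads")
})

test_that("coverage filter applies the within-one-group rule", {
  cm <- make_cm(
    total_con = list(c(6, 6, 0), c(6, 4, 0), c(2, 4, 0), c(2, 4, 0)),
    meth_con = list(c(1, 1, 0), c(1, 1, 0), c(1, 1, 0), c(1, 1, 0)),
    total_res = list(c(1, 4, 5), c(1, 4, 5), c(1, 4, 0), c(1, 4, 0)),
    meth_res = list(c(0, 1, 2), c(0, 1, 2), c(0, 1, 0), c(0, 1, 0)))
  out <- coverage_filter(cm, 5, 2)
  # site 1: CON has two samples >= 5 -> kept
  # site 2: no group has two samples >= 5 -> dropped
  # site 3: RES has two samples >= 5 -> kept ("in any group")
  expect_equal(out$sites$pos, c(1000L, 3000L))
  log <- attr(out, "filter_log")
  expect_equal(log$n_kept, 2L)
  # idempotent, and counts unchanged
  again <- coverage_filter(out, 5, 2)
  expect_identical(again$meth, out$meth)
  expect_identical(again$sites, out$sites)
  expect_identical(out$meth[1, ], cm$meth[1, ])
})

test_that("sample sheet validation enforces the paired design", {
  bad <- data.frame(sample = c("a", "b"), group = c("CON", "CON"),
                    pair = c(1, 1))
  expect_error(validate_sample_sheet(bad), "both groups")
  bad2 <- data.frame(sample = c("a", "b", "c"),
                     group = c("CON", "RES", "RES"), pair = c(1, 1, 1))
  expect_error(validate_sample_sheet(bad2), "exactly one")
  p <- tempfile()
  write_sample_sheet(sheet1, p)
  expect_equal(read_sample_sheet(p)$sample, c("CON1", "RES1"))
})
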