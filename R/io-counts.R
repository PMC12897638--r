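#' Read per-cytosine methylation count files into a count matrix
#'
#' Supports two extractor dialects, both six-column TSVs:
#' * `bismark_cov`: chrom, start (1-based), end, methylation %, count
#'   methylated, count unmethylated;
#' * `methyldackel_bedgraph`: chrom, start (0-based), end, methylation %,
#'   count methylated, count unmethylated.
#'
#' The percentage column is ignored in favour of the counts; coordinates
#' are normalised to 1-based cytosine positions. Files are merged on the
#' (chrom, pos) key: a site absent from a sample gets `total_reads = 0`
#' there (dropping low-coverage sites is a separate, logged step — see
#' [coverage_filter()]).
#'
#' @param paths Named character vector of file paths; names are sample ids
#'   and must match the sheet.
#' @param dialect `"bismark_cov"` or `"methyldackel_bedgraph"`; no sniffing.
#' @param sheet Sample sheet (see [validate_sample_sheet()]).
#' @return A [count_matrix()].
#' @export
read_counts <- function(paths, dialect = c("bismark_cov", "methyldackel_bedgraph"),
                        sheet) {
  dialect <- match.arg(dialect)
  sheet <- validate_sample_sheet(sheet)
  if (is.null(names(paths)) || !setequal(names(paths), sheet$sample))
    stop2("paths must be named by sample id and cover the sample sheet")
  per_sample <- lapply(sheet$sample, function(s) {
    rec <- read_count_file(paths[[s]], dialect)
    if (anyDuplicated(site_key(rec)))
      stop2("duplicate site within sample '", s, "' in ", paths[[s]])
    rec
  })
  names(per_sample) <- sheet$sample

  keys <- unique(do.call(rbind, lapply(per_sample, function(r)
    r[, c("chrom", "pos")])))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  rownames(keys) <- NULL
  kk <- site_key(keys)
  meth <- total <- matrix(0L, nrow(keys), nrow(sheet),
                          dimnames = list(NULL, sheet$sample))
  for (s in sheet$sample) {
    i <- match(site_key(per_sample[[s]]), kk)
    meth[i, s] <- per_sample[[s]]$meth
    total[i, s] <- per_sample[[s]]$total
  }
  count_matrix(keys, meth, total, sheet)
}

read_count_file <- function(path, dialect) {
  if (!file.exists(path)) stop2("count file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric", "numeric", "numeric"),
                      col.names = c("chrom", "start", "end", "pct",
                                    "meth", "unmeth")),
    error = function(e) stop2("malformed count file ", path, ": ",
                              conditionMessage(e)))
  bad <- which(df$meth < 0 | df$unmeth < 0 |
                 df$meth != floor(df$meth) | df$unmeth != floor(df$unmeth))
  if (length(bad))
    stop2("invalid counts (meth ", df$meth[bad[1]], ", unmeth ",
          df$unmeth[bad[1]], ") at ", path, " line ", bad[1])
  pos <- if (dialect == "methyldackel_bedgraph") df$start + 1 else df$start
  if (any(pos < 1)) stop2("position < 1 in ", path)
  data.frame(chrom = df$chrom, pos = as.integer(pos),
             meth = as.integer(df$meth),
             total = as.integer(df$meth + df$unmeth),
             stringsAsFactors = FALSE)
}

#' Write a count matrix to per-sample count files
#'
#' Inverse of [read_counts()]: one file per sample in the requested
#' dialect. Sites with zero coverage in a sample are omitted from that
#' sample's file, as extractors do.
#'
#' @param cm A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @param dialect Output dialect, as in [read_counts()].
#' @return Named vector of written paths, invisibly.
#' @export
write_counts <- function(cm, dir,
                         dialect = c("bismark_cov", "methyldackel_bedgraph")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "bismark_cov") ".cov" else ".bedGraph"
  paths <- vapply(cm$sheet$sample, function(s) {
    keep <- cm$total[, s] > 0
    meth <- cm$meth[keep, s]; total <- cm$total[keep, s]
    pos <- cm$sites$pos[keep]
    start <- if (dialect == "bismark_cov") pos else pos - 1L
    df <- data.frame(cm$sites$chrom[keep], start, pos,
                     round(100 * meth / total, 6), meth, total - meth)
    p <- file.path(dir, paste0(s, ext))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Collapse opposite-strand cytosine records onto CpG positions
#'
#' For extractors that report the + and - strand cytosines of a CpG
#' separately: counts of the minus-strand record (at `pos + 1`) are summed
#' onto the plus-strand C position. Records not matching any supplied CpG
#' position pass through unchanged. Pooled counts, not averaged ratios:
#' 3/6 at the + C and 0/4 at the - C collapse to 3/10.
#'
#' @param records data.frame with `chrom`, `pos`, `meth`, `total`.
#' @param cpg_positions data.frame with `chrom`, `pos` giving the
#'   plus-strand C of each CpG dinucleotide.
#' @return Collapsed records, sorted by (chrom, pos).
#' @export
collapse_strands <- function(records, cpg_positions) {
  ck <- site_key(cpg_positions)
  if (anyDuplicated(ck)) stop2("duplicate CpG positions supplied")
  minus_key <- paste(cpg_positions$chrom, cpg_positions$pos + 1, sep = ":")
  if (any(minus_key %in% ck))
    stop2("overlapping collapse requests: adjacent positions ",
          "both declared as plus-strand CpG cytosines")
  rk <- site_key(records)
  target <- ifelse(rk %in% ck, rk,
                   ifelse(rk %in% minus_key, ck[match(rk, minus_key)], rk))
  agg <- stats::aggregate(records[, c("meth", "total")],
                          by = list(key = target), FUN = sum)
  parts <- strsplit(agg$key, ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    meth = agg$meth, total = agg$total, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Methylation ratio of a cytosine
#'
#' Reads reporting a C divided by reads reporting a C or a T. No smoothing
#' and no pseudocounts; zero total coverage is an error (a "no coverage"
#' condition the caller must filter out first), never silently 0.
#'
#' @param meth_reads,total_reads Non-negative counts, `meth <= total`.
#' @return Ratio in \[0, 1\].
#' @export
compute_ratio <- function(meth_reads, total_reads) {
  if (any(total_reads == 0))
    stop2("no coverage: total_reads = 0 has no defined ratio; ",
          "filter uncovered sites before computing ratios")
  if (any(meth_reads < 0) || any(meth_reads > total_reads))
    stop2("require 0 <= meth_reads <= total_reads")
  meth_reads / total_reads
}

#' Coverage pre-filter
#'
#' Keeps a CpG iff at least one group contains `min_samples` or more
#' samples with read depth `>= min_depth` at that site (the qualifying
#' samples must lie within a single group). Counts are never altered, only
#' site membership; site order is preserved and the kept/total counts are
#' attached as the `filter_log` attribute.
#'
#' @param cm A [count_matrix()].
#' @param min_depth Minimum read depth per qualifying sample (default 5).
#' @param min_samples Minimum qualifying samples within one group
#'   (default 2).
#' @return Filtered [count_matrix()].
#' @export
coverage_filter <- function(cm, min_depth = 5L, min_samples = 2L) {
  stopifnot(min_depth >= 1, min_samples >= 1)
  ok <- cm$total >= min_depth
  keep <- rep(FALSE, nrow(cm$sites))
  for (g in unique(cm$sheet$group)) {
    cols <- cm$sheet$sample[cm$sheet$group == g]
    keep <- keep | rowSums(ok[, cols, drop = FALSE]) >= min_samples
  }
  out <- subset_sites(cm, keep)
  attr(out, "filter_log") <- list(n_in = nrow(cm$sites), n_kept = sum(keep),
                                  min_depth = min_depth,
                                  min_samples = min_samples)
  out
}

#' Read / write a sample sheet TSV (`sample  group  pair`)
#' @param path File path.
#' @return [read_sample_sheet()]: a validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(utils::read.table(path, header = TRUE, sep = "\t",
                                          stringsAsFactors = FALSE))
}

#' @rdname read_sample_sheet
#' @param sheet A sample sheet.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(validate_sample_sheet(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
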