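#' Construct a per-CpG count matrix with design metadata
#'
#' The central container of the pipeline: an ordered site list with, per
#' sample, methylated and total read counts, plus the sample sheet tying
#' each sample to its treatment group (CON/RES) and twin pair.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based position of
#'   the CpG cytosine).
#' @param meth,total Integer matrices, sites x samples, with
#'   `0 <= meth <= total`; column names are sample ids.
#' @param sheet data.frame with columns `sample`, `group` (`CON`/`RES`),
#'   `pair`; every pair must have exactly one CON and one RES sample.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(sites, meth, total, sheet) {
  sheet <- validate_sample_sheet(sheet)
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (!identical(dim(meth), dim(total)) || nrow(meth) != nrow(sites))
    stop2("meth/total dimensions must match each other and the site list")
  if (is.null(colnames(meth))) colnames(meth) <- sheet$sample
  if (is.null(colnames(total))) colnames(total) <- colnames(meth)
  if (!setequal(colnames(meth), sheet$sample))
    stop2("count matrix columns must match the sample sheet")
  meth <- meth[, sheet$sample, drop = FALSE]
  total <- total[, sheet$sample, drop = FALSE]
  if (any(meth < 0) || any(total < 0) || any(meth > total))
    stop2("counts must satisfy 0 <= meth_reads <= total_reads")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, c("chrom", "pos"), drop = FALSE]
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop2("duplicate sites in count matrix")
  rownames(sites) <- NULL
  structure(
    list(sites = sites,
         meth = meth[ord, , drop = FALSE],
         total = total[ord, , drop = FALSE],
         sheet = sheet),
    class = "count_matrix"
  )
}

#' Validate a sample sheet
#'
#' @param sheet data.frame with columns `sample`, `group`, `pair`.
#' @return The sheet with `group` normalised to character `CON`/`RES`.
#' @export
validate_sample_sheet <- function(sheet) {
  stopifnot(is.data.frame(sheet),
            all(c("sample", "group", "pair") %in% names(sheet)))
  sheet$sample <- as.character(sheet$sample)
  sheet$group <- as.character(sheet$group)
  if (!all(sheet$group %in% c("CON", "RES")))
    stop2("group must be CON or RES")
  if (anyDuplicated(sheet$sample)) stop2("duplicate sample ids in sheet")
  if (!all(c("CON", "RES") %in% sheet$group))
    stop2("both groups must be non-empty")
  tab <- table(sheet$pair, sheet$group)
  if (!all(tab == 1L))
    stop2("each pair id must map to exactly one CON and one RES sample")
  sheet[, c("sample", "group", "pair")]
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$sites), "CpG sites x", ncol(x$meth),
      "samples (", sum(x$sheet$group == "CON"), "CON /",
      sum(x$sheet$group == "RES"), "RES,",
      length(unique(x$sheet$pair)), "pairs )\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$meth)

# subset sites by logical/integer index, preserving metadata
subset_sites <- function(cm, idx) {
  cm$sites <- cm$sites[idx, , drop = FALSE]
  rownames(cm$sites) <- NULL
  cm$meth <- cm$meth[idx, , drop = FALSE]
  cm$total <- cm$total[idx, , drop = FALSE]
  cm
}

site_key <- function(df) paste(df$chrom, df$pos, sep = ":")
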