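#' Two-tier dmCpG calling configuration
#'
#' @param alpha FDR threshold on `padj` (inclusive; default 0.05).
#' @param min_diff Absolute methylation-difference threshold (inclusive;
#'   default 0.10).
#' @param consensus_k Minimum number of qualifying pairs for a consensus
#'   call (default 3).
#' @param n_pairs Number of pairs in the design (default 4).
#' @return A `tier_config` list.
#' @export
tier_config <- function(alpha = 0.05, min_diff = 0.10,
                        consensus_k = 3L, n_pairs = 4L) {
  if (alpha <= 0 || alpha > 1) stop2("alpha must lie in (0, 1]")
  if (min_diff < 0 || min_diff > 1) stop2("min_diff must lie in [0, 1]")
  if (consensus_k < 1 || consensus_k > n_pairs)
    stop2("consensus_k must lie in [1, n_pairs]")
  structure(list(alpha = alpha, min_diff = min_diff,
                 consensus_k = as.integer(consensus_k),
                 n_pairs = as.integer(n_pairs)), class = "tier_config")
}

#' Group-level dmCpG filter
#'
#' Keeps sites with `padj <= alpha` AND `|meth_diff| >= min_diff` (both
#' inclusive, exactly as the thresholds are printed) and assigns a
#' direction: `hyper` for positive `meth_diff` (higher methylation in the
#' nutrient-restricted group), `hypo` for negative. Untestable sites never
#' qualify.
#'
#' @param results Output of [wald_test_group()].
#' @param cfg A [tier_config()].
#' @return data.frame of dmCpGs with a `direction` column.
#' @export
filter_group_level <- function(results, cfg = tier_config()) {
  keep <- !is.na(results$padj) & results$padj <= cfg$alpha &
    abs(results$meth_diff) >= cfg$min_diff
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$meth_diff > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Per-pair dmCpG filter
#'
#' Applies the same inclusive thresholds as [filter_group_level()] to each
#' pair's test results independently; a site may pass in some pairs only.
#'
#' @param pair_results List of [wald_test_pair()] outputs (or one combined
#'   data.frame with a `pair` column).
#' @param cfg A [tier_config()].
#' @return Named list of per-pair dmCpG data.frames.
#' @export
filter_pairwise <- function(pair_results, cfg = tier_config()) {
  if (is.data.frame(pair_results))
    pair_results <- split(pair_results, pair_results$pair)
  out <- lapply(pair_results, function(res) {
    keep <- !is.na(res$padj) & res$padj <= cfg$alpha &
      abs(res$meth_diff_pair) >= cfg$min_diff
    df <- res[keep, , drop = FALSE]
    df$direction <- ifelse(df$meth_diff_pair > 0, "hyper", "hypo")
    rownames(df) <- NULL
    df
  })
  if (is.null(names(out)))
    names(out) <- vapply(pair_results, function(res)
      as.character(res$pair[1]), character(1))
  out
}

#' Direction class of a set of signed methylation differences
#'
#' All positive: `hyper`; all negative: `hypo`; otherwise `mixed`
#' (concordant directionality across qualifying pairs is not enforced).
#' Zero differences cannot occur after effect-size thresholding and are
#' rejected as an upstream bug.
#'
#' @param diffs Non-empty numeric vector of non-zero differences.
#' @return `"hyper"`, `"hypo"` or `"mixed"`.
#' @export
classify_direction <- function(diffs) {
  if (!length(diffs)) stop2("empty difference vector")
  if (any(diffs == 0))
    stop2("zero methylation difference cannot reach direction ",
          "classification (|diff| threshold upstream)")
  if (all(diffs > 0)) "hyper" else if (all(diffs < 0)) "hypo" else "mixed"
}

#' k-of-n consensus across twin pairs
#'
#' A site is retained iff it passed the per-pair thresholds in at least
#' `consensus_k` of the pairs. Matching is by exact (chrom, pos) key.
#' Evidence is aggregated over the qualifying pairs only: `mean_diff` is
#' the mean of their methylation differences, `min_padj` the smallest of
#' their adjusted p-values, and `direction` is `hyper`/`hypo` when all
#' qualifying differences agree in sign, else `mixed`.
#'
#' @param pair_sets Named list of per-pair dmCpG data.frames
#'   ([filter_pairwise()]).
#' @param cfg A [tier_config()].
#' @return data.frame: `chrom`, `pos`, `n_qualifying`, `pairs`
#'   (semicolon-joined ids), `mean_diff`, `min_padj`, `direction`, plus
#'   semicolon-joined per-pair `diffs` and `padjs`.
#' @export
consensus <- function(pair_sets, cfg = tier_config()) {
  for (nm in names(pair_sets))
    if (anyDuplicated(site_key(pair_sets[[nm]])))
      stop2("duplicated site within pair set '", nm,
            "': upstream bug in per-pair filtering")
  all_rows <- do.call(rbind, lapply(names(pair_sets), function(nm) {
    d <- pair_sets[[nm]]
    if (!nrow(d)) return(NULL)
    data.frame(chrom = d$chrom, pos = d$pos, pair = nm,
               diff = d$meth_diff_pair, padj = d$padj,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      n_qualifying = integer(0), pairs = character(0),
                      mean_diff = numeric(0), min_padj = numeric(0),
                      direction = character(0), diffs = character(0),
                      padjs = character(0), stringsAsFactors = FALSE)
  if (is.null(all_rows) || !nrow(all_rows)) return(empty)
  sp <- split(all_rows, site_key(all_rows))
  keep <- sp[vapply(sp, nrow, 1L) >= cfg$consensus_k]
  if (!length(keep)) return(empty)
  out <- do.call(rbind, lapply(keep, function(d) {
    d <- d[order(d$pair), , drop = FALSE]
    data.frame(chrom = d$chrom[1], pos = d$pos[1],
               n_qualifying = nrow(d),
               pairs = paste(d$pair, collapse = ";"),
               mean_diff = mean(d$diff),
               min_padj = min(d$padj),
               direction = classify_direction(d$diff),
               diffs = paste(signif(d$diff, 6), collapse = ";"),
               padjs = paste(signif(d$padj, 6), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
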