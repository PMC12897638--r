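#' Read / write gene sets in GMT format
#'
#' GMT: one term per line, tab-separated — term id, description, then one
#' or more member gene symbols. Duplicate members within a term are
#' dropped. The source tag of a term is the prefix of its id before the
#' first `:` (e.g. `collectionA:T0001`), or `"terms"` when the id carries
#' no prefix.
#'
#' @param path File path.
#' @return A `term_set`: list of terms, each with `id`, `name`, `source`,
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  terms <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop2("malformed GMT line ", i, " in ", path,
            ": need term id, description and >= 1 gene")
    src <- if (grepl(":", f[1], fixed = TRUE))
      sub(":.*$", "", f[1]) else "terms"
    list(id = f[1], name = f[2], source = src,
         genes = unique(f[-(1:2)]))
  })
  structure(terms, class = "term_set")
}

#' @rdname read_gmt
#' @param terms A `term_set`.
#' @export
write_gmt <- function(terms, path) {
  writeLines(vapply(terms, function(t)
    paste(c(t$id, t$name, t$genes), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= x)` of drawing at least the observed
#' intersection when `|query|` genes are sampled without replacement from
#' the universe, with `X ~ Hypergeometric(N = |universe|,
#' K = |term n universe|, n = |query|)`. Exact (stats::phyper), no
#' approximation. The term is intersected with the universe before
#' testing; the query must be a subset of the universe.
#'
#' @param query,term,universe Character vectors of gene symbols.
#' @return The p-value.
#' @export
hypergeom_test <- function(query, term, universe) {
  query <- unique(query); term <- unique(term); universe <- unique(universe)
  if (!length(query)) stop2("empty query gene list")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop2("query genes absent from the universe: ",
          paste(utils::head(extra, 10), collapse = ", "))
  K <- length(intersect(term, universe))
  x <- length(intersect(query, term))
  N <- length(universe)
  n <- length(query)
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' One hypergeometric test per term, BH-adjusted within each source
#' collection separately (mirroring per-database reporting). The rich
#' factor is `intersection_size / term_size` (term size after
#' intersection with the universe).
#'
#' @param query Character vector of gene symbols (subset of `universe`).
#' @param termsets A `term_set` ([read_gmt()] / [gen_gene_sets()]).
#' @param universe Background gene symbols.
#' @param q_threshold Significance threshold on FDR q (default 0.05).
#' @return data.frame, one row per term: `term_id`, `term_name`, `source`,
#'   `query_size`, `term_size`, `background_size`, `intersection_size`,
#'   `intersection_genes`, `p`, `fdr_q`, `rich_factor`, `neg_log10_fdr`,
#'   `significant`.
#' @export
enrich <- function(query, termsets, universe, q_threshold = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(termsets))
    return(data.frame(term_id = character(0), term_name = character(0),
                      source = character(0), query_size = integer(0),
                      term_size = integer(0), background_size = integer(0),
                      intersection_size = integer(0),
                      intersection_genes = character(0), p = numeric(0),
                      fdr_q = numeric(0), rich_factor = numeric(0),
                      neg_log10_fdr = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  rows <- do.call(rbind, lapply(termsets, function(t) {
    tg <- intersect(unique(t$genes), universe)
    ig <- sort(intersect(query, tg))
    data.frame(term_id = t$id, term_name = t$name, source = t$source,
               query_size = length(query), term_size = length(tg),
               background_size = length(universe),
               intersection_size = length(ig),
               intersection_genes = paste(ig, collapse = ";"),
               p = hypergeom_test(query, tg, universe),
               stringsAsFactors = FALSE)
  }))
  rows$fdr_q <- NA_real_
  for (src in unique(rows$source)) {
    sel <- rows$source == src
    rows$fdr_q[sel] <- bh_adjust(rows$p[sel])
  }
  rows$rich_factor <- ifelse(rows$term_size > 0,
                             rows$intersection_size / rows$term_size, NA_real_)
  rows$neg_log10_fdr <- -log10(rows$fdr_q)
  rows$significant <- rows$fdr_q <= q_threshold
  rownames(rows) <- NULL
  rows
}

#' Select the top enriched terms for plotting
#'
#' Significant rows sorted by FDR q ascending, ties broken by rich factor
#' descending, then term id; the first `n` are returned (all of them when
#' fewer terms meet significance).
#'
#' @param rows [enrich()] output.
#' @param n Number of terms (default 12).
#' @return The selected rows.
#' @export
select_top_terms <- function(rows, n = 12L) {
  sig <- rows[rows$significant, , drop = FALSE]
  ord <- order(sig$fdr_q, -sig$rich_factor, sig$term_id)
  out <- sig[ord, , drop = FALSE][seq_len(min(n, nrow(sig))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
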