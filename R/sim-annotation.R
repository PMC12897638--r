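#' Generate a synthetic gene/feature annotation
#'
#' Lays out `n_genes` transcripts per chromosome with exons, introns (the
#' inter-exon gaps), a strand-aware promoter window upstream of each TSS,
#' a `gene_body` span, and CpG islands over a subset of promoters. When
#' `engineer_overlap` is on (and at least two genes fit), one locus per
#' chromosome carries two overlapping genes on opposite strands arranged so
#' that an exon of one gene lies inside an intron of the other: a single
#' CpG there legitimately receives multiple annotation categories, which is
#' what makes regional site counts non-additive downstream.
#'
#' @param config A [sim_config()].
#' @return A `feature_set`: a data.frame with columns `chrom`, `start`,
#'   `end` (1-based inclusive), `strand`, `kind` (one of `promoter`,
#'   `exon`, `intron`, `gene_body`, `cpg_island`), `gene_symbol`,
#'   `transcript_accession`; the transcript-to-symbol mapping table is
#'   attached as attribute `gene_map`.
#' @examples
#' fs <- gen_feature_annotation(sim_config(n_genes = 4, seed = 7))
#' table(fs$kind)
#' @export
gen_feature_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "annotation"))

  gene_counter <- 0L
  rows <- list()

  new_transcript <- function(chrom, exon_starts, exon_ends, strand) {
    gene_counter <<- gene_counter + 1L
    sym <- sprintf("GENE%03d", gene_counter)
    acc <- sprintf("XM_%06d", gene_counter)
    body <- c(min(exon_starts), max(exon_ends))
    prom <- if (strand == "+") {
      c(body[1] - config$promoter_up, body[1] + config$promoter_down)
    } else {
      c(body[2] - config$promoter_down, body[2] + config$promoter_up)
    }
    prom <- pmin(pmax(prom, 1), config$chrom_length)
    out <- data.frame(
      chrom = chrom,
      start = c(body[1], exon_starts, prom[1]),
      end = c(body[2], exon_ends, prom[2]),
      strand = strand,
      kind = c("gene_body", rep("exon", length(exon_starts)), "promoter"),
      gene_symbol = sym, transcript_accession = acc,
      stringsAsFactors = FALSE
    )
    k <- length(exon_starts)
    if (k > 1L) {
      out <- rbind(out, data.frame(
        chrom = chrom, start = exon_ends[-k] + 1, end = exon_starts[-1] - 1,
        strand = strand, kind = "intron", gene_symbol = sym,
        transcript_accession = acc, stringsAsFactors = FALSE
      ))
    }
    out
  }

  for (ci in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ci)
    cursor <- config$promoter_up + 500
    remaining <- config$n_genes

    if (config$engineer_overlap && remaining >= 2L) {
      # gene A (+): exons [s,s+200] and [s+1000,s+1200];
      # gene B (-): exons [s+300,s+400] and [s+2300,s+2400].
      # A's second exon sits in B's intron and B's first exon in A's intron.
      s <- cursor
      rows[[length(rows) + 1L]] <-
        new_transcript(chrom, c(s, s + 1000), c(s + 200, s + 1200), "+")
      rows[[length(rows) + 1L]] <-
        new_transcript(chrom, c(s + 300, s + 2300), c(s + 400, s + 2400), "-")
      cursor <- s + 2400 + round(stats::runif(1, 1000, 4000))
      remaining <- remaining - 2L
    }

    while (remaining > 0L) {
      k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
      exon_len <- round(stats::runif(k, 150, 400))
      intron_len <- if (k > 1) round(stats::runif(k - 1, 400, 1500)) else numeric(0)
      starts <- cursor + c(0, cumsum(exon_len[-k] + intron_len))
      ends <- starts + exon_len - 1
      if (max(ends) + config$promoter_up > config$chrom_length) {
        stop2("infeasible packing: cannot place ", config$n_genes,
              " genes of this size on a chromosome of ", config$chrom_length,
              " bp (ran out of room at gene ", config$n_genes - remaining + 1,
              " on ", chrom, "); increase chrom_length or reduce n_genes")
      }
      strand <- sample(c("+", "-"), 1)
      rows[[length(rows) + 1L]] <- new_transcript(chrom, starts, ends, strand)
      cursor <- max(ends) + round(stats::runif(1, 2500, 6000))
      remaining <- remaining - 1L
    }

    # CpG islands centred on a sample of this chromosome's TSS positions
    chrom_rows <- do.call(rbind, rows)
    proms <- chrom_rows[chrom_rows$chrom == chrom & chrom_rows$kind == "promoter", ]
    n_isl <- min(config$n_islands, nrow(proms))
    if (n_isl > 0L) {
      pick <- proms[sample(nrow(proms), n_isl), ]
      centre <- round((pick$start + pick$end) / 2)
      half <- round(stats::runif(n_isl, 150, 400))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom,
        start = pmax(1, centre - half), end = pmin(config$chrom_length, centre + half),
        strand = "+", kind = "cpg_island",
        gene_symbol = NA_character_, transcript_accession = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }

  fs <- do.call(rbind, rows)
  fs <- fs[order(fs$chrom, fs$start, fs$end, fs$kind), , drop = FALSE]
  rownames(fs) <- NULL
  gm <- unique(fs[!is.na(fs$transcript_accession),
                  c("transcript_accession", "gene_symbol")])
  names(gm) <- c("accession", "symbol")
  rownames(gm) <- NULL
  structure(fs, gene_map = gm, class = c("feature_set", "data.frame"))
}

#' Generate synthetic gene-set collections
#'
#' Draws gene sets over the annotated gene universe, split across two
#' opaque source collections (stand-ins for pathway databases queried
#' side by side). Purely random membership: under a true treatment effect
#' concentrated in a subset of genes, sets that happen to intersect that
#' subset become enriched.
#'
#' @param features A `feature_set` (or character vector of gene symbols).
#' @param n_terms Number of terms to draw in total.
#' @param size_range Length-2 integer range of term sizes.
#' @param sources Character vector of source tags to cycle over.
#' @param seed Integer seed.
#' @return A `term_set` list; each element has `id`, `name`, `source`,
#'   `genes`.
#' @export
gen_gene_sets <- function(features, n_terms = 40L, size_range = c(5L, 25L),
                          sources = c("collectionA", "collectionB"),
                          seed = 1L) {
  genes <- if (is.character(features)) unique(features) else
    unique(stats::na.omit(features$gene_symbol))
  if (length(genes) < size_range[2])
    size_range[2] <- max(size_range[1], length(genes))
  set.seed(substream_seed(seed, "genesets"))
  terms <- lapply(seq_len(n_terms), function(i) {
    src <- sources[(i - 1L) %% length(sources) + 1L]
    sz <- sample(seq(size_range[1], size_range[2]), 1)
    list(id = sprintf("%s:T%04d", src, i),
         name = sprintf("synthetic term %d", i),
         source = src,
         genes = sort(sample(genes, sz)))
  })
  structure(terms, class = "term_set")
}
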