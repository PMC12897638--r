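#' Write / read feature annotation files
#'
#' Two on-disk forms are supported:
#' * GFF3 (1-based inclusive), via rtracklayer, with the feature kind as
#'   the `type` column and `gene` / `transcript_id` attributes;
#' * a BED6-plus dialect (0-based half-open) with the feature kind in
#'   column 7 and the gene symbol in column 8.
#'
#' Both round-trip to the same in-memory `feature_set` (1-based inclusive
#' coordinates).
#'
#' @param features A `feature_set` data.frame (see
#'   [gen_feature_annotation()]).
#' @param path File path.
#' @return The path (writers, invisibly) or a `feature_set` (readers).
#' @export
write_features_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand,
    type = features$kind,
    source = "twinmeth",
    gene = features$gene_symbol,
    transcript_id = features$transcript_accession)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_features_gff3
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  fs <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = as.character(md$type),
    gene_symbol = if ("gene" %in% names(md)) as.character(md$gene) else NA_character_,
    transcript_accession = if ("transcript_id" %in% names(md))
      as.character(md$transcript_id) else NA_character_,
    stringsAsFactors = FALSE)
  as_feature_set(fs)
}

#' @rdname write_features_gff3
#' @export
write_features_bed <- function(features, path) {
  df <- data.frame(features$chrom, features$start - 1L, features$end,
                   ifelse(is.na(features$transcript_accession), ".",
                          features$transcript_accession),
                   0L, features$strand, features$kind,
                   ifelse(is.na(features$gene_symbol), ".",
                          features$gene_symbol))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_features_gff3
#' @export
read_features_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 7) stop2("BED feature file needs >= 7 columns (kind in 7)")
  fs <- data.frame(
    chrom = df[[1]], start = df[[2]] + 1L, end = df[[3]],
    strand = df[[6]], kind = df[[7]],
    gene_symbol = if (ncol(df) >= 8) ifelse(df[[8]] == ".", NA, df[[8]])
      else NA_character_,
    transcript_accession = ifelse(df[[4]] == ".", NA, df[[4]]),
    stringsAsFactors = FALSE)
  as_feature_set(fs)
}

as_feature_set <- function(fs) {
  fs <- fs[order(fs$chrom, fs$start, fs$end, fs$kind), , drop = FALSE]
  rownames(fs) <- NULL
  gm <- unique(fs[!is.na(fs$transcript_accession),
                  c("transcript_accession", "gene_symbol")])
  names(gm) <- c("accession", "symbol")
  rownames(gm) <- NULL
  structure(fs, gene_map = gm, class = c("feature_set", "data.frame"))
}

#' Read a transcript-accession to gene-symbol mapping TSV
#'
#' Two columns, `accession` and `symbol`, with a header. Used when
#' annotation carries transcript accessions only.
#'
#' @param path File path.
#' @return data.frame with columns `accession`, `symbol`.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("accession", "symbol") %in% names(df)))
    stop2("gene map needs columns 'accession' and 'symbol'")
  df
}
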