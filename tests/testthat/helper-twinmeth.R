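`%||%` <- function(a, b) if (is.null(a)) b else a

site_key <- function(df) paste(df$chrom, df$pos, sep = ":")

# small, fast configuration for structural tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cpgs = 1500L, chrom_length = 1e5, n_genes = 6L,
                   n_islands = 3L, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# build a count matrix directly from per-group depth/meth specifications:
# meth/total are lists of per-sample vectors (one value per site)
make_cm <- function(total_con, meth_con, total_res, meth_res,
                    chrom = "chr1", pos = NULL) {
  n <- length(total_con[[1]])
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  np <- length(total_con)
  sheet <- data.frame(sample = c(paste0("CON", 1:np), paste0("RES", 1:np)),
                      group = rep(c("CON", "RES"), each = np),
                      pair = rep(1:np, 2))
  total <- cbind(do.call(cbind, total_con), do.call(cbind, total_res))
  meth <- cbind(do.call(cbind, meth_con), do.call(cbind, meth_res))
  colnames(total) <- colnames(meth) <- sheet$sample
  count_matrix(data.frame(chrom = chrom, pos = pos), meth, total, sheet)
}

# naive all-pairs overlap annotation oracle (1-based inclusive intervals)
naive_annotate <- function(sites, features) {
  lab <- lapply(seq_len(nrow(sites)), function(i) {
    hit <- features$chrom == sites$chrom[i] &
      features$start <= sites$pos[i] & features$end >= sites$pos[i]
    kinds <- unique(features$kind[hit])
    out <- intersect(c("promoter", "exon", "intron", "cpg_island"), kinds)
    if (any(kinds %in% c("exon", "intron"))) out <- c(out, "genic")
    if (!any(kinds %in% c("gene_body", "promoter"))) out <- c(out, "intergenic")
    sort(out)
  })
  lab
}

# brute-force BH: for each p_i take the best achievable step-up bound
naive_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(p[p >= pi], function(t) m * t / sum(p <= t), numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# exhaustive hypergeometric upper tail by enumerating query draws
naive_hyper <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # first K elements are the term
  mean(hits >= x)
}
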