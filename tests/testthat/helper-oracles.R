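# Independent brute-force oracles used to validate the implementation.

# regex-based G-tract scan over an intron-only window (positions -L..-1);
# maximal runs fully inside [search_from, search_to]
oracle_g_tracts <- function(window, min_len = 3, search_from = -15,
                            search_to = -3) {
  L <- nchar(window)
  m <- gregexpr("G+", toupper(window))[[1]]
  if (m[1] == -1) {
    return(data.frame(first_g = integer(), length = integer()))
  }
  first <- as.integer(m) - L - 1L          # string index -> position
  len <- attr(m, "match.length")
  last <- first + len - 1L
  keep <- len >= min_len & first >= max(search_from, -L) & last <= search_to
  data.frame(first_g = first[keep], length = len[keep])
}

# hypergeometric upper tail by explicit enumeration of all C(N, n) draws
oracle_hyper_enum <- function(k, K, n, N) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(matrix(pop[draws], nrow = n)) >= k)
}

# exact two-sided permutation p-value for the two-sample t statistic
oracle_perm_t <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  splits <- utils::combn(length(pool), nx)
  tstat <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }
  t_obs <- tstat(x, y)
  t_all <- apply(splits, 2, function(idx) {
    tstat(pool[idx], pool[-idx])
  })
  list(t_obs = t_obs, p = mean(abs(t_all) >= abs(t_obs) - 1e-12),
       t_all = t_all)
}

# build a tiny GTF file from an exon table
write_test_gtf <- function(df, path = tempfile(fileext = ".gtf")) {
  write_gtf(df, path)
  path
}

exon_df <- function(tx, gene, chrom, strand, starts, ends) {
  data.frame(transcript_id = tx, gene_id = gene, chrom = chrom,
             strand = strand, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

# annotation + windows + calls for a cached synthetic genome
sim_bundle <- function(seed = 11, n_genes = 40, ...) {
  cfg <- repa_sim_config(seed = seed, n_genes = n_genes, ...)
  sim <- generate_genome(cfg)
  introns <- derive_introns(sim$annotation)
  windows <- extract_windows(sim$genome, introns,
                             cfg$intron_span, cfg$exon_span)
  list(cfg = cfg, sim = sim, introns = introns, windows = windows)
}
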