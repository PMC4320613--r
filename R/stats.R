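# Enrichment statistics: upper-tail hypergeometric tests (positional purine
# enrichment, alternative-splicing abundance) and right-tailed Fisher
# gene-set enrichment with random-query backgrounds.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Drawing `n` items without replacement from a population of `N` containing
#' `K` successes, the probability of observing at least `k` successes.
#' Computed by exact summation of log-space terms, so extreme tails do not
#' underflow to 0 down to the smallest representable double; values below
#' 1e-300 carry an `underflow_risk` attribute instead of being printed as 0.
#'
#' @param k Observed successes (0 <= k <= min(K, n)).
#' @param K Population successes.
#' @param n Number of draws.
#' @param N Population size.
#' @return The p-value in (0, 1]; `P(X >= 0) = 1`.
#' @export
#' @examples
#' hypergeom_upper(3, 5, 4, 10)  # 55/210
hypergeom_upper <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L,
            length(N) == 1L)
  if (is.na(k) || is.na(K) || is.na(n) || is.na(N)) {
    return(NA_real_)
  }
  if (N < 0 || K < 0 || K > N || n < 0 || n > N) {
    stop("invalid hypergeometric bounds (need 0 <= K <= N, 0 <= n <= N)")
  }
  if (k > min(K, n)) stop("k exceeds min(K, n)")
  kmin <- max(0, n - (N - K))   # lower support bound
  if (k <= kmin) return(1)
  terms <- stats::dhyper(seq.int(k, min(K, n)), K, N - K, n, log = TRUE)
  p <- min(exp(logsumexp(terms)), 1)
  if (p < 1e-300) attr(p, "underflow_risk") <- TRUE
  p
}

#' Per-position purine enrichment of one profile over another
#'
#' At each position, an upper-tail hypergeometric test of the query's purine
#' count within the pooled (query + background) population: the population
#' is all informative bases at that position across both sets, successes are
#' purines, draws are the query's bases.
#'
#' @param profile_query,profile_background `position_profile` objects over
#'   the same positions (counts, not just frequencies, are required).
#' @return Data frame `position`, `k` (query purines), `n` (query size),
#'   `K` (pooled purines), `N` (pooled size), `p`.
#' @export
positional_purine_test <- function(profile_query, profile_background) {
  if (!identical(profile_query$positions, profile_background$positions)) {
    stop("profiles must cover the same positions")
  }
  pos <- profile_query$positions
  purines <- c("A", "G")
  kq <- colSums(profile_query$counts[purines, , drop = FALSE])
  kb <- colSums(profile_background$counts[purines, , drop = FALSE])
  nq <- profile_query$n_counts
  nb <- profile_background$n_counts
  p <- vapply(seq_along(pos), function(j) {
    hypergeom_upper(kq[j], kq[j] + kb[j], nq[j], nq[j] + nb[j])
  }, 0)
  data.frame(position = pos, k = as.integer(kq), n = as.integer(nq),
             K = as.integer(kq + kb), N = as.integer(nq + nb), p = p)
}

#' Alternative-splicing abundance of a site group, normalized and tested
#'
#' Normalized abundance is the group's alternative fraction divided by the
#' baseline (whole-population or random-exon) alternative fraction, so the
#' baseline group itself scores 1; significance is an upper-tail
#' hypergeometric test of the group's alternative count within the
#' population.
#'
#' @param group_alt_count,group_size Alternative sites and total sites in
#'   the group.
#' @param population_alt_count,population_size Same for the baseline
#'   population.
#' @return List with `abundance`, `group_fraction`, `baseline_fraction`,
#'   `p`.
#' @export
as_abundance_test <- function(group_alt_count, group_size,
                              population_alt_count, population_size) {
  stopifnot(group_alt_count <= group_size,
            population_alt_count <= population_size,
            group_size <= population_size)
  baseline <- population_alt_count / population_size
  if (baseline == 0) stop("baseline alternative fraction is zero")
  gf <- group_alt_count / group_size
  list(abundance = gf / baseline,
       group_fraction = gf,
       baseline_fraction = baseline,
       p = hypergeom_upper(group_alt_count, population_alt_count,
                           group_size, population_size))
}

#' Right-tailed Fisher gene-set enrichment
#'
#' For each gene set, the right-tailed Fisher exact test of the overlap with
#' the query within the universe (identical to the upper-tail
#' hypergeometric on the corresponding 2x2 table). Optionally also
#' evaluates `n_random` random query sets of matched (or given) size, the
#' background bars against which the real query's `-log10(p)` is compared.
#' No multiple-testing correction is applied by default; set
#' `adjust = TRUE` for Benjamini-Hochberg.
#'
#' @param query_genes Character vector of query gene ids (must lie in
#'   `universe`).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); genes outside the universe are ignored.
#' @param universe Character vector of all eligible gene ids.
#' @param n_random Number of random query sets to evaluate (default 0).
#' @param random_size Size of each random query (default: size of the real
#'   query).
#' @param adjust Add a Benjamini-Hochberg adjusted column (default FALSE).
#' @return List of class `gene_set_enrichment`: `results` (data frame
#'   `set_name`, `set_size`, `overlap`, `p`, `minus_log10_p`, sorted by p)
#'   and `random` (long data frame of random-query p-values, or NULL).
#' @export
gene_set_enrichment <- function(query_genes, gene_sets, universe,
                                n_random = 0L, random_size = NULL,
                                adjust = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe)) {
    stop("query genes must be a subset of the universe")
  }
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  one <- function(q) {
    vapply(sets, function(s) {
      hypergeom_upper(length(intersect(q, s)), length(s), length(q),
                      length(universe))
    }, 0)
  }
  p <- one(query_genes)
  res <- data.frame(set_name = names(sets),
                    set_size = lengths(sets),
                    overlap = vapply(sets, function(s) {
                      length(intersect(query_genes, s))
                    }, 0L),
                    p = unname(p),
                    minus_log10_p = unname(-log10(p)),
                    stringsAsFactors = FALSE)
  if (adjust) res$p_bh <- stats::p.adjust(res$p, "BH")
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  random <- NULL
  if (n_random > 0L) {
    if (is.null(random_size)) random_size <- length(query_genes)
    random <- do.call(rbind, lapply(seq_len(n_random), function(r) {
      q <- sample(universe, random_size)
      data.frame(replicate = r, set_name = names(sets),
                 p = unname(one(q)), stringsAsFactors = FALSE)
    }))
    random$minus_log10_p <- -log10(random$p)
    rownames(random) <- NULL
  }
  structure(list(results = res, random = random,
                 n_query = length(query_genes),
                 n_universe = length(universe)),
            class = "gene_set_enrichment")
}

#' @export
print.gene_set_enrichment <- function(x, ...) {
  cat("gene_set_enrichment:", x$n_query, "query genes in a universe of",
      x$n_universe, "\n")
  print(utils::head(x$results, 10))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1)
  sets
}
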