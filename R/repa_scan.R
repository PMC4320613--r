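# Core acceptor scan: purine content, REPA calls, G tracts, hexamer groups,
# positional profiles.

REPA_GROUP_LABELS <- c("gtggaa", "aaataa", "ggggg", "ggaaa", "gaaaa")

#' Fraction of purines (A/G) in a window position range
#'
#' N bases are removed from the denominator; a range that is all N returns
#' `NA`. Positions are intron-relative (see [intron_positions()]); the
#' default range -10..-3 is the interval the REPA definition tests.
#'
#' @param window Character vector of acceptor windows (uppercase or lower).
#' @param from,to Intron-relative position range (5' to 3').
#' @param exon_span Number of exonic bases at the 3' end of `window`
#'   (default 0: intron-only windows).
#' @return Numeric vector of purine fractions in `[0, 1]` (or `NA`).
#' @export
#' @examples
#' purine_fraction("GTCTTGGGGGTTTAG")   # 5/8
purine_fraction <- function(window, from = -10L, to = -3L, exon_span = 0L) {
  if (from > to) stop("`from` must be 5' of `to`")
  b <- window_bases(window, from, to, exon_span)
  pur <- rowSums(b == "A" | b == "G")
  informative <- rowSums(b != "N")
  ifelse(informative == 0L, NA_real_, pur / informative)
}

#' Is an acceptor a purine-rich (REPA) candidate?
#'
#' `TRUE` iff the acceptor dinucleotide (positions -2..-1) is `AG` and the
#' purine fraction over -10..-3 strictly exceeds `threshold` (with 8
#' informative positions, >0.60 means at least 5 purines; exactly 4/8
#' fails). Truncated windows that do not cover -10..-1 return `FALSE` and
#' are flagged in the `truncated` attribute.
#'
#' @inheritParams purine_fraction
#' @param threshold Strict lower bound on the purine fraction (default 0.60).
#' @param truncated Optional logical vector flagging windows that do not
#'   cover the full range.
#' @return Logical vector; attribute `truncated` marks sites decided by
#'   truncation rather than composition.
#' @export
is_repa_candidate <- function(window, threshold = 0.60, exon_span = 0L,
                              truncated = NULL) {
  intron_span <- nchar(window) - exon_span
  short <- intron_span < 10L
  if (!is.null(truncated)) short <- short | truncated
  out <- logical(length(window))
  if (any(!short)) {
    w <- window[!short]
    ag <- window_bases(w, -2L, -1L, exon_span)
    is_ag <- ag[, 1] == "A" & ag[, 2] == "G"
    pf <- purine_fraction(w, -10L, -3L, exon_span)
    out[!short] <- is_ag & !is.na(pf) & pf > threshold
  }
  structure(out, truncated = short)
}

#' Find maximal G tracts in an acceptor window
#'
#' Reports maximal runs of G (no sub-runs) of length at least `min_len`
#' lying entirely within `search_from..search_to` of the intron end; runs
#' may not invade the acceptor AG (they must end at or 5' of -3). Runs
#' longer than `max_len` are reported with their true length and flagged
#' `over_cap`.
#'
#' @inheritParams purine_fraction
#' @param min_len,max_len Reported run-length range (defaults 3 and 8).
#' @param search_from,search_to Intron-relative search interval (defaults
#'   -15..-3). Clipped to the window's intronic extent.
#' @return For a single window, a data frame with columns `first_g`
#'   (intron-relative position of the 5'-most G), `length`, `over_cap`,
#'   sorted 5' to 3'; zero rows when there is no tract.
#' @export
#' @examples
#' find_g_tracts("GTCTTGGGGGTTTAG")   # one G5 starting at -10
find_g_tracts <- function(window, min_len = 3L, max_len = 8L,
                          search_from = -15L, search_to = -3L,
                          exon_span = 0L) {
  stopifnot(length(window) == 1L)
  intron_span <- nchar(window) - exon_span
  from <- max(search_from, -intron_span)
  if (from > search_to) {
    return(data.frame(first_g = integer(), length = integer(),
                      over_cap = logical()))
  }
  b <- as.vector(window_bases(window, from, search_to, exon_span))
  pos <- seq.int(from, search_to)  # all negative, no zero crossing
  r <- rle(b == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gi <- which(r$values & r$lengths >= min_len)
  # maximality beyond the clipped 5' edge: a run starting at the very first
  # searched base may continue 5' of `search_from`; such a run's true first
  # G is outside the search interval, so it is not reported.
  if (length(gi) && -intron_span < search_from) {
    full <- window_bases(window, -intron_span, search_to, exon_span)
    lead <- as.vector(full)[seq_len(from - (-intron_span))]
    if (length(lead) && lead[length(lead)] == "G") {
      gi <- gi[starts[gi] != 1L]
    }
  }
  # maximality at the 3' edge: a run continuing past `search_to` (toward or
  # into the acceptor AG) does not end at or 5' of -3, so it is not a tract.
  if (length(gi) && search_to < -1L) {
    nxt <- as.vector(window_bases(window, search_to + 1L, search_to + 1L,
                                  exon_span))
    if (nxt == "G") gi <- gi[ends[gi] != length(b)]
  }
  if (!length(gi)) {
    return(data.frame(first_g = integer(), length = integer(),
                      over_cap = logical()))
  }
  data.frame(first_g = pos[starts[gi]],
             length = r$lengths[gi],
             over_cap = r$lengths[gi] > max_len)
}

#' Classify an acceptor window into a hexamer/pentamer group
#'
#' Literal motif match anywhere within -12..-3, resolved by a fixed
#' precedence order (`labels`, first match wins; longer motifs are listed
#' first by default). When no motif matches but the -3 base is a purine, the
#' site is labelled `nnnrag_like` (purine at the consensus Y position);
#' otherwise `other`.
#'
#' @inheritParams purine_fraction
#' @param labels Character vector of motifs in precedence order.
#' @return Character vector of group labels.
#' @export
classify_group <- function(window, labels = REPA_GROUP_LABELS,
                           exon_span = 0L) {
  labels_uc <- toupper(labels)
  region <- apply(window_bases(window, -12L, -3L, exon_span), 1, paste,
                  collapse = "")
  minus3 <- as.vector(window_bases(window, -3L, -3L, exon_span))
  out <- rep("other", length(window))
  out[minus3 %in% c("A", "G")] <- "nnnrag_like"
  for (k in rev(seq_along(labels_uc))) {  # earlier labels overwrite later
    hit <- grepl(labels_uc[k], region, fixed = TRUE)
    out[hit] <- labels[k]
  }
  out
}

#' Scan acceptor windows for purine-rich (REPA) sites and G tracts
#'
#' The per-site call table of the pipeline: purine fraction over -10..-3,
#' the strict >`threshold` REPA call (AG acceptors only), the hexamer group
#' label, and one representative G tract per site (the 5'-most; ties by
#' longest, then most 3', cannot occur for maximal runs at distinct
#' positions but the rule is fixed).
#'
#' @param windows An `acceptor_windows` data frame (or character vector of
#'   same-length windows, `exon_span` taken as 0).
#' @inheritParams is_repa_candidate
#' @inheritParams find_g_tracts
#' @return Data frame of class `repa_calls`: `site_id`, `window`,
#'   `purine_fraction_10_3`, `is_repa`, `group_label`, `n_tracts`,
#'   `first_g`, `tract_length`, `over_cap`, `truncated`.
#' @export
scan_sites <- function(windows, threshold = 0.60, min_len = 3L, max_len = 8L,
                       search_from = -15L, search_to = -3L,
                       group_labels = REPA_GROUP_LABELS) {
  w <- as_window_df(windows)
  exon_span <- attr(w, "exon_span") %||% 0L
  n <- nrow(w)
  full <- !w$truncated
  pf <- rep(NA_real_, n); repa <- logical(n)
  grp <- rep(NA_character_, n)
  n_tr <- integer(n); fg <- rep(NA_integer_, n)
  tl <- rep(NA_integer_, n); oc <- rep(NA, n)
  if (any(full)) {
    pf[full] <- purine_fraction(w$window[full], -10L, -3L, exon_span)
    repa[full] <- as.vector(is_repa_candidate(w$window[full], threshold,
                                              exon_span))
    grp[full] <- classify_group(w$window[full], group_labels, exon_span)
  }
  for (i in which(full)) {
    tr <- find_g_tracts(w$window[i], min_len, max_len, search_from,
                        search_to, exon_span)
    n_tr[i] <- nrow(tr)
    if (nrow(tr)) {
      tr <- tr[order(tr$first_g, -tr$length), , drop = FALSE]
      fg[i] <- tr$first_g[1]; tl[i] <- tr$length[1]; oc[i] <- tr$over_cap[1]
    }
  }
  out <- data.frame(site_id = w$site_id, window = w$window,
                    purine_fraction_10_3 = pf, is_repa = repa,
                    group_label = grp, n_tracts = n_tr, first_g = fg,
                    tract_length = tl, over_cap = oc,
                    truncated = w$truncated, stringsAsFactors = FALSE)
  structure(out, threshold = threshold,
            class = c("repa_calls", "data.frame"))
}

#' All G tracts per site
#'
#' Unlike [scan_sites()], which keeps one representative tract per site,
#' this returns every maximal tract.
#'
#' @inheritParams scan_sites
#' @return Data frame `site_id`, `first_g`, `length`, `over_cap`.
#' @export
site_g_tracts <- function(windows, min_len = 3L, max_len = 8L,
                          search_from = -15L, search_to = -3L) {
  w <- as_window_df(windows)
  exon_span <- attr(w, "exon_span") %||% 0L
  res <- lapply(which(!w$truncated), function(i) {
    tr <- find_g_tracts(w$window[i], min_len, max_len, search_from,
                        search_to, exon_span)
    if (nrow(tr)) cbind(site_id = w$site_id[i], tr) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(site_id = character(), first_g = integer(),
                      length = integer(), over_cap = logical())
  }
  rownames(out) <- NULL
  out
}

#' Per-position nucleotide frequencies over a set of windows
#'
#' Frequencies at each intron-relative position, with N bases excluded from
#' the denominators, plus the A/G (purine) marginal used for positional
#' enrichment plots and tests. All windows must share the same span;
#' truncated windows must be excluded by the caller.
#'
#' @inheritParams purine_fraction
#' @param windows Character vector of equal-length windows, or an
#'   `acceptor_windows` data frame (truncated rows dropped with a message).
#' @return Object of class `position_profile`: list with `positions`,
#'   `counts` (4 x P matrix, rows A/C/G/T), `n_counts` (informative
#'   denominators), `n_n` (N counts), `freq`, `purine_freq`, `n_sites`.
#' @export
position_profile <- function(windows, exon_span = NULL) {
  w <- as_window_df(windows)
  if (any(w$truncated)) {
    message(sum(w$truncated), " truncated window(s) excluded from profile")
    w <- w[!w$truncated, , drop = FALSE]
  }
  if (nrow(w) == 0L) stop("no full-length windows to profile")
  if (is.null(exon_span)) exon_span <- attr(w, "exon_span") %||% 0L
  L <- unique(nchar(w$window))
  if (length(L) != 1L) stop("windows must share a common span")
  intron_span <- L - exon_span
  pos <- intron_positions(intron_span, exon_span)
  b <- window_bases(w$window, -intron_span,
                    if (exon_span > 0) exon_span else -1L, exon_span)
  counts <- sapply(seq_along(pos), function(j) {
    c(A = sum(b[, j] == "A"), C = sum(b[, j] == "C"),
      G = sum(b[, j] == "G"), T = sum(b[, j] == "T"))
  })
  colnames(counts) <- pos
  n_n <- nrow(w) - colSums(counts)
  n_counts <- colSums(counts)
  freq <- sweep(counts, 2, pmax(n_counts, 1L), "/")
  freq[, n_counts == 0L] <- NA_real_
  structure(list(positions = pos, counts = counts, n_counts = n_counts,
                 n_n = n_n, freq = freq,
                 purine_freq = freq["A", ] + freq["G", ],
                 n_sites = nrow(w)),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat("position_profile over", x$n_sites, "sites,",
      length(x$positions), "positions\n")
  cat("A/G fraction by position:\n")
  print(round(x$purine_freq, 3))
  invisible(x)
}

#' @export
plot.position_profile <- function(x, ..., col = "black") {
  graphics::plot(seq_along(x$positions), 100 * x$purine_freq, type = "b",
                 xaxt = "n", xlab = "position", ylab = "% A/G",
                 ylim = c(0, 100), col = col, ...)
  graphics::axis(1, at = seq_along(x$positions), labels = x$positions)
  invisible(x)
}

#' Distribution of first-G positions / run lengths over sites
#'
#' One count per site, using the site's representative tract (5'-most, ties
#' by longest) as computed by [scan_sites()]. Sites without a tract do not
#' contribute; the histogram total equals the number of contributing sites.
#'
#' @param calls A `repa_calls` data frame.
#' @param positions Optional integer positions to tabulate over (zeros
#'   filled); default spans the observed range.
#' @return Named integer vector of counts.
#' @export
first_g_histogram <- function(calls, positions = NULL) {
  fg <- calls$first_g[!is.na(calls$first_g)]
  if (is.null(positions)) {
    positions <- if (length(fg)) seq(min(fg), max(fg)) else integer(0)
  }
  tab <- table(factor(fg, levels = positions))
  stats::setNames(as.integer(tab), names(tab))
}

#' @rdname first_g_histogram
#' @param lengths Optional run lengths to tabulate over.
#' @export
run_length_distribution <- function(calls, lengths = NULL) {
  tl <- calls$tract_length[!is.na(calls$tract_length)]
  if (is.null(lengths)) {
    lengths <- if (length(tl)) seq(min(tl), max(tl)) else integer(0)
  }
  tab <- table(factor(tl, levels = lengths))
  stats::setNames(as.integer(tab), names(tab))
}

# accept either an acceptor_windows df or a bare character vector
as_window_df <- function(windows) {
  if (is.character(windows)) {
    structure(data.frame(site_id = paste0("w", seq_along(windows)),
                         window = toupper(windows),
                         truncated = FALSE, stringsAsFactors = FALSE),
              exon_span = 0L)
  } else {
    windows$window <- toupper(windows$window)
    if (is.null(windows$truncated)) windows$truncated <- FALSE
    windows
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
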