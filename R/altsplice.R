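# Alternative-splicing event classification from multi-transcript
# annotation: pairwise transcript comparison within each gene.
#
# Definitions (pair A, B of transcripts of one gene):
#   cassette_exon   an internal exon of one transcript absent from the other
#                   while both flanking splice junctions are shared
#   alt_3ss         two introns sharing a donor but differing at the
#                   acceptor, with no complete exon of either transcript
#                   between the two acceptors (which would make it a
#                   skipping junction instead)
#   alt_5ss         shared acceptor, differing donors, same exclusion
#   retained_intron an intron of one transcript fully contained within a
#                   single exon of the other
# Precedence when one genomic region satisfies several definitions:
# retained_intron > alt_3ss > alt_5ss > cassette_exon.

AS_EVENT_TYPES <- c("cassette_exon", "alt_3ss", "alt_5ss", "retained_intron")
AS_PRECEDENCE <- c(retained_intron = 1L, alt_3ss = 2L, alt_5ss = 3L,
                   cassette_exon = 4L)

#' Detect alternative-splicing events from transcript models
#'
#' Pairwise comparison of the transcripts of each multi-isoform gene, with
#' events deduplicated across pairs and overlapping definitions resolved by
#' a fixed precedence (retained_intron > alt_3ss > alt_5ss > cassette_exon;
#' superseded events are counted in the `n_superseded` attribute). Detection
#' is symmetric in transcript order.
#'
#' @param models A `transcript_models` data frame.
#' @return Data frame of class `as_events`: `gene_id`, `event_type`,
#'   `chrom`, `strand`, `start`, `end` (genomic interval of the event),
#'   `acceptors` (comma-separated genomic acceptor coordinates implicated),
#'   `transcript_1`, `transcript_2` (witness pair).
#' @export
detect_as_events <- function(models) {
  df <- as.data.frame(models)
  res <- list()
  for (g in unique(df$gene_id)) {
    gdf <- df[df$gene_id == g, , drop = FALSE]
    txs <- sort(unique(gdf$transcript_id))
    if (length(txs) < 2L) next
    exons <- lapply(txs, function(t) {
      e <- gdf[gdf$transcript_id == t, c("start", "end"), drop = FALSE]
      e[order(e$start), , drop = FALSE]
    })
    names(exons) <- txs
    chrom <- gdf$chrom[1]; strand <- gdf$strand[1]
    for (i in seq_len(length(txs) - 1L)) for (j in (i + 1L):length(txs)) {
      ev <- pair_events(exons[[i]], exons[[j]], strand)
      if (nrow(ev)) {
        ev$gene_id <- g; ev$chrom <- chrom; ev$strand <- strand
        ev$transcript_1 <- txs[i]; ev$transcript_2 <- txs[j]
        res[[length(res) + 1L]] <- ev
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(event_type = character(), start = integer(),
               end = integer(), acceptors = character(),
               gene_id = character(), chrom = character(),
               strand = character(), transcript_1 = character(),
               transcript_2 = character(), stringsAsFactors = FALSE)
  # dedup identical events found in several transcript pairs
  key <- paste(out$chrom, out$strand, out$event_type, out$start, out$end)
  out <- out[!duplicated(key), , drop = FALSE]
  # precedence for one region matching several definitions
  rkey <- paste(out$chrom, out$strand, out$start, out$end)
  ord <- order(rkey, AS_PRECEDENCE[out$event_type])
  out <- out[ord, , drop = FALSE]
  drop <- duplicated(paste(out$chrom, out$strand, out$start, out$end))
  n_superseded <- sum(drop)
  out <- out[!drop, , drop = FALSE]
  out <- out[order(out$gene_id, out$start, out$end), ,
             drop = FALSE]
  out <- out[, c("gene_id", "event_type", "chrom", "strand", "start",
                 "end", "acceptors", "transcript_1", "transcript_2")]
  rownames(out) <- NULL
  structure(out, n_superseded = n_superseded,
            class = c("as_events", "data.frame"))
}

# events for one ordered transcript pair; exA/exB are genomic-sorted exon
# tables. Symmetric: directional checks run both ways.
pair_events <- function(exA, exB, strand) {
  intr <- function(ex) {
    n <- nrow(ex)
    if (n < 2L) {
      return(data.frame(start = integer(), end = integer()))
    }
    s <- ex$end[-n] + 1L; e <- ex$start[-1] - 1L
    keep <- e >= s
    data.frame(start = s[keep], end = e[keep])
  }
  inA <- intr(exA); inB <- intr(exB)
  donor <- function(x) if (strand == "+") x$start else x$end
  acceptor <- function(x) if (strand == "+") x$end else x$start
  all_ex <- rbind(exA, exB)
  # is any complete exon (of either transcript) strictly inside (lo, hi)?
  exon_between <- function(lo, hi) {
    any(all_ex$start > lo & all_ex$end < hi)
  }
  rows <- list()
  add <- function(type, start, end, accs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      event_type = type, start = start, end = end,
      acceptors = paste(sort(unique(accs)), collapse = ","),
      stringsAsFactors = FALSE)
  }

  if (nrow(inA) && nrow(inB)) {
    dA <- donor(inA); aA <- acceptor(inA)
    dB <- donor(inB); aB <- acceptor(inB)
    for (p in seq_along(dA)) for (q in seq_along(dB)) {
      if (inA$start[p] == inB$start[q] && inA$end[p] == inB$end[q]) next
      if (dA[p] == dB[q] && aA[p] != aB[q]) {
        lo <- min(aA[p], aB[q]); hi <- max(aA[p], aB[q])
        if (!exon_between(lo, hi)) {
          add("alt_3ss", lo, hi, c(aA[p], aB[q]))
        }
      }
      if (aA[p] == aB[q] && dA[p] != dB[q]) {
        lo <- min(dA[p], dB[q]); hi <- max(dA[p], dB[q])
        if (!exon_between(lo, hi)) {
          add("alt_5ss", lo, hi, aA[p])
        }
      }
    }
  }

  cassette_dir <- function(exS, exO) {
    n <- nrow(exS)
    if (n < 3L) return()
    for (k in 2:(n - 1L)) {
      overl <- any(exO$end >= exS$start[k] & exO$start <= exS$end[k])
      if (overl) next
      m <- nrow(exO)
      if (m < 2L) next
      junction <- any(exO$end[-m] == exS$end[k - 1L] &
                        exO$start[-1] == exS$start[k + 1L])
      if (junction) {
        acc <- if (strand == "+") exS$start[k] - 1L else exS$end[k] + 1L
        add("cassette_exon", exS$start[k], exS$end[k], acc)
      }
    }
  }
  cassette_dir(exA, exB)
  cassette_dir(exB, exA)

  retained_dir <- function(inS, exO) {
    if (!nrow(inS)) return()
    for (k in seq_len(nrow(inS))) {
      inside <- any(exO$start <= inS$start[k] - 1L &
                      exO$end >= inS$end[k] + 1L)
      if (inside) {
        acc <- if (strand == "+") inS$end[k] else inS$start[k]
        add("retained_intron", inS$start[k], inS$end[k], acc)
      }
    }
  }
  retained_dir(inA, exB)
  retained_dir(inB, exA)

  if (length(rows)) do.call(rbind, rows) else
    data.frame(event_type = character(), start = integer(),
               end = integer(), acceptors = character(),
               stringsAsFactors = FALSE)
}

#' Annotate acceptor sites with alternative-splicing status
#'
#' A site is alternative iff at least one event's defining acceptor equals
#' the site's acceptor coordinate, or the event interval covers it (same
#' chrom and strand). Multi-type sites carry all types.
#'
#' @param events An `as_events` data frame.
#' @param sites An `acceptor_windows`/`repa_calls`-like data frame with
#'   `site_id` and either (`chrom`, `strand`, `acceptor`) columns or
#'   `chrom:strand:acceptor`-formatted site ids.
#' @return Data frame `site_id`, `is_alternative`, `event_types`
#'   (comma-separated, `""` when none).
#' @export
associate_sites <- function(events, sites) {
  s <- as.data.frame(sites)
  if (!all(c("chrom", "strand", "acceptor") %in% names(s))) {
    parts <- strsplit(s$site_id, ":", fixed = TRUE)
    s$chrom <- vapply(parts, `[`, "", 1)
    s$strand <- vapply(parts, `[`, "", 2)
    s$acceptor <- as.integer(vapply(parts, `[`, "", 3))
  }
  ev_acc <- lapply(strsplit(events$acceptors, ",", fixed = TRUE),
                   as.integer)
  is_alt <- logical(nrow(s)); types <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    same <- events$chrom == s$chrom[i] & events$strand == s$strand[i]
    if (!any(same)) next
    hit <- same & (vapply(ev_acc, function(a) s$acceptor[i] %in% a,
                          logical(1)) |
                     (events$start <= s$acceptor[i] &
                        events$end >= s$acceptor[i]))
    if (any(hit)) {
      is_alt[i] <- TRUE
      types[i] <- paste(sort(unique(events$event_type[hit])),
                        collapse = ",")
    }
  }
  data.frame(site_id = s$site_id, is_alternative = is_alt,
             event_types = types, stringsAsFactors = FALSE)
}

#' Distribution of alternative-splicing event types, with fold enrichment
#'
#' Proportions of each event type among associated sites (multi-type sites
#' contribute one count per type), and fold enrichment over optional
#' reference proportions (e.g. transcriptome-wide survey proportions
#' supplied as configuration). Folds are only defined where the reference
#' proportion is positive; without a reference, proportions alone are
#' returned.
#'
#' @param associated_sites Output of [associate_sites()] (or any data frame
#'   with an `event_types` column).
#' @param reference_proportions Optional named numeric vector of reference
#'   proportions by event type.
#' @return Data frame of class `as_type_distribution`: `event_type`,
#'   `count`, `proportion`, `reference`, `fold_enrichment`.
#' @export
type_distribution <- function(associated_sites,
                              reference_proportions = NULL) {
  et <- associated_sites$event_types
  et <- et[!is.na(et) & nzchar(et)]
  if (!length(et)) stop("no associated sites")
  occ <- unlist(strsplit(et, ",", fixed = TRUE))
  lev <- union(AS_EVENT_TYPES, unique(occ))
  cnt <- table(factor(occ, levels = lev))
  out <- data.frame(event_type = lev, count = as.integer(cnt),
                    proportion = as.numeric(cnt) / sum(cnt),
                    stringsAsFactors = FALSE)
  if (!is.null(reference_proportions)) {
    out$reference <- unname(reference_proportions[out$event_type])
    out$fold_enrichment <- ifelse(
      !is.na(out$reference) & out$reference > 0,
      out$proportion / out$reference, NA_real_)
  } else {
    out$reference <- NA_real_
    out$fold_enrichment <- NA_real_
  }
  structure(out, class = c("as_type_distribution", "data.frame"))
}
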