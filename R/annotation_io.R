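# Genome + annotation input, intron derivation, acceptor-window extraction,
# and BED/TSV output.

#' Parse a GTF or GFF3 annotation into transcript models
#'
#' Reads exon features and returns one record per exon, grouped by transcript,
#' with exons ranked in transcription order (descending genomic coordinate on
#' the minus strand). The dialect (GTF vs GFF3) is auto-detected from the
#' attribute-column syntax. Records with `end < start` are rejected and
#' counted; transcripts without a usable strand are dropped with a warning.
#'
#' @param path Path to a GTF2.2 or GFF3 file.
#' @return A data frame of class `transcript_models` with columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `exon_rank`; attributes `n_rejected` (malformed coordinate records) and
#'   `n_unstranded` (transcripts dropped for strand `*` or `.`).
#' @export
parse_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  fmt <- detect_annotation_dialect(path)

  raw <- readLines(path, warn = FALSE)
  body <- raw[!startsWith(raw, "#") & nzchar(trimws(raw))]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok_len <- lengths(fields) >= 9L
  st <- suppressWarnings(as.numeric(vapply(fields, function(f) f[4], "")))
  en <- suppressWarnings(as.numeric(vapply(fields, function(f) f[5], "")))
  bad <- !ok_len | is.na(st) | is.na(en) | en < st
  n_rejected <- sum(bad)
  src <- path
  if (n_rejected > 0L) {
    src <- tempfile(fileext = paste0(".", fmt))
    writeLines(c(raw[startsWith(raw, "#")], body[!bad]), src)
    on.exit(unlink(src), add = TRUE)
  }

  gr <- rtracklayer::import(src, format = fmt)
  type <- tolower(as.character(gr$type))
  meta <- as.data.frame(S4Vectors::mcols(gr))

  ex <- gr[type == "exon"]
  exmeta <- meta[type == "exon", , drop = FALSE]
  if (length(ex) == 0L) stop("no exon features in ", path)

  if (fmt == "gtf") {
    tx_id <- as.character(exmeta$transcript_id)
    gene_id <- as.character(exmeta$gene_id)
  } else {
    tx_id <- vapply(exmeta$Parent, function(p) {
      if (length(p)) as.character(p[[1]]) else NA_character_
    }, "")
    # gene id via the transcript-level features' Parent, when present
    has_id <- !is.na(meta$ID) & type != "exon"
    g_of_tx <- vapply(meta$Parent[has_id], function(p) {
      if (length(p)) as.character(p[[1]]) else NA_character_
    }, "")
    names(g_of_tx) <- as.character(meta$ID[has_id])
    gene_id <- unname(g_of_tx[tx_id])
    gene_id[is.na(gene_id)] <- tx_id[is.na(gene_id)]
  }

  df <- data.frame(
    transcript_id = tx_id,
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(BiocGenerics::strand(ex)),
    start = BiocGenerics::start(ex),
    end = BiocGenerics::end(ex),
    stringsAsFactors = FALSE
  )
  df <- df[!is.na(df$transcript_id), , drop = FALSE]

  unstranded <- unique(df$transcript_id[!(df$strand %in% c("+", "-"))])
  if (length(unstranded)) {
    warning(length(unstranded), " transcript(s) dropped: unparseable strand")
    df <- df[!(df$transcript_id %in% unstranded), , drop = FALSE]
  }

  # transcription order: ascending start on +, descending on -
  key <- ifelse(df$strand == "+", df$start, -df$start)
  df <- df[order(df$transcript_id, key), , drop = FALSE]
  df$exon_rank <- stats::ave(seq_len(nrow(df)), df$transcript_id,
                             FUN = seq_along)
  rownames(df) <- NULL
  structure(df,
            n_rejected = n_rejected,
            n_unstranded = length(unstranded),
            class = c("transcript_models", "data.frame"))
}

detect_annotation_dialect <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("no feature lines found in ", path)
    if (startsWith(ln, "#") || !nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    attrs <- if (length(f) >= 9) f[9] else ""
    return(if (grepl("=", attrs, fixed = TRUE) &&
               !grepl("\"", attrs, fixed = TRUE)) "gff3" else "gtf")
  }
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", length(unique(x$transcript_id)), "transcripts,",
      length(unique(x$gene_id)), "genes,", nrow(x), "exons\n")
  invisible(x)
}

#' Derive introns from transcript models
#'
#' One intron per adjacent exon pair per transcript, then (by default)
#' deduplicated genome-wide by (chrom, strand, start, end) so each unique
#' acceptor is counted once downstream. Single-exon transcripts yield no
#' introns; zero-length exon gaps are skipped. Both are counted in
#' attributes.
#'
#' @param models A `transcript_models` data frame.
#' @param dedup Deduplicate identical introns across transcripts (default
#'   `TRUE`).
#' @return Data frame of class `introns` with columns `chrom`, `strand`,
#'   `start`, `end` (1-based closed intronic bases), `acceptor` (genomic
#'   coordinate of the last intronic base on the transcribed strand),
#'   `gene_id`, `transcript_id`, `upstream_exon_rank`, `n_support`
#'   (transcripts sharing the intron when `dedup = TRUE`).
#' @export
derive_introns <- function(models, dedup = TRUE) {
  df <- as.data.frame(models)
  if (is.null(df$exon_rank)) {
    key <- ifelse(df$strand == "+", df$start, -df$start)
    df <- df[order(df$transcript_id, key), , drop = FALSE]
    df$exon_rank <- stats::ave(seq_len(nrow(df)), df$transcript_id,
                               FUN = seq_along)
  }
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  n <- nrow(df)
  if (n < 2L) {
    out <- empty_introns()
    return(out)
  }
  same <- df$transcript_id[-1] == df$transcript_id[-n]
  i_up <- which(same)            # upstream exon row (genomic order)
  istart <- df$end[i_up] + 1L
  iend <- df$start[i_up + 1L] - 1L
  keep <- iend >= istart
  n_zero_gap <- sum(!keep)
  i_up <- i_up[keep]; istart <- istart[keep]; iend <- iend[keep]

  strand <- df$strand[i_up]
  res <- data.frame(
    chrom = df$chrom[i_up],
    strand = strand,
    start = istart,
    end = iend,
    acceptor = ifelse(strand == "+", iend, istart),
    gene_id = df$gene_id[i_up],
    transcript_id = df$transcript_id[i_up],
    upstream_exon_rank = ifelse(strand == "+", df$exon_rank[i_up],
                                df$exon_rank[i_up + 1L]),
    stringsAsFactors = FALSE
  )
  n_single_exon <- sum(tapply(df$exon_rank, df$transcript_id, max) == 1L)
  n_before <- nrow(res)
  if (dedup && n_before) {
    key <- paste(res$chrom, res$strand, res$start, res$end, sep = "\r")
    res$n_support <- as.integer(table(key)[key])
    res <- res[!duplicated(key), , drop = FALSE]
    res <- res[order(res$chrom, res$start, res$end, res$strand), ,
               drop = FALSE]
  } else {
    res$n_support <- rep(1L, nrow(res))
  }
  rownames(res) <- NULL
  structure(res,
            n_single_exon = n_single_exon,
            n_zero_gap = n_zero_gap,
            n_before_dedup = n_before,
            class = c("introns", "data.frame"))
}

empty_introns <- function() {
  structure(
    data.frame(chrom = character(), strand = character(), start = integer(),
               end = integer(), acceptor = integer(), gene_id = character(),
               transcript_id = character(), upstream_exon_rank = integer(),
               n_support = integer(), stringsAsFactors = FALSE),
    n_single_exon = 0L, n_zero_gap = 0L, n_before_dedup = 0L,
    class = c("introns", "data.frame"))
}

#' Extract strand-corrected acceptor windows
#'
#' For each intron, extracts `intron_span` intronic bases ending at the
#' acceptor plus `exon_span` bases of the downstream exon, on the transcribed
#' strand (minus-strand sites are reverse-complemented). Soft-masked
#' (lowercase) genome sequence is uppercased. Introns shorter than
#' `intron_span` yield a truncated window carrying a flag. Sites on missing
#' contigs are skipped and recorded.
#'
#' @param genome A `DNAStringSet`, or a path to a FASTA file (names are
#'   truncated at the first whitespace).
#' @param introns An `introns` data frame from [derive_introns()].
#' @param intron_span,exon_span Number of intronic / exonic bases to include
#'   (defaults 20 and 3, the 23-nt acceptor scoring window).
#' @return Data frame of class `acceptor_windows` with columns `site_id`
#'   (`chrom:strand:acceptor`), `chrom`, `strand`, `acceptor`, `gene_id`,
#'   `window`, `intron_span`, `exon_span`, `truncated`,
#'   `acceptor_dinucleotide`; attribute `skipped` records per-site errors.
#' @export
extract_windows <- function(genome, introns, intron_span = 20L,
                            exon_span = 3L) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- as.character(genome)
  lens <- nchar(seqs)

  n <- nrow(introns)
  window <- character(n); isp <- integer(n); esp <- integer(n)
  trunc <- logical(n); err <- character(n)
  for (i in seq_len(n)) {
    chrom <- introns$chrom[i]
    if (!chrom %in% names(seqs)) { err[i] <- "contig missing"; next }
    seq <- seqs[[chrom]]; clen <- lens[[chrom]]
    s <- introns$start[i]; e <- introns$end[i]
    ilen <- e - s + 1L
    ispan <- min(intron_span, ilen)
    if (introns$strand[i] == "+") {
      e_to <- min(e + exon_span, clen)
      espan <- e_to - e
      window[i] <- toupper(substr(seq, e - ispan + 1L, e_to))
    } else {
      s_from <- max(s - exon_span, 1L)
      espan <- s - s_from
      window[i] <- revcomp(toupper(substr(seq, s_from, s + ispan - 1L)))
    }
    isp[i] <- ispan; esp[i] <- espan
    trunc[i] <- ispan < intron_span || espan < exon_span
  }
  ok <- err == ""
  skipped <- data.frame(site = which(!ok), chrom = introns$chrom[!ok],
                        reason = err[!ok], stringsAsFactors = FALSE)
  out <- data.frame(
    site_id = paste(introns$chrom, introns$strand, introns$acceptor,
                    sep = ":")[ok],
    chrom = introns$chrom[ok],
    strand = introns$strand[ok],
    acceptor = introns$acceptor[ok],
    gene_id = if ("gene_id" %in% names(introns)) introns$gene_id[ok]
              else NA_character_,
    window = window[ok],
    intron_span = isp[ok],
    exon_span = esp[ok],
    truncated = trunc[ok],
    stringsAsFactors = FALSE
  )
  out$acceptor_dinucleotide <- ifelse(
    out$intron_span >= 2L,
    substr(out$window, out$intron_span - 1L, out$intron_span), NA_character_)
  # several introns can share one acceptor (e.g. alternative donors);
  # downstream analyses count unique 3' splice sites, so keep one window
  # per site_id (windows at a shared acceptor are identical unless
  # truncated; prefer the non-truncated one)
  out <- out[order(out$site_id, out$truncated), , drop = FALSE]
  out <- out[!duplicated(out$site_id), , drop = FALSE]
  out <- out[order(out$chrom, out$acceptor, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, intron_span = intron_span, exon_span = exon_span,
            skipped = skipped,
            class = c("acceptor_windows", "data.frame"))
}

#' Write acceptor sites as BED6
#'
#' Intervals are the acceptor AG dinucleotide in 0-based half-open BED
#' convention (an AG at 1-based closed `[199, 200]` on `+` becomes
#' `198..200`), sorted by chrom then start.
#'
#' @param windows An `acceptor_windows` data frame.
#' @param path Output path.
#' @export
write_sites_bed <- function(windows, path) {
  if (nrow(windows) == 0L) { file.create(path); return(invisible(path)) }
  # genomic 1-based closed interval of the AG dinucleotide
  g_start <- ifelse(windows$strand == "+", windows$acceptor - 1L,
                    windows$acceptor)
  g_end <- ifelse(windows$strand == "+", windows$acceptor,
                  windows$acceptor + 1L)
  bed <- to_bed_coords(g_start, g_end)
  df <- data.frame(chrom = windows$chrom, start = bed$start, end = bed$end,
                   name = windows$site_id, score = 0L,
                   strand = windows$strand, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read acceptor sites as TSV
#'
#' The TSV carries all window columns and round-trips losslessly through
#' [read_sites_tsv()].
#'
#' @param windows An `acceptor_windows` data frame.
#' @param path File path.
#' @export
write_sites_tsv <- function(windows, path) {
  df <- as.data.frame(windows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (col in c("site_id", "chrom", "strand", "window",
                "acceptor_dinucleotide")) {
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  }
  isp <- if (nrow(df)) max(df$intron_span) else 0L
  esp <- if (nrow(df)) max(df$exon_span) else 0L
  structure(df, intron_span = isp, exon_span = esp,
            class = c("acceptor_windows", "data.frame"))
}

#' Write transcript models as GTF
#'
#' Emits one `exon` feature line per exon with `gene_id` and `transcript_id`
#' attributes (GTF2.2 syntax).
#'
#' @param models A `transcript_models`-like data frame (`chrom`, `start`,
#'   `end`, `strand`, `gene_id`, `transcript_id`).
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  df <- as.data.frame(models)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   df$gene_id, df$transcript_id)
  lines <- paste(df$chrom, "repascan", "exon", df$start, df$end, ".",
                 df$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
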