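# Intron-relative coordinate convention, used everywhere in the package:
# positions count from the intron/exon boundary and skip zero,
#   ... -3 -2 -1 | +1 +2 +3 ...
# so -1 is the last intronic base (the G of the acceptor AG) and +1 is the
# first exonic base.  All position arithmetic funnels through these helpers;
# the GTF (1-based closed) vs BED (0-based half-open) conversion likewise
# lives only here.

#' Intron-relative positions covered by an acceptor window
#'
#' @param intron_span Number of intronic bases in the window.
#' @param exon_span Number of exonic bases in the window.
#' @return Integer vector of positions, `-intron_span .. -1, +1 .. +exon_span`
#'   (there is no position 0).
#' @export
#' @examples
#' intron_positions(5, 2)
intron_positions <- function(intron_span, exon_span = 0L) {
  c(seq.int(-intron_span, -1L),
    if (exon_span > 0L) seq_len(exon_span) else integer(0))
}

#' Map intron-relative positions to 1-based indices within a window string
#'
#' @param pos Integer positions (negative = intronic, positive = exonic;
#'   0 is invalid).
#' @param intron_span Number of intronic bases in the window.
#' @return Integer indices into the window string.
#' @export
pos_to_index <- function(pos, intron_span) {
  pos <- as.integer(pos)
  if (any(pos == 0L)) {
    stop("intron-relative position 0 does not exist (positions skip 0)")
  }
  ifelse(pos < 0L, intron_span + pos + 1L, intron_span + pos)
}

# 1-based closed genomic interval -> BED 0-based half-open
to_bed_coords <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

# bases of one or more windows at intron-relative positions from..to
window_bases <- function(window, from, to, exon_span = 0L) {
  n <- nchar(window)
  if (length(unique(n)) != 1L) stop("windows must share a common length")
  intron_span <- n[1] - exon_span
  pos <- setdiff(seq.int(from, to), 0L)
  if (min(pos) < -intron_span || max(pos) > exon_span) {
    stop("position range ", from, "..", to, " outside window")
  }
  idx <- pos_to_index(pos, intron_span)
  m <- matrix(unlist(strsplit(toupper(window), "", fixed = TRUE)),
              nrow = length(window), byrow = TRUE)
  structure(m[, idx, drop = FALSE], positions = pos)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
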