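# Seeded synthetic-data generators: genomes + annotations with planted
# acceptor windows and alternative-splicing witness transcripts, and
# simulated ortholog window sets with scripted emergence clades.
#
# Planted compositions enforce a margin around the REPA decision boundary
# (>= 6/8 purines over -10..-3 for purine-rich sites, <= 4/8 for
# constitutive ones -- deterministically below the strict >60% rule, which
# needs 5/8) so recovery tests cannot flicker at the threshold.
# Counts (purine-rich fraction, alternative fraction, event-type mixture)
# are assigned deterministically by largest remainder, not by per-gene
# coin flips, so planted proportions are recovered exactly.

#' Configuration for the synthetic-genome generator
#'
#' Defaults emulate the observed study conditions: constitutive acceptors
#' with ~20% A/G over -10..-5 on a pyrimidine-dominated background,
#' purine-rich acceptors with ~70% A/G, planted G tracts whose first G lies
#' in -11..-6 (bimodal with peaks at -10 and -8) with run lengths 3..8
#' dominated by G3-5 (~98.5%), a 68% alternative fraction among purine-rich
#' sites, and an event-type mixture whose retained-intron share is 17x and
#' alternative-3'SS share 1.6x their transcriptome-wide reference
#' proportions.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_genes Number of genes.
#' @param repa_fraction Fraction of genes whose focus acceptor is planted
#'   purine-rich.
#' @param as_fraction Fraction of purine-rich focus acceptors given an
#'   alternative-splicing witness transcript.
#' @param intron_span,exon_span Acceptor-window geometry used downstream.
#' @param constitutive_ag,repa_ag Per-position P(A or G) of the two planted
#'   compositions over -20..-3.
#' @param first_g_probs Named probabilities of the planted tract's first-G
#'   position (over -11..-6).
#' @param g_len_probs Named probabilities of the planted run length (3..8).
#' @param as_event_mixture Named mixture over the four event types.
#' @param reference_proportions Reference (transcriptome-wide) event-type
#'   proportions used for fold enrichment.
#' @return List of class `repa_sim_config`.
#' @export
repa_sim_config <- function(seed = 1L,
                            n_genes = 60L,
                            repa_fraction = 0.5,
                            as_fraction = 0.68,
                            intron_span = 20L,
                            exon_span = 3L,
                            constitutive_ag = 0.20,
                            repa_ag = 0.70,
                            first_g_probs = c("-11" = 0.15, "-10" = 0.26,
                                              "-9" = 0.14, "-8" = 0.24,
                                              "-7" = 0.13, "-6" = 0.08),
                            g_len_probs = c("3" = 0.55, "4" = 0.28,
                                            "5" = 0.155, "6" = 0.008,
                                            "7" = 0.004, "8" = 0.003),
                            as_event_mixture = c(cassette_exon = 0.16,
                                                 alt_3ss = 0.40,
                                                 alt_5ss = 0.10,
                                                 retained_intron = 0.34),
                            reference_proportions = c(cassette_exon = 0.52,
                                                      alt_3ss = 0.25,
                                                      alt_5ss = 0.21,
                                                      retained_intron =
                                                        0.02)) {
  for (v in list(first_g_probs, g_len_probs, as_event_mixture,
                 reference_proportions)) {
    if (abs(sum(v) - 1) > 1e-9) {
      stop("probability vector does not sum to 1: ",
           paste(names(v), collapse = ","))
    }
  }
  stopifnot(repa_fraction >= 0, repa_fraction <= 1,
            as_fraction >= 0, as_fraction <= 1, n_genes >= 1)
  structure(as.list(environment()), class = "repa_sim_config")
}

# deterministic integer allocation of n among proportions p (largest
# remainder)
allocate_counts <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

sample_base <- function(n, p_ag) {
  # purines split ~2:1 A:G within the A/G mass, pyrimidines ~1:1 C:T
  probs <- c(A = 2 / 3 * p_ag, C = (1 - p_ag) / 2, G = 1 / 3 * p_ag,
             T = (1 - p_ag) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = probs)
}

# break every G run of length >= min_len whose span intersects positions
# idx_range (indices into the vector), replacing middle bases with repl
break_g_runs <- function(bases, min_len, idx_range, repl = "A") {
  repeat {
    r <- rle(bases == "G")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    gi <- which(r$values & r$lengths >= min_len &
                  starts <= max(idx_range) & ends >= min(idx_range))
    if (!length(gi)) return(bases)
    k <- gi[1]
    mid <- starts[k] + (r$lengths[k] %/% 2L)
    bases[mid] <- repl
  }
}

# One planted acceptor tail over positions -span..-1 (transcribed strand),
# ending in AG. `kind` is "constitutive" or "repa"; for "repa" a G tract of
# `len` Gs starting at `first_g` is planted, flanked by non-G, and is the
# only G run of >= 3 in the scan range.
make_acceptor_tail <- function(kind, span, cfg, first_g = NA, len = NA) {
  idx_of <- function(pos) span + pos + 1L   # negative positions only
  scan_idx <- idx_of(-min(15L, span)):idx_of(-3L)
  for (attempt in seq_len(200L)) {
    p_ag <- if (kind == "repa") cfg$repa_ag else cfg$constitutive_ag
    b <- sample_base(span, p_ag)
    b[idx_of(-2L)] <- "A"; b[idx_of(-1L)] <- "G"
    range83 <- idx_of(-10L):idx_of(-3L)
    if (kind == "repa") {
      ti <- idx_of(first_g):idx_of(first_g + len - 1L)
      b[ti] <- "G"
      if (min(ti) > 1L && b[min(ti) - 1L] == "G") b[min(ti) - 1L] <- "A"
      if (max(ti) < span && b[max(ti) + 1L] == "G") {
        b[max(ti) + 1L] <- "A"
      }
      # the planted run must be the only reportable tract
      sub <- b; sub[ti] <- "g"            # mask planted run
      sub <- break_g_runs(sub, 3L, scan_idx, repl = "A")
      sub[ti] <- "G"
      b <- sub
      # enforce >= 6/8 purines over -10..-3
      while (sum(b[range83] %in% c("A", "G")) < 6L) {
        py <- intersect(range83, which(!(b %in% c("A", "G"))))
        py <- setdiff(py, ti)
        if (!length(py)) break
        b[py[1]] <- "A"
      }
      ok <- sum(b[range83] %in% c("A", "G")) >= 6L
    } else {
      b <- break_g_runs(b, 3L, scan_idx, repl = "T")
      # at most 4/8 purines: deterministically below the strict >60% rule
      # (which needs 5/8) without distorting the ~20% A/G composition
      ok <- sum(b[range83] %in% c("A", "G")) <= 4L
    }
    if (ok) return(paste(b, collapse = ""))
  }
  stop("infeasible planted composition for kind=", kind)
}

sample_tract_geometry <- function(cfg) {
  fg <- as.integer(sample(names(cfg$first_g_probs), 1L,
                          prob = cfg$first_g_probs))
  max_len <- -2L - fg          # last G must sit at or 5' of -3
  lp <- cfg$g_len_probs[as.integer(names(cfg$g_len_probs)) <= max_len]
  len <- as.integer(sample(names(lp), 1L, prob = lp / sum(lp)))
  c(first_g = fg, len = len)
}

#' Generate a synthetic genome with planted acceptors and AS events
#'
#' Builds `n_genes` multi-exon genes (2-6 exons, alternating strands, two
#' contigs), plants a purine-rich or constitutive acceptor window at each
#' intron end, gives a deterministic subset of the purine-rich focus
#' acceptors an alternative-splicing witness transcript realizing the
#' configured event-type mixture, and returns the genome, the annotation,
#' and a per-site truth table. Byte-identical output under the same seed.
#'
#' @param config A `repa_sim_config`.
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gtf`, `truth.tsv`.
#' @return List of class `repa_sim_genome`: `genome` (DNAStringSet),
#'   `annotation` (`transcript_models`-style exon data frame), `truth`
#'   (per-acceptor data frame: `site_id`, `gene_id`, `is_repa`, `first_g`,
#'   `tract_length`, `as_type`, `is_alternative`), `events_truth`,
#'   `counts`, `config`, and the file paths when written.
#' @export
generate_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "repa_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  span <- 20L   # designed acceptor tail length (covers the -20..-1 window)

  n_repa <- round(n * cfg$repa_fraction)
  repa_genes <- sort(sample.int(n, n_repa))
  n_as <- round(n_repa * cfg$as_fraction)
  as_genes <- sort(sample(repa_genes, n_as))
  type_counts <- allocate_counts(n_as, cfg$as_event_mixture)
  gene_type <- stats::setNames(rep(NA_character_, n), paste0("g", 1:n))
  if (n_as > 0L) {
    gene_type[paste0("g", as_genes)] <- sample(
      rep(names(type_counts), type_counts))
  }

  chroms <- c("chrS1", "chrS2")
  chrom_seq <- stats::setNames(vector("list", 2), chroms)
  chrom_seq[[1]] <- chrom_seq[[2]] <- character(0)
  cursor <- stats::setNames(c(0L, 0L), chroms)

  exon_rows <- list(); truth_rows <- list(); event_rows <- list()
  n_tx <- 0L

  for (g in seq_len(n)) {
    gid <- paste0("g", g)
    is_repa_gene <- g %in% repa_genes
    ev <- gene_type[[gid]]
    n_ex <- if (!is.na(ev) && ev == "cassette_exon") {
      sample(3:6, 1L)
    } else {
      sample(2:6, 1L)
    }
    ex_len <- sample(80:200, n_ex, replace = TRUE)
    in_len <- sample(60:150, n_ex - 1L, replace = TRUE)
    focus <- if (!is.na(ev) && ev == "cassette_exon") {
      sample.int(n_ex - 2L, 1L)      # cassette exon must be internal
    } else {
      sample.int(n_ex - 1L, 1L)
    }

    # transcribed-strand gene sequence
    glen <- sum(ex_len) + sum(in_len)
    seq_b <- sample(DNA_BASES, glen, replace = TRUE)
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    pos <- 0L
    tract <- c(first_g = NA_integer_, len = NA_integer_)
    for (k in seq_len(n_ex)) {
      ex_start[k] <- pos + 1L; pos <- pos + ex_len[k]; ex_end[k] <- pos
      if (k < n_ex) {
        istart <- pos + 1L; pos <- pos + in_len[k]; iend <- pos
        kind <- if (is_repa_gene && k == focus) "repa" else "constitutive"
        if (kind == "repa") {
          tract <- sample_tract_geometry(cfg)
          tail_seq <- make_acceptor_tail("repa", span, cfg,
                                         tract["first_g"], tract["len"])
        } else {
          tail_seq <- make_acceptor_tail("constitutive", span, cfg)
        }
        seq_b[(iend - span + 1L):iend] <- strsplit(tail_seq, "")[[1]]
      }
    }
    # alt-3'SS witness: the shifted acceptor must itself look like a clean
    # constitutive acceptor (AG preceded by pyrimidines), so design the
    # first 12 bases of the downstream exon accordingly.
    if (!is.na(ev) && ev == "alt_3ss") {
      es <- ex_start[focus + 1L]
      py <- sample(c("C", "T"), 10L, replace = TRUE)
      seq_b[es:(es + 9L)] <- py
      seq_b[es + 10L] <- "A"; seq_b[es + 11L] <- "G"
    }

    strand <- if (g %% 2L == 1L) "+" else "-"
    chrom <- if (g <= ceiling(n / 2)) chroms[1] else chroms[2]
    gap <- sample(200:500, 1L)
    gap_seq <- sample(DNA_BASES, gap, replace = TRUE)
    offset <- cursor[[chrom]] + gap
    gene_g <- if (strand == "+") seq_b else
      rev(chartr("ACGT", "TGCA", seq_b))
    chrom_seq[[chrom]] <- c(chrom_seq[[chrom]], gap_seq, gene_g)
    cursor[[chrom]] <- offset + glen
    t2g <- if (strand == "+") {
      function(p) offset + p
    } else {
      function(p) offset + glen - p + 1L
    }

    g_ex <- t(vapply(seq_len(n_ex), function(k) {
      range(t2g(ex_start[k]), t2g(ex_end[k]))
    }, c(0L, 0L)))

    tx1 <- paste0(gid, ".t1")
    n_tx <- n_tx + 1L
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      transcript_id = tx1, gene_id = gid, chrom = chrom, strand = strand,
      start = g_ex[, 1], end = g_ex[, 2], stringsAsFactors = FALSE)

    # per-intron truth
    for (k in seq_len(n_ex - 1L)) {
      i_t_end <- ex_start[k + 1L] - 1L
      acc_g <- t2g(i_t_end)   # genomic coordinate of the -1 base
      focus_here <- is_repa_gene && k == focus
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        site_id = paste(chrom, strand, acc_g, sep = ":"),
        gene_id = gid,
        is_repa = focus_here,
        first_g = if (focus_here) tract[["first_g"]] else NA_integer_,
        tract_length = if (focus_here) tract[["len"]] else NA_integer_,
        as_type = if (focus_here && !is.na(ev)) ev else NA_character_,
        is_alternative = focus_here && !is.na(ev),
        stringsAsFactors = FALSE)
    }

    # witness transcript
    if (!is.na(ev)) {
      tx2 <- paste0(gid, ".t2")
      n_tx <- n_tx + 1L
      v_start <- ex_start; v_end <- ex_end
      drop_k <- NULL
      if (ev == "cassette_exon") {
        drop_k <- focus + 1L
      } else if (ev == "alt_3ss") {
        v_start[focus + 1L] <- v_start[focus + 1L] + 12L
      } else if (ev == "alt_5ss") {
        v_end[focus] <- v_end[focus] - 12L
      } else if (ev == "retained_intron") {
        v_end[focus] <- v_end[focus + 1L]
        drop_k <- focus + 1L
      }
      keep <- setdiff(seq_len(n_ex), drop_k)
      gv <- t(vapply(keep, function(k) {
        range(t2g(v_start[k]), t2g(v_end[k]))
      }, c(0L, 0L)))
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = tx2, gene_id = gid, chrom = chrom,
        strand = strand, start = gv[, 1], end = gv[, 2],
        stringsAsFactors = FALSE)
      # event truth (genomic)
      i_t_end <- ex_start[focus + 1L] - 1L
      acc_g <- t2g(i_t_end)
      event_rows[[length(event_rows) + 1L]] <- data.frame(
        gene_id = gid, event_type = ev, chrom = chrom, strand = strand,
        acceptor = acc_g, stringsAsFactors = FALSE)
      if (ev == "alt_3ss") {
        # second acceptor of the event: the shifted intron end
        acc2 <- t2g(ex_start[focus + 1L] + 11L)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          site_id = paste(chrom, strand, acc2, sep = ":"),
          gene_id = gid, is_repa = FALSE, first_g = NA_integer_,
          tract_length = NA_integer_, as_type = ev,
          is_alternative = TRUE, stringsAsFactors = FALSE)
      }
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, "",
                                            collapse = ""))
  names(genome) <- chroms
  annotation <- do.call(rbind, exon_rows)
  truth <- do.call(rbind, truth_rows)
  truth <- truth[!duplicated(truth$site_id), , drop = FALSE]
  rownames(truth) <- NULL
  events_truth <- if (length(event_rows)) do.call(rbind, event_rows) else
    data.frame(gene_id = character(), event_type = character(),
               chrom = character(), strand = character(),
               acceptor = integer(), stringsAsFactors = FALSE)

  out <- list(genome = genome, annotation = annotation, truth = truth,
              events_truth = events_truth,
              counts = list(n_genes = n, n_transcripts = n_tx,
                            n_repa = n_repa, n_as = n_as,
                            n_unique_acceptors = nrow(truth),
                            type_counts = type_counts),
              config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$fasta_path <- file.path(out_dir, "genome.fa")
    out$gtf_path <- file.path(out_dir, "annotation.gtf")
    out$truth_path <- file.path(out_dir, "truth.tsv")
    Biostrings::writeXStringSet(genome, out$fasta_path)
    write_gtf(annotation, out$gtf_path)
    utils::write.table(truth, out$truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  structure(out, class = "repa_sim_genome")
}

#' @export
print.repa_sim_genome <- function(x, ...) {
  cat("repa_sim_genome:", x$counts$n_genes, "genes,",
      x$counts$n_transcripts, "transcripts,",
      sum(Biostrings::width(x$genome)), "bp on", length(x$genome),
      "contigs\n")
  cat("  planted purine-rich focus acceptors:", x$counts$n_repa,
      "(", x$counts$n_as, "with AS witnesses )\n")
  invisible(x)
}

#' Generate simulated ortholog window sets with scripted emergence
#'
#' Assigns each gene a scripted emergence scenario (mammalian-ancestor
#' emergence at the marsupial or other-mammal level, or pre-mammalian
#' emergence at the bird/reptile/fish level, with deterministic counts),
#' fills each clade with `species_per_clade` windows that carry or lack a
#' G tract accordingly, interrupts tracts with a single T (secondary loss)
#' at `loss_rate` per species within present clades, and marks clade cells
#' not-determined at `nd_rate`.
#'
#' @param n_genes Number of simulated genes.
#' @param pct_mammalian Fraction of genes with mammalian-ancestor emergence
#'   (deterministic count).
#' @param loss_rate Per-species probability of secondary tract loss within
#'   a present clade.
#' @param nd_rate Per-cell probability that a clade is not determined.
#' @param species_per_clade Species per clade column.
#' @param seed Integer seed.
#' @return List of class `repa_sim_orthologs`: `table` (an
#'   `ortholog_windows` data frame), `truth` (`gene_symbol`, `scenario`,
#'   `scripted_call`).
#' @export
generate_ortholog_sets <- function(n_genes = 100L, pct_mammalian = 0.87,
                                   loss_rate = 0.1, nd_rate = 0,
                                   species_per_clade = 3L, seed = 1L) {
  set.seed(seed)
  n_mam <- round(n_genes * pct_mammalian)
  scripted <- c(rep("mammalian_ancestor", n_mam),
                rep("pre_mammalian", n_genes - n_mam))
  scripted <- sample(scripted)
  scenarios <- ifelse(
    scripted == "mammalian_ancestor",
    sample(c("marsupials", "other_mammals"), n_genes, replace = TRUE),
    sample(c("birds", "reptiles", "fish"), n_genes, replace = TRUE))

  present_clades <- function(sc) {
    switch(sc,
           other_mammals = "other_mammals",
           marsupials = c("marsupials", "other_mammals"),
           birds = c("birds", "marsupials", "other_mammals"),
           reptiles = c("reptiles", "marsupials", "other_mammals"),
           fish = REPA_CLADES)
  }
  present_window <- function() {
    b <- sample(c("C", "T", "C", "T", "A"), 15L, replace = TRUE)
    b <- break_g_runs(b, 3L, 1:13)
    b[4:7] <- "G"                      # G4 at -12..-9
    b[3] <- "T"; b[8] <- "T"
    b[14] <- "A"; b[15] <- "G"
    paste(b, collapse = "")
  }
  absent_window <- function() {
    b <- sample(c("C", "T", "C", "T", "A", "G"), 15L, replace = TRUE,
                prob = c(.3, .3, .15, .15, .07, .03))
    b <- break_g_runs(b, 3L, 1:13, repl = "T")
    b[14] <- "A"; b[15] <- "G"
    paste(b, collapse = "")
  }
  lose_tract <- function(w) {
    # wallaby-style interruption: split the run with a single T
    b <- strsplit(w, "")[[1]]
    b <- break_g_runs(b, 3L, 1:13, repl = "T")
    paste(b, collapse = "")
  }

  rows <- list()
  for (i in seq_len(n_genes)) {
    gene <- sprintf("simgene%04d", i)
    pres <- present_clades(scenarios[i])
    for (cl in REPA_CLADES) {
      nd_cell <- nd_rate > 0 && stats::runif(1) < nd_rate
      for (s in seq_len(species_per_clade)) {
        sp <- paste0(cl, "_sp", s)
        seqv <- if (nd_cell) {
          "ND"
        } else if (cl %in% pres) {
          w <- present_window()
          if (stats::runif(1) < loss_rate) lose_tract(w) else w
        } else {
          absent_window()
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene_symbol = gene, species = sp, clade = cl, sequence = seqv,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(
    table = structure(tab, class = c("ortholog_windows", "data.frame")),
    truth = data.frame(gene_symbol = sprintf("simgene%04d",
                                             seq_len(n_genes)),
                       scenario = scenarios, scripted_call = scripted,
                       stringsAsFactors = FALSE)),
    class = "repa_sim_orthologs")
}
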