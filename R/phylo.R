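# Evolutionary emergence of acceptor G tracts across vertebrate classes:
# per-species presence/absence at orthologous acceptors, completeness
# filtering, and clade-of-emergence calls under a Dollo assumption (a tract
# arises once and may be lost repeatedly, so absence in a lineage nested
# inside presence is treated as secondary loss).

#' Vertebrate clade ladder used for emergence calls
#'
#' Ordered from the outermost class to the innermost: fish, reptiles, birds
#' (reptiles and birds as siblings at one level), marsupials, other
#' mammals.
#' @export
REPA_CLADES <- c("fish", "reptiles", "birds", "marsupials", "other_mammals")

#' Load an ortholog acceptor-window table
#'
#' TSV with columns `gene_symbol`, `species`, `clade` and `sequence`, one
#' row per gene x species. The `sequence` cell is either an acceptor window
#' (A/C/G/T/N, 3' intron end, position -1 last), a direct presence digit
#' (`1`/`0`) for panels where only the determination is available, or `ND`
#' (not determined). Extra columns are carried through.
#'
#' @param path Path to the TSV.
#' @return Data frame of class `ortholog_windows`.
#' @export
load_ortholog_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  need <- c("gene_symbol", "species", "clade", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ortholog table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$sequence <- as.character(df$sequence)
  df$clade <- as.character(df$clade)
  bad <- setdiff(unique(df$clade), REPA_CLADES)
  if (length(bad)) {
    stop("unknown clade label(s): ", paste(bad, collapse = ", "),
         " (expected: ", paste(REPA_CLADES, collapse = ", "), ")")
  }
  structure(df, class = c("ortholog_windows", "data.frame"))
}

#' Curated vertebrate acceptor G-tract panel
#'
#' A packaged panel of 21 human 3' splice sites whose G tracts were
#' examined across vertebrate classes: the human acceptor window
#' (-15..-1 of the intron end) plus per-clade presence/absence/ND
#' determinations for other mammals, marsupials, birds, reptiles and fish.
#'
#' @return An `ortholog_windows` data frame (21 genes x 5 clades).
#' @export
#' @examples
#' tab <- repa_vertebrate_table()
#' length(unique(tab$gene_symbol))
repa_vertebrate_table <- function() {
  load_ortholog_table(system.file("extdata",
                                  "vertebrate_acceptor_gtracts.tsv",
                                  package = "repascan", mustWork = TRUE))
}

status_of_cell <- function(sequence, gmin) {
  s <- trimws(sequence)
  if (is.na(s) || toupper(s) == "ND" || s == "") return(NA)
  if (s %in% c("0", "1")) return(s == "1")
  if (!grepl("^[ACGTNacgtn]+$", s)) {
    stop("unrecognized sequence/status cell: ", s)
  }
  nrow(find_g_tracts(toupper(s), min_len = gmin)) > 0L
}

#' Per-clade G-tract presence for one gene
#'
#' Clade presence is an OR over the clade's species: 1 if at least one
#' determined species carries a G tract of length >= `gmin` within -15..-3,
#' 0 if all determined species lack one, ND when no species is determined.
#' A row is `complete` when all five clades are determined.
#'
#' @param window_set Rows of an `ortholog_windows` table for one gene.
#' @param gmin Minimal tract length (default 3, the minimal functional
#'   G-tract unit).
#' @return One-row data frame: `gene_symbol`, one integer column per clade
#'   (1/0/`NA` for ND), `complete`.
#' @export
presence_row <- function(window_set, gmin = 3L) {
  stopifnot(length(unique(window_set$gene_symbol)) == 1L)
  out <- data.frame(gene_symbol = window_set$gene_symbol[1],
                    stringsAsFactors = FALSE)
  for (cl in REPA_CLADES) {
    cells <- window_set$sequence[window_set$clade == cl]
    st <- vapply(cells, status_of_cell, NA, gmin = gmin)
    out[[cl]] <- if (!length(st) || all(is.na(st))) NA_integer_
                 else as.integer(any(st, na.rm = TRUE))
  }
  out$complete <- !anyNA(out[REPA_CLADES])
  out
}

#' Presence/absence matrix over all genes of an ortholog table
#'
#' @param table An `ortholog_windows` data frame.
#' @inheritParams presence_row
#' @return Data frame of class `presence_matrix`, one row per gene (see
#'   [presence_row()]), in first-appearance gene order.
#' @export
presence_matrix <- function(table, gmin = 3L) {
  genes <- unique(table$gene_symbol)
  rows <- lapply(genes, function(g) {
    presence_row(table[table$gene_symbol == g, , drop = FALSE], gmin)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("presence_matrix", "data.frame"))
}

#' Call the clade of emergence for each gene
#'
#' Dollo logic on the clade ladder: a gene is called
#' `mammalian_ancestor` when the tract is present in at least one mammalian
#' clade (marsupials or other mammals) and determined absent in birds,
#' reptiles and fish -- absence within a nested mammalian lineage is treated
#' as secondary loss, not independent absence. It is `pre_mammalian` when
#' present in any of birds, reptiles or fish. Rows absent everywhere are
#' `absent`; anything else (undetermined cells blocking the call) is
#' `undetermined`.
#'
#' @param rows A `presence_matrix` data frame.
#' @return The same data frame with an `emergence_call` column.
#' @export
call_emergence <- function(rows) {
  nonmam <- c("birds", "reptiles", "fish")
  call1 <- function(r) {
    nm <- unlist(r[nonmam]); mm <- unlist(r[c("marsupials",
                                              "other_mammals")])
    if (any(nm == 1L, na.rm = TRUE)) return("pre_mammalian")
    if (any(mm == 1L, na.rm = TRUE) && all(!is.na(nm)) && all(nm == 0L)) {
      return("mammalian_ancestor")
    }
    if (all(!is.na(c(nm, mm))) && all(c(nm, mm) == 0L)) return("absent")
    "undetermined"
  }
  rows$emergence_call <- vapply(seq_len(nrow(rows)), function(i) {
    call1(rows[i, , drop = FALSE])
  }, "")
  rows
}

#' Summarize emergence calls
#'
#' Only complete rows (all five clades determined) enter the percentages;
#' complete rows partition into mammalian-ancestor, pre-mammalian, and
#' absent-everywhere. Also reported (not part of the partition): among
#' mammalian-ancestor rows, how many are present in marsupials versus only
#' in other mammals (marsupial absence read as loss under Dollo logic).
#'
#' @param rows Output of [call_emergence()].
#' @return List of class `emergence_summary`: `n_rows`, `n_complete`,
#'   `n_mammalian`, `n_pre_mammalian`, `n_absent`, `pct_mammalian`
#'   (of complete rows; `NA` when none), `n_marsupial_present_mammalian`,
#'   `n_marsupial_absent_mammalian`, `clade_presence` (per-clade presence
#'   counts among complete rows).
#' @export
summarize_emergence <- function(rows) {
  if (!"emergence_call" %in% names(rows)) rows <- call_emergence(rows)
  comp <- rows[rows$complete, , drop = FALSE]
  n_complete <- nrow(comp)
  n_mam <- sum(comp$emergence_call == "mammalian_ancestor")
  n_pre <- sum(comp$emergence_call == "pre_mammalian")
  n_abs <- sum(comp$emergence_call == "absent")
  mam <- comp[comp$emergence_call == "mammalian_ancestor", , drop = FALSE]
  structure(list(
    n_rows = nrow(rows),
    n_complete = n_complete,
    n_mammalian = n_mam,
    n_pre_mammalian = n_pre,
    n_absent = n_abs,
    pct_mammalian = if (n_complete) 100 * n_mam / n_complete else NA_real_,
    n_marsupial_present_mammalian = sum(mam$marsupials == 1L),
    n_marsupial_absent_mammalian = sum(mam$marsupials == 0L),
    clade_presence = vapply(REPA_CLADES, function(cl) {
      sum(comp[[cl]] == 1L)
    }, 0L)
  ), class = "emergence_summary")
}

#' @export
print.emergence_summary <- function(x, ...) {
  cat("emergence_summary:", x$n_rows, "genes,", x$n_complete,
      "complete in every clade\n")
  cat(sprintf("  mammalian-ancestor: %d (%.1f%% of complete)\n",
              x$n_mammalian, x$pct_mammalian))
  cat("  pre-mammalian:", x$n_pre_mammalian,
      " absent everywhere:", x$n_absent, "\n")
  cat("  mammalian rows absent in marsupials (secondary loss):",
      x$n_marsupial_absent_mammalian, "\n")
  invisible(x)
}
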