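test_that("GTF parsing yields transcript models in transcription order", {
  df <- rbind(
    exon_df("t1", "gA", "chr1", "+", c(1, 201), c(100, 300)),
    exon_df("t2", "gB", "chr1", "-", c(401, 601), c(500, 700))
  )
  path <- write_test_gtf(df)
  models <- parse_annotation(path)
  expect_s3_class(models, "transcript_models")
  expect_equal(length(unique(models$transcript_id)), 2L)

  m1 <- models[models$transcript_id == "t1", ]
  expect_equal(m1$start, c(1, 201))
  expect_equal(m1$exon_rank, c(1, 2))

  # minus strand: transcription order is descending genomic coordinate
  m2 <- models[models$transcript_id == "t2", ]
  expect_equal(m2$start, c(601, 401))
  expect_equal(m2$exon_rank, c(1, 2))
})

test_that("GFF3 dialect is auto-detected and parsed", {
  lines <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=gA",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tParent=t1"
  )
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  models <- parse_annotation(path)
  expect_equal(nrow(models), 2L)
  expect_equal(unique(models$gene_id), "gA")
  expect_equal(unique(models$transcript_id), "t1")
})

test_that("malformed coordinate records are rejected and counted", {
  df <- exon_df("t1", "gA", "chr1", "+", c(1, 201), c(100, 300))
  path <- write_test_gtf(df)
  lines <- readLines(path)
  bad <- sub("\t201\t300\t", "\t301\t300\t", lines[2], fixed = TRUE)
  writeLines(c(lines[1], bad), path)
  models <- parse_annotation(path)
  expect_equal(attr(models, "n_rejected"), 1L)
  expect_equal(nrow(models), 1L)
})

test_that("introns are derived per adjacent exon pair and deduplicated", {
  df <- rbind(
    exon_df("t1", "gA", "chr1", "+", c(1, 201), c(100, 300)),
    exon_df("t2", "gA", "chr1", "+", c(1, 201), c(100, 320)),   # same intron
    exon_df("t3", "gB", "chr1", "+", c(1001, 1101, 1301),
            c(1050, 1200, 1400))
  )
  introns <- derive_introns(df)
  expect_equal(nrow(introns), 3L)   # 1 shared + 2 from the 3-exon gene
  shared <- introns[introns$start == 101, ]
  expect_equal(shared$end, 200)
  expect_equal(shared$n_support, 2L)
  expect_equal(shared$acceptor, 200)
  expect_equal(sum(introns$gene_id == "gB"), 2L)

  # minus strand acceptor is the genomic start of the intron
  dfm <- exon_df("t4", "gC", "chr1", "-", c(1, 201), c(100, 300))
  im <- derive_introns(dfm)
  expect_equal(im$acceptor, 101)
})

test_that("zero-length exon gaps yield no intron but are counted", {
  df <- exon_df("t1", "gA", "chr1", "+", c(1, 101), c(100, 200))
  introns <- derive_introns(df)
  expect_equal(nrow(introns), 0L)
  expect_equal(attr(introns, "n_zero_gap"), 1L)
})

test_that("window extraction is strand-correct and truncation-aware", {
  # plant the 15-nt acceptor tail at a known intron end on both strands
  tail15 <- "GTCTTGGGGGTTTAG"
  plus_chrom <- paste0(strrep("T", 85), tail15, strrep("C", 50))
  minus_chrom <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus_chrom)))
  genome <- Biostrings::DNAStringSet(c(p = plus_chrom, m = minus_chrom))

  ip <- data.frame(chrom = "p", strand = "+", start = 21L, end = 100L,
                   acceptor = 100L, gene_id = "gA",
                   stringsAsFactors = FALSE)
  im <- data.frame(chrom = "m", strand = "-", start = 51L, end = 130L,
                   acceptor = 51L, gene_id = "gA",
                   stringsAsFactors = FALSE)
  wp <- extract_windows(genome, ip, intron_span = 15L, exon_span = 0L)
  wm <- extract_windows(genome, im, intron_span = 15L, exon_span = 0L)
  expect_equal(wp$window, tail15)
  expect_equal(wm$window, tail15)   # strand round trip
  expect_equal(wp$acceptor_dinucleotide, "AG")
  expect_false(wp$truncated)

  # exon bases are read past the acceptor
  wpe <- extract_windows(genome, ip, intron_span = 15L, exon_span = 3L)
  expect_equal(wpe$window, paste0(tail15, "CCC"))

  # soft-masked input is uppercased
  soft <- Biostrings::DNAStringSet(c(p = tolower(plus_chrom)))
  ws <- extract_windows(soft, ip, intron_span = 15L, exon_span = 0L)
  expect_equal(ws$window, tail15)

  # short intron -> truncated window with flag
  ishort <- data.frame(chrom = "p", strand = "+", start = 91L, end = 100L,
                       acceptor = 100L, gene_id = "gA",
                       stringsAsFactors = FALSE)
  wt <- extract_windows(genome, ishort, intron_span = 20L, exon_span = 0L)
  expect_true(wt$truncated)
  expect_equal(nchar(wt$window), 10L)

  # missing contig -> skipped with an error record
  imiss <- data.frame(chrom = "nope", strand = "+", start = 1L, end = 50L,
                      acceptor = 50L, gene_id = "gA",
                      stringsAsFactors = FALSE)
  wmiss <- extract_windows(genome, imiss, 15L, 0L)
  expect_equal(nrow(wmiss), 0L)
  expect_equal(attr(wmiss, "skipped")$reason, "contig missing")
})

test_that("coordinate mirror round-trip holds across a synthetic genome", {
  b <- sim_bundle(seed = 23, n_genes = 10)
  genome <- b$sim$genome
  widths <- Biostrings::width(genome)
  mirrored <- Biostrings::reverseComplement(genome)
  introns <- b$introns
  mint <- introns
  L <- widths[match(introns$chrom, names(genome))]
  mint$start <- L - introns$end + 1L
  mint$end <- L - introns$start + 1L
  mint$strand <- ifelse(introns$strand == "+", "-", "+")
  mint$acceptor <- ifelse(mint$strand == "+", mint$end, mint$start)
  w1 <- extract_windows(genome, introns, 20L, 3L)
  w2 <- extract_windows(mirrored, mint, 20L, 3L)
  key1 <- w1$window[order(w1$window)]
  key2 <- w2$window[order(w2$window)]
  expect_equal(key1, key2)
})

test_that("AG-terminated non-truncated windows end in AG", {
  b <- sim_bundle(seed = 5, n_genes = 15)
  w <- b$windows[!b$windows$truncated, ]
  expect_true(all(w$acceptor_dinucleotide == "AG"))
})

test_that("BED output uses 0-based half-open acceptor intervals, sorted", {
  w <- data.frame(site_id = c("chr1:+:200", "chr1:-:50"),
                  chrom = "chr1", strand = c("+", "-"),
                  acceptor = c(200L, 50L), gene_id = "g",
                  window = "X", intron_span = 15L, exon_span = 0L,
                  truncated = FALSE, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_sites_bed(w, path)
  bed <- utils::read.table(path, sep = "\t")
  # AG at 1-based [199,200] on + -> 198..200; at [50,51] on - -> 49..51
  expect_equal(bed$V2, c(49L, 198L))
  expect_equal(bed$V3, c(51L, 200L))
  expect_true(!is.unsorted(bed$V2))

  # empty set -> empty file, no crash
  path2 <- tempfile(fileext = ".bed")
  write_sites_bed(w[0, ], path2)
  expect_true(file.exists(path2))
  expect_equal(length(readLines(path2)), 0L)
})

test_that("sites TSV round-trips losslessly", {
  b <- sim_bundle(seed = 3, n_genes = 8)
  path <- tempfile(fileext = ".tsv")
  write_sites_tsv(b$windows, path)
  back <- read_sites_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(b$windows),
               ignore_attr = TRUE)
})

test_that("synthetic annotation bookkeeping matches the generator truth", {
  cfg <- repa_sim_config(seed = 31, n_genes = 60)
  dir <- tempfile()
  sim <- generate_genome(cfg, out_dir = dir)
  models <- parse_annotation(sim$gtf_path)
  expect_equal(length(unique(models$transcript_id)),
               sim$counts$n_transcripts)
  introns <- derive_introns(models)
  w <- extract_windows(sim$fasta_path, introns, 20L, 3L)
  expect_setequal(w$site_id, sim$truth$site_id)
  expect_equal(nrow(w), sim$counts$n_unique_acceptors)
})
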